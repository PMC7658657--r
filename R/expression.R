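# Expression-level screening: the pan-cancer dysregulation matrix,
# multi-cancer gene/pair screens, per-sample abnormality calls for
# AA/AN/NN grouping, and the up/down z-score summary.

#' Build the gene x cancer dysregulation-status matrix
#'
#' Collects per-cancer DE statuses into one matrix; genes absent from a
#' cancer's result are `normal` there. `n_dysregulated[g]` counts cancers
#' with status != normal.
#'
#' @param de_results list of [de_test()] data.frames, one per cancer, or a
#'   single row-bound data.frame with a `cancer` column.
#' @return object of class `sl_dysreg`: list(status = character matrix
#'   genes x cancers, n_dysregulated, n_up, n_down = named integer vectors).
#' @export
build_dysregulation_matrix <- function(de_results) {
  if (is.data.frame(de_results)) {
    de <- de_results
  } else {
    de <- do.call(rbind, de_results)
  }
  stop_cols(de, c("gene", "cancer", "status"), "DE results")
  if (anyDuplicated(de[, c("gene", "cancer")])) {
    dup <- de[duplicated(de[, c("gene", "cancer")]), c("gene", "cancer")]
    stop("conflicting duplicate DE entries, e.g. ",
         dup$gene[1], " / ", dup$cancer[1], call. = FALSE)
  }
  genes <- sort(unique(de$gene))
  cancers <- sort(unique(de$cancer))
  status <- matrix("normal", length(genes), length(cancers),
                   dimnames = list(genes, cancers))
  status[cbind(match(de$gene, genes), match(de$cancer, cancers))] <- de$status
  obj <- list(status = status,
              n_dysregulated = rowSums(status != "normal"),
              n_up = rowSums(status == "up"),
              n_down = rowSums(status == "down"))
  class(obj) <- "sl_dysreg"
  obj
}

#' @export
print.sl_dysreg <- function(x, ...) {
  cat(sprintf("dysregulation matrix: %d genes x %d cancers; %d genes dysregulated somewhere\n",
              nrow(x$status), ncol(x$status), sum(x$n_dysregulated > 0)))
  invisible(x)
}

#' Select genes dysregulated in many cancer types
#'
#' @param matrix an `sl_dysreg` object.
#' @param min_cancers minimum number of dysregulated cancers
#'   (default 11, the strict reading of "more than 10").
#' @return sorted character vector of gene symbols.
#' @export
select_dysregulated_genes <- function(matrix, min_cancers = 11L) {
  sort(names(matrix$n_dysregulated)[matrix$n_dysregulated >= min_cancers])
}

#' Select catalog pairs whose BOTH members are recurrently dysregulated
#'
#' @param catalog catalog data.frame.
#' @param selected_genes genes from [select_dysregulated_genes()].
#' @return subset of `catalog`.
#' @export
select_dysregulated_pairs <- function(catalog, selected_genes) {
  keep <- catalog$gene_a %in% selected_genes &
    catalog$gene_b %in% selected_genes
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample per-gene abnormal-expression flags
#'
#' A sample's expression of a gene is abnormal when its
#' `log2(normalized + 1)` value deviates from the normal-sample mean by
#' more than `z_cut` normal-sample standard deviations. Genes with zero
#' variance among normals are never abnormal. This per-patient rule is a
#' documented stand-in (see the vignette): the AA/AN/NN grouping needs a
#' per-sample call that the screening thresholds themselves do not define.
#'
#' @param counts gene x sample count matrix.
#' @param normal_samples character vector of normal-sample column names
#'   (or logical/integer column index).
#' @param z_cut z-score threshold (default 1.96).
#' @return logical gene x sample matrix of abnormality flags.
#' @export
sample_abnormality <- function(counts, normal_samples, z_cut = 1.96) {
  counts <- as.matrix(counts)
  if (is.character(normal_samples)) normal_samples <- match(normal_samples, colnames(counts))
  if (is.logical(normal_samples)) normal_samples <- which(normal_samples)
  if (length(normal_samples) < 3L)
    stop("need at least 3 normal samples to estimate the reference ",
         "distribution", call. = FALSE)
  x <- log2(sweep(counts, 2, size_factors(counts), "/") + 1)
  mu <- rowMeans(x[, normal_samples, drop = FALSE])
  sdv <- apply(x[, normal_samples, drop = FALSE], 1, stats::sd)
  z <- abs(x - mu) / ifelse(sdv > 0, sdv, Inf)
  z > z_cut
}

#' Assign AA/AN/NN expression groups for one pair
#'
#' AA: both genes abnormally expressed in the sample; NN: neither;
#' AN: exactly one. Exact analogue of the MM/MW/WW mutation grouping.
#'
#' @param pair list with gene_a, gene_b.
#' @param abnormal_flags logical gene x sample matrix from
#'   [sample_abnormality()].
#' @param cancer optional cancer code copied into the result.
#' @return data.frame sample, group, pair, cancer.
#' @export
assign_expression_groups <- function(pair, abnormal_flags, cancer = NA_character_) {
  for (g in c(pair$gene_a, pair$gene_b))
    if (!g %in% rownames(abnormal_flags))
      stop("no abnormality flags for gene ", g, call. = FALSE)
  fa <- abnormal_flags[pair$gene_a, ]
  fb <- abnormal_flags[pair$gene_b, ]
  group <- ifelse(fa & fb, "AA", ifelse(fa | fb, "AN", "NN"))
  data.frame(sample = colnames(abnormal_flags), group = group,
             pair = pair_key(pair$gene_a, pair$gene_b), cancer = cancer,
             stringsAsFactors = FALSE)
}

#' Up/down z-score of a gene set
#'
#' `(up - down) / count`: the balance of up- vs down-regulated genes in a
#' set of `count` genes, in [-1, 1].
#'
#' @param up number of up-regulated genes.
#' @param down number of down-regulated genes.
#' @param count total number of genes in the set.
#' @return numeric scalar in [-1, 1].
#' @export
go_zscore <- function(up, down, count) {
  if (count <= 0) stop("count must be positive", call. = FALSE)
  if (up < 0 || down < 0 || up + down > count)
    stop("need up, down >= 0 and up + down <= count", call. = FALSE)
  (up - down) / count
}

#' Direction consistency of a dysregulated gene
#'
#' Descriptive summary (not a filter): the fraction of a gene's
#' dysregulated cancers sharing the majority sign.
#'
#' @param matrix an `sl_dysreg` object.
#' @return named numeric vector per gene (NA for genes never dysregulated).
#' @export
direction_consistency <- function(matrix) {
  up <- matrix$n_up; down <- matrix$n_down
  tot <- up + down
  ifelse(tot > 0, pmax(up, down) / tot, NA_real_)
}
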