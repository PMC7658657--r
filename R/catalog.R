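# Catalog construction: yeast-derived SL pairs, ortholog transfer, merge
# with human databases, degree statistics, and gene-characteristic
# annotation.
#
# A catalog is a data.frame with one row per unordered gene pair:
#   gene_a, gene_b   canonical order (gene_a < gene_b lexicographically)
#   sources          semicolon-joined subset of
#                    {yeast_predicted, human_predicted, human_validated}
#   yeast_score      genetic-interaction score (NA unless yeast-derived)
#   orig_a, orig_b   the pair in its original source order, kept as
#                    metadata for positional analysis downstream

CHARACTERISTIC_NAMES <- c("hallmark", "cgc", "essential", "oncogene",
                          "tsg", "actionable", "drug_target")

#' Load yeast genetic-interaction pairs passing the SL score screen
#'
#' Strongly negative genetic-interaction scores mark synthetic-lethal or
#' synthetic-sick pairs; only rows with `score <= score_threshold` are
#' retained. Self-pairs are dropped and unordered duplicates collapse to
#' the most negative (strongest) score.
#'
#' @param path TSV with columns gene_a, gene_b, score.
#' @param score_threshold retain scores at or below this value
#'   (default -0.35).
#' @return data.frame with columns gene_a, gene_b (canonical order), score.
#' @export
load_yeast_pairs <- function(path, score_threshold = -0.35) {
  tab <- read_tsv_file(path)
  stop_cols(tab, c("gene_a", "gene_b", "score"), "yeast pair table")
  score <- suppressWarnings(as.numeric(tab$score))
  bad <- which(is.na(score) | is.na(tab$gene_a) | is.na(tab$gene_b) |
                 tab$gene_a == "" | tab$gene_b == "")
  if (length(bad))
    stop(sprintf("malformed yeast pair row(s) at data line %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  keep <- score <= score_threshold & tab$gene_a != tab$gene_b
  a <- as.character(tab$gene_a[keep]); b <- as.character(tab$gene_b[keep])
  s <- score[keep]
  ord <- canonical_order(a, b)
  key <- paste(ord$a, ord$b, sep = "|")
  # collapse duplicates keeping the minimum (most negative) score
  min_s <- tapply(s, key, min)
  first <- !duplicated(key)
  out <- data.frame(gene_a = ord$a[first], gene_b = ord$b[first],
                    score = as.numeric(min_s[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Transfer yeast pairs to human candidates through an ortholog map
#'
#' Each yeast pair expands to the Cartesian product of the human orthologs
#' of its two members; pairs with an unmapped member are dropped (counted),
#' as are pairs that collapse onto a single human gene. Every transferred
#' pair inherits the yeast score.
#'
#' @param yeast_pairs data.frame from [load_yeast_pairs()].
#' @param ortholog_map named list: yeast gene -> character vector of human
#'   genes, or a data.frame with columns yeast_gene, human_gene.
#' @return data.frame with columns gene_a, gene_b (canonical), sources
#'   ("yeast_predicted"), yeast_score, orig_a, orig_b; attribute
#'   `dropped` = list(unmapped = n, self = n).
#' @export
map_orthologs <- function(yeast_pairs, ortholog_map) {
  if (is.data.frame(ortholog_map)) {
    stop_cols(ortholog_map, c("yeast_gene", "human_gene"), "ortholog map")
    ortholog_map <- split(as.character(ortholog_map$human_gene),
                          as.character(ortholog_map$yeast_gene))
  }
  unmapped <- 0L; selfpairs <- 0L
  rows <- vector("list", nrow(yeast_pairs))
  for (i in seq_len(nrow(yeast_pairs))) {
    ha <- ortholog_map[[yeast_pairs$gene_a[i]]]
    hb <- ortholog_map[[yeast_pairs$gene_b[i]]]
    if (is.null(ha) || is.null(hb) || !length(ha) || !length(hb)) {
      unmapped <- unmapped + 1L
      next
    }
    grid <- expand.grid(orig_a = ha, orig_b = hb,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    self <- grid$orig_a == grid$orig_b
    selfpairs <- selfpairs + sum(self)
    grid <- grid[!self, , drop = FALSE]
    if (nrow(grid)) {
      grid$yeast_score <- yeast_pairs$score[i]
      rows[[i]] <- grid
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(orig_a = character(), orig_b = character(),
                      yeast_score = numeric(), stringsAsFactors = FALSE)
  ord <- canonical_order(out$orig_a, out$orig_b)
  out$gene_a <- ord$a; out$gene_b <- ord$b
  key <- paste(out$gene_a, out$gene_b, sep = "|")
  min_s <- tapply(out$yeast_score, key, min)
  first <- !duplicated(key)
  res <- data.frame(gene_a = out$gene_a[first], gene_b = out$gene_b[first],
                    sources = rep("yeast_predicted", sum(first)),
                    yeast_score = as.numeric(min_s[key[first]]),
                    orig_a = out$orig_a[first], orig_b = out$orig_b[first],
                    stringsAsFactors = FALSE)
  res <- res[order(res$gene_a, res$gene_b), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped") <- list(unmapped = unmapped, self = selfpairs)
  res
}

# Normalise a human pair table (gene_a, gene_b, source) to catalog columns.
as_catalog <- function(pairs) {
  stop_cols(pairs, c("gene_a", "gene_b"), "pair table")
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  if (is.null(pairs$sources))
    pairs$sources <- pairs$source %||% "human_predicted"
  if (is.null(pairs$yeast_score)) pairs$yeast_score <- NA_real_
  if (is.null(pairs$orig_a)) { pairs$orig_a <- pairs$gene_a; pairs$orig_b <- pairs$gene_b }
  keep <- pairs$gene_a != pairs$gene_b
  pairs <- pairs[keep, , drop = FALSE]
  ord <- canonical_order(pairs$gene_a, pairs$gene_b)
  pairs$gene_a <- ord$a; pairs$gene_b <- ord$b
  pairs[, c("gene_a", "gene_b", "sources", "yeast_score", "orig_a", "orig_b"),
        drop = FALSE]
}

#' Merge yeast-derived and human SL pairs into one catalog
#'
#' Unordered-pair union; a pair present in both inputs gets the union of
#' source labels and keeps its yeast score. The summary partitions genes
#' into yeast-only / human-only / common.
#'
#' @param yeast_derived data.frame from [map_orthologs()] (may be empty).
#' @param human_db data.frame with columns gene_a, gene_b and source (one
#'   of human_predicted, human_validated), or already catalog-shaped.
#' @return catalog data.frame; attribute `summary` = list(n_pairs, n_genes,
#'   genes_common, genes_yeast_only, genes_human_only).
#' @export
merge_catalog <- function(yeast_derived, human_db) {
  y <- if (nrow(yeast_derived)) as_catalog(yeast_derived) else yeast_derived
  h <- as_catalog(human_db)
  all <- rbind(if (nrow(yeast_derived)) y else NULL, h)
  if (is.null(all)) all <- h
  key <- paste(all$gene_a, all$gene_b, sep = "|")
  merged <- lapply(split(seq_len(nrow(all)), key), function(idx) {
    src <- sort(unique(unlist(strsplit(all$sources[idx], ";", fixed = TRUE))))
    sc <- all$yeast_score[idx]
    sc <- if (all(is.na(sc))) NA_real_ else min(sc, na.rm = TRUE)
    data.frame(gene_a = all$gene_a[idx[1]], gene_b = all$gene_b[idx[1]],
               sources = paste(src, collapse = ";"), yeast_score = sc,
               orig_a = all$orig_a[idx[1]], orig_b = all$orig_b[idx[1]],
               stringsAsFactors = FALSE)
  })
  cat <- do.call(rbind, merged)
  cat <- cat[order(cat$gene_a, cat$gene_b), , drop = FALSE]
  rownames(cat) <- NULL
  yg <- unique(c(y$gene_a, y$gene_b))
  hg <- unique(c(h$gene_a, h$gene_b))
  attr(cat, "summary") <- list(
    n_pairs = nrow(cat),
    n_genes = length(unique(c(cat$gene_a, cat$gene_b))),
    genes_common = sort(intersect(yg, hg)),
    genes_yeast_only = sort(setdiff(yg, hg)),
    genes_human_only = sort(setdiff(hg, yg)))
  cat
}

#' Interaction-degree distribution of a catalog
#'
#' Degree of a gene = number of distinct SL partners. Degrees are binned
#' as {1}, {2-10}, {11-50}, {>50}; bin fractions are over all genes.
#'
#' @param catalog catalog data.frame (gene_a, gene_b).
#' @return list with `degree` (named integer vector) and `bins`
#'   (data.frame bin, n_genes, fraction).
#' @export
degree_distribution <- function(catalog) {
  if (!nrow(catalog)) stop("catalog is empty", call. = FALSE)
  uniq <- !duplicated(pair_key(catalog$gene_a, catalog$gene_b))
  ends <- c(catalog$gene_a[uniq], catalog$gene_b[uniq])
  tab <- table(ends)
  genes <- sort(unique(c(catalog$gene_a, catalog$gene_b)))
  deg <- stats::setNames(as.integer(tab[genes]), genes)
  bins <- cut(deg, breaks = c(0, 1, 10, 50, Inf),
              labels = c("1", "2-10", "11-50", ">50"))
  tab <- table(bins)
  list(degree = deg,
       bins = data.frame(bin = names(tab), n_genes = as.integer(tab),
                         fraction = as.numeric(tab) / length(deg),
                         stringsAsFactors = FALSE))
}

#' Annotate genes with cancer-relevant characteristics
#'
#' The seven binary characteristics (hallmarks of cancer, Cancer Gene
#' Census membership, core essentiality, oncogene, tumor suppressor,
#' actionable, drug target) come in as named gene sets.
#'
#' @param genes character vector of gene symbols.
#' @param characteristic_sets named list of gene sets; names must be
#'   exactly `r paste(CHARACTERISTIC_NAMES, collapse = ", ")`.
#' @return data.frame with columns gene, one logical column per
#'   characteristic, and n_characteristics; attribute `coverage` gives the
#'   per-characteristic fraction of input genes covered.
#' @export
annotate_genes <- function(genes, characteristic_sets) {
  unknown <- setdiff(names(characteristic_sets), CHARACTERISTIC_NAMES)
  if (length(unknown))
    stop("unknown characteristic set name(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(CHARACTERISTIC_NAMES, names(characteristic_sets))
  if (length(missing))
    stop("missing characteristic set(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  flags <- vapply(CHARACTERISTIC_NAMES, function(nm)
    genes %in% characteristic_sets[[nm]], logical(length(genes)))
  flags <- matrix(flags, nrow = length(genes),
                  dimnames = list(NULL, CHARACTERISTIC_NAMES))
  out <- data.frame(gene = genes, flags,
                    n_characteristics = as.integer(rowSums(flags)),
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- colMeans(flags)
  out
}

#' Select core genes with at least `min_characteristics` characteristics
#'
#' @param annotations data.frame from [annotate_genes()].
#' @param min_characteristics minimum number of characteristics (default 4).
#' @return character vector of genes sorted by decreasing characteristic
#'   count, ties by symbol.
#' @export
select_core_genes <- function(annotations, min_characteristics = 4L) {
  keep <- annotations$n_characteristics >= min_characteristics
  sel <- annotations[keep, , drop = FALSE]
  sel$gene[order(-sel$n_characteristics, sel$gene)]
}
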