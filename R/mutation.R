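# Mutation-level screening: per-cancer mutation frequencies, the
# recurrently-mutated pair screen, MM/MW/WW patient grouping, variant-class
# composition, and drug-response association.
#
# Mutation calls are MAF-subset tables: one row per call with columns
# sample, gene, cancer, variant_class (missense, nonsense, frameshift,
# splice, other). Repeated (sample, gene) calls are legal and deduplicated
# wherever frequency is counted.

VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "splice", "other")

#' Per-gene per-cancer mutation frequency
#'
#' Frequency = number of distinct mutated samples / cohort size. Cohort
#' sizes are passed explicitly (full per-cancer cohort, not the number of
#' samples appearing in the call file) to avoid silent undercounting.
#'
#' @param calls data.frame with columns sample, gene, cancer.
#' @param cohort_sizes named integer vector, cancer code -> cohort size.
#' @return data.frame gene, cancer, n_mutated, frequency; attribute
#'   `matrix` holds the gene x cancer frequency matrix used by the screens.
#' @export
mutation_frequency <- function(calls, cohort_sizes) {
  stop_cols(calls, c("sample", "gene", "cancer"), "mutation calls")
  if (any(cohort_sizes <= 0)) stop("cohort sizes must be positive", call. = FALSE)
  unknown <- setdiff(unique(calls$cancer), names(cohort_sizes))
  if (length(unknown))
    stop("calls reference cancer type(s) with no cohort size: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  dedup <- unique(calls[, c("sample", "gene", "cancer")])
  counts <- table(dedup$gene, dedup$cancer)
  genes <- rownames(counts)
  cancers <- names(cohort_sizes)
  m <- matrix(0, length(genes), length(cancers),
              dimnames = list(genes, cancers))
  if (length(counts)) m[, colnames(counts)] <- unclass(counts)
  freq <- sweep(m, 2, as.numeric(cohort_sizes[cancers]), "/")
  long <- data.frame(gene = rep(genes, times = length(cancers)),
                     cancer = rep(cancers, each = length(genes)),
                     n_mutated = as.integer(m), frequency = as.numeric(freq),
                     stringsAsFactors = FALSE)
  long <- long[long$n_mutated > 0, , drop = FALSE]
  rownames(long) <- NULL
  attr(long, "matrix") <- freq
  long
}

# Extract the gene x cancer frequency matrix from mutation_frequency()
# output (or accept a matrix directly).
freq_matrix <- function(freqs) {
  if (is.matrix(freqs)) return(freqs)
  m <- attr(freqs, "matrix")
  if (is.null(m)) stop("frequency table lacks its matrix attribute; ",
                       "pass the output of mutation_frequency()", call. = FALSE)
  m
}

#' Screen catalog pairs for recurrent mutation of both genes
#'
#' A pair qualifies when the set of cancers in which BOTH genes exceed
#' `min_freq` mutation frequency has at least `min_cancers` members.
#'
#' @param catalog catalog data.frame.
#' @param freqs output of [mutation_frequency()] (or a gene x cancer
#'   frequency matrix).
#' @param min_freq per-cancer frequency that must be exceeded
#'   (default 0.02, i.e. strictly more than 2% of samples).
#' @param min_cancers minimum number of qualifying cancers (default 5).
#' @return subset of `catalog` with an added `qualifying_cancers` column
#'   (semicolon-joined) and `n_qualifying` integer column.
#' @export
select_mutated_pairs <- function(catalog, freqs, min_freq = 0.02,
                                 min_cancers = 5L) {
  m <- freq_matrix(freqs)
  get_row <- function(g) if (g %in% rownames(m)) m[g, ] else
    stats::setNames(numeric(ncol(m)), colnames(m))
  qual <- lapply(seq_len(nrow(catalog)), function(i) {
    both <- get_row(catalog$gene_a[i]) > min_freq &
      get_row(catalog$gene_b[i]) > min_freq
    colnames(m)[both]
  })
  n_q <- lengths(qual)
  keep <- n_q >= min_cancers
  out <- catalog[keep, , drop = FALSE]
  out$qualifying_cancers <- vapply(qual[keep], paste, character(1),
                                   collapse = ";")
  out$n_qualifying <- n_q[keep]
  rownames(out) <- NULL
  out
}

#' Assign MM/MW/WW groups for one pair in one cancer cohort
#'
#' MM: both genes mutated in the sample; WW: neither; MW: exactly one.
#' The partition is exhaustive and exclusive over the cohort.
#'
#' @param pair list or one-row data.frame with gene_a, gene_b.
#' @param calls mutation call table.
#' @param cancer cancer-type code.
#' @param cohort character vector of all sample barcodes of that cohort.
#' @return data.frame sample, group, pair, cancer.
#' @export
assign_mutation_groups <- function(pair, calls, cancer, cohort) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  sub <- calls[calls$cancer == cancer, , drop = FALSE]
  mut_a <- cohort %in% sub$sample[sub$gene == pair$gene_a]
  mut_b <- cohort %in% sub$sample[sub$gene == pair$gene_b]
  group <- ifelse(mut_a & mut_b, "MM", ifelse(mut_a | mut_b, "MW", "WW"))
  data.frame(sample = cohort, group = group,
             pair = pair_key(pair$gene_a, pair$gene_b), cancer = cancer,
             stringsAsFactors = FALSE)
}

#' Variant-class composition of the calls touching a pair
#'
#' @param pair list with gene_a, gene_b.
#' @param calls mutation call table with variant_class.
#' @return named numeric proportion vector over
#'   missense, nonsense, frameshift, splice, other (sums to 1).
#' @export
mutation_type_composition <- function(pair, calls) {
  sub <- calls[calls$gene %in% c(pair$gene_a, pair$gene_b), , drop = FALSE]
  if (!nrow(sub)) stop("pair has no mutation calls", call. = FALSE)
  tab <- table(factor(sub$variant_class, levels = VARIANT_CLASSES))
  stats::setNames(as.numeric(tab) / nrow(sub), VARIANT_CLASSES)
}

#' Drug-response association between two patient groups
#'
#' For each drug, the effect is the difference of mean normalized response
#' between the two groups (responses on a min-max-normalized [0, 1] scale);
#' the p-value is a two-sided Mann-Whitney test. A drug is flagged
#' significant when `|effect| > effect_cut`, `p < alpha`, and its BH FDR
#' across the drugs tested for this contrast is below `fdr_cut`. Drugs for
#' which either group has fewer than 3 responding samples are skipped and
#' listed in the `skipped` attribute.
#'
#' @param groups data.frame from [assign_mutation_groups()] or
#'   [assign_expression_groups()].
#' @param drug_matrix sample x drug numeric matrix (rownames = samples),
#'   values in [0, 1]; NA = not measured.
#' @param group_pair length-2 character, e.g. c("MM", "WW"): the contrast
#'   group1 minus group2.
#' @param effect_cut minimum absolute effect (default 0.10).
#' @param alpha per-test p cut (default 0.05).
#' @param fdr_cut BH FDR cut across drugs (default 0.10).
#' @return data.frame drug, n1, n2, effect, pvalue, fdr, significant;
#'   attribute `skipped` = data.frame(drug, reason).
#' @export
drug_association <- function(groups, drug_matrix, group_pair = c("MM", "WW"),
                             effect_cut = 0.10, alpha = 0.05, fdr_cut = 0.10) {
  stopifnot(length(group_pair) == 2L)
  s1 <- groups$sample[groups$group == group_pair[1]]
  s2 <- groups$sample[groups$group == group_pair[2]]
  res <- list(); skipped <- list()
  for (drug in colnames(drug_matrix)) {
    r1 <- drug_matrix[intersect(s1, rownames(drug_matrix)), drug]
    r2 <- drug_matrix[intersect(s2, rownames(drug_matrix)), drug]
    r1 <- r1[!is.na(r1)]; r2 <- r2[!is.na(r2)]
    if (length(r1) < 3L || length(r2) < 3L) {
      skipped[[drug]] <- data.frame(drug = drug,
                                    reason = "group below minimum size (3)",
                                    stringsAsFactors = FALSE)
      next
    }
    p <- suppressWarnings(stats::wilcox.test(r1, r2, exact = FALSE)$p.value)
    res[[drug]] <- data.frame(drug = drug, n1 = length(r1), n2 = length(r2),
                              effect = mean(r1) - mean(r2), pvalue = p,
                              stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(drug = character(), n1 = integer(), n2 = integer(),
               effect = numeric(), pvalue = numeric())
  if (nrow(out)) {
    out$fdr <- bh_adjust(out$pvalue)
    out$significant <- abs(out$effect) > effect_cut & out$pvalue < alpha &
      out$fdr < fdr_cut
  } else {
    out$fdr <- numeric(); out$significant <- logical()
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}
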