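# Combined mutation + expression screen: pairs with one recurrently
# mutated gene whose SL partner is recurrently up-regulated, plus
# positional and high-mutation summaries.
#
# Orientation matters here: a pair can qualify with either member as the
# mutated gene, and both orientations are emitted as separate records.
# `mutated_position` refers to the pair's original source order (orig_a /
# orig_b catalog metadata), which the canonical storage order preserves.
# By construction the mutated gene's own expression is never filtered.

#' Select combined mutation/up-regulation candidate pairs
#'
#' A (mutated_gene, partner_gene) orientation of a catalog pair qualifies
#' when the mutated gene's frequency exceeds `min_freq` in at least
#' `min_mut_cancers` cancers and the partner has status `up` in at least
#' `min_up_cancers` cancers. Down-regulated partners do not qualify; the
#' mutated gene's own expression is not considered.
#'
#' @param catalog catalog data.frame (with orig_a/orig_b metadata).
#' @param freqs [mutation_frequency()] output or frequency matrix.
#' @param matrix an `sl_dysreg` object.
#' @param min_freq mutation frequency to exceed (default 0.02).
#' @param min_mut_cancers minimum qualifying mutation cancers (default 5).
#' @param min_up_cancers minimum up-regulated cancers (default 11).
#' @return data.frame with one row per qualifying orientation: gene_a,
#'   gene_b, mutated_gene, partner_gene, mutated_position (first/second),
#'   n_mut_cancers, n_up_cancers, qualifying_mut_cancers,
#'   qualifying_up_cancers (semicolon-joined).
#' @export
select_combined_pairs <- function(catalog, freqs, matrix, min_freq = 0.02,
                                  min_mut_cancers = 5L, min_up_cancers = 11L) {
  fm <- freq_matrix(freqs)
  status <- matrix$status
  mut_cancers <- function(g) {
    if (!g %in% rownames(fm)) return(character(0))
    colnames(fm)[fm[g, ] > min_freq]
  }
  up_cancers <- function(g) {
    if (!g %in% rownames(status)) return(character(0))
    colnames(status)[status[g, ] == "up"]
  }
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    orig <- c(catalog$orig_a[i] %||% catalog$gene_a[i],
              catalog$orig_b[i] %||% catalog$gene_b[i])
    for (k in 1:2) {
      mg <- orig[k]; pg <- orig[3 - k]
      mc <- mut_cancers(mg); uc <- up_cancers(pg)
      if (length(mc) >= min_mut_cancers && length(uc) >= min_up_cancers) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = catalog$gene_a[i], gene_b = catalog$gene_b[i],
          mutated_gene = mg, partner_gene = pg,
          mutated_position = c("first", "second")[k],
          n_mut_cancers = length(mc), n_up_cancers = length(uc),
          qualifying_mut_cancers = paste(sort(mc), collapse = ";"),
          qualifying_up_cancers = paste(sort(uc), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(),
               mutated_gene = character(), partner_gene = character(),
               mutated_position = character(), n_mut_cancers = integer(),
               n_up_cancers = integer(), qualifying_mut_cancers = character(),
               qualifying_up_cancers = character(), stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, out$mutated_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positional summary of combined pairs
#'
#' Counts qualifying orientations by the mutated gene's position in the
#' original source order, and the partners' expression-direction fractions
#' (share of `up` statuses across each partner's full per-cancer profile).
#'
#' @param pairs data.frame from [select_combined_pairs()].
#' @param matrix an `sl_dysreg` object (for partner direction fractions);
#'   optional.
#' @return list(position_counts = named integer vector,
#'   partner_up_fraction = named numeric per position, n_records).
#' @export
positional_summary <- function(pairs, matrix = NULL) {
  pos <- factor(pairs$mutated_position, levels = c("first", "second"))
  counts <- table(pos)
  upfrac <- c(first = NA_real_, second = NA_real_)
  if (!is.null(matrix) && nrow(pairs)) {
    status <- matrix$status
    for (p in c("first", "second")) {
      partners <- pairs$partner_gene[pairs$mutated_position == p]
      partners <- partners[partners %in% rownames(status)]
      if (length(partners)) {
        st <- status[partners, , drop = FALSE]
        upfrac[p] <- sum(st == "up") / length(st)
      }
    }
  }
  list(position_counts = stats::setNames(as.integer(counts), names(counts)),
       partner_up_fraction = upfrac,
       n_records = nrow(pairs))
}

#' High-mutation subset of combined pairs
#'
#' Pairs whose mutated gene exceeds `high_freq` mutation frequency in at
#' least one cancer type.
#'
#' @param pairs data.frame from [select_combined_pairs()].
#' @param freqs [mutation_frequency()] output or frequency matrix.
#' @param high_freq frequency to exceed in >= 1 cancer (default 0.03).
#' @return subset of `pairs` (same columns).
#' @export
high_mutation_subset <- function(pairs, freqs, high_freq = 0.03) {
  fm <- freq_matrix(freqs)
  keep <- vapply(pairs$mutated_gene, function(g) {
    g %in% rownames(fm) && max(fm[g, ]) > high_freq
  }, logical(1))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
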