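# Differential-expression engine: median-of-ratios normalisation, a
# vectorised Welch t-test on the log scale, and Benjamini-Hochberg
# adjustment. The screens downstream consume only (baseMean, log2FC,
# padj, direction), so this deliberately simple estimator stands in for a
# full negative-binomial GLM; the trade-off is documented in the package
# vignette.

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed against a geometric-mean pseudo
#' reference over genes with all-positive counts, the standard
#' normalisation for sequencing depth in count data.
#'
#' @param counts numeric gene x sample matrix of nonnegative counts.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) return(stats::setNames(1, colnames(counts)))
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has positive counts in every sample; cannot form the ",
         "geometric reference (consider a pseudo-reference fallback)",
         call. = FALSE)
  lc <- log(counts[ref, , drop = FALSE])
  logratio <- lc - rowMeans(lc)
  sf <- exp(apply(logratio, 2, stats::median))
  stats::setNames(sf, colnames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; output order
#' matches input order.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

# Row-wise Welch t-test on a matrix, comparing columns in g1 vs g2.
# Returns list(diff, p). Degenerate rows (zero variance in both groups):
# p = 1 if the means agree, 0 otherwise.
row_welch <- function(x, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE]); m2 <- rowMeans(x[, g2, drop = FALSE])
  v1 <- rowSums((x[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((x[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  p[degen] <- ifelse(abs(m1[degen] - m2[degen]) < .Machine$double.eps^0.5, 1, 0)
  list(diff = m1 - m2, p = p)
}

#' Tumor vs normal differential expression for one cancer type
#'
#' Counts are normalised by [size_factors()]; the fold change is
#' `log2((mean normalized tumor + 1) / (mean normalized normal + 1))`
#' (pseudo-count 1 for stability at zero); the p-value is a two-sided
#' Welch t-test on `log2(normalized + 1)`; padj is Benjamini-Hochberg over
#' the genes of this cancer type. Status is `up` when
#' `log2FC > fc_cut & padj < alpha`, `down` for the mirror condition,
#' else `normal`.
#'
#' @param counts gene x sample count matrix (rownames = genes).
#' @param labels character vector per column, "tumor" or "normal".
#' @param fc_cut absolute log2 fold-change cut for calling status
#'   (default 1.5).
#' @param alpha adjusted-p cut (default 0.05).
#' @param cancer optional cancer-type code copied into the result.
#' @return data.frame: gene, cancer, baseMean, log2FC, pvalue, padj, status.
#' @export
de_test <- function(counts, labels, fc_cut = 1.5, alpha = 0.05,
                    cancer = NA_character_) {
  counts <- as.matrix(counts)
  if (!all(labels %in% c("tumor", "normal")))
    stop("labels must be 'tumor' or 'normal'", call. = FALSE)
  tum <- which(labels == "tumor"); nor <- which(labels == "normal")
  if (length(tum) < 2L || length(nor) < 2L)
    stop("need at least 2 tumor and 2 normal samples; refusing ",
         "single-sample inference", call. = FALSE)
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  mt <- rowMeans(norm[, tum, drop = FALSE])
  mn <- rowMeans(norm[, nor, drop = FALSE])
  log2fc <- log2((mt + 1) / (mn + 1))
  wt <- row_welch(log2(norm + 1), tum, nor)
  padj <- bh_adjust(wt$p)
  status <- rep("normal", nrow(counts))
  status[log2fc > fc_cut & padj < alpha] <- "up"
  status[log2fc < -fc_cut & padj < alpha] <- "down"
  data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             cancer = cancer,
             baseMean = rowMeans(norm),
             log2FC = log2fc, pvalue = wt$p, padj = padj, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}
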