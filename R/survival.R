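# Survival analysis and the randomization empirical null.
#
# Kaplan-Meier estimation and the k-sample log-rank test are delegated to
# the survival package (survfit/survdiff) behind this module's interface;
# the prognostic scan over pairs and the randomization test against
# random non-SL pair sets are implemented here.

GROUP_SCHEMES <- list(mutation = c("MM", "MW", "WW"),
                      expression = c("AA", "AN", "NN"))

# Levels of the grouping scheme present in a label vector, in extreme-to-
# extreme order (MM..WW or AA..NN).
scheme_levels <- function(labels) {
  for (lv in GROUP_SCHEMES) if (any(labels %in% lv)) return(lv)
  sort(unique(labels))
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator for each group of a survival record table.
#'
#' @param records data.frame with columns time (> 0), event (0/1), group.
#' @return data.frame group, time, n_risk, n_event, surv (step function
#'   values at event times; S(0) = 1 implied).
#' @export
km_estimate <- function(records) {
  stop_cols(records, c("time", "event", "group"), "survival records")
  if (any(records$time <= 0)) stop("times must be strictly positive", call. = FALSE)
  if (any(table(records$group) < 1L)) stop("empty group", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = records)
  strata <- if (is.null(fit$strata)) stats::setNames(length(fit$time),
                                                     unique(records$group))
            else fit$strata
  grp <- rep(sub("^group=", "", names(strata)), strata)
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv,
             stringsAsFactors = FALSE)
}

# Core k-sample log-rank computation on bare vectors. group is an integer
# vector in 1..k. Returns c(statistic, df). Direct O-E / covariance
# summation over distinct event times; equals survival::survdiff's
# chi-square (verified against it in the test suite), but cheap enough to
# sit inside the randomization loop.
logrank_stat <- function(time, event, group, k) {
  ut <- sort(unique(time[event == 1]))
  J <- length(ut)
  if (!J) return(c(statistic = 0, df = k - 1))
  # at-risk counts per group at each event time
  nrisk <- matrix(0, J, k)
  devent <- matrix(0, J, k)
  for (g in seq_len(k)) {
    tg <- sort(time[group == g])
    nrisk[, g] <- length(tg) - findInterval(ut, tg, left.open = TRUE)
    te <- time[group == g & event == 1]
    if (length(te)) {
      idx <- match(te, ut)
      devent[, g] <- tabulate(idx, nbins = J)
    }
  }
  nj <- rowSums(nrisk)
  dj <- rowSums(devent)
  E <- devent
  U <- numeric(k)
  V <- matrix(0, k, k)
  pj <- nrisk / nj
  U <- colSums(devent - dj * pj)
  mult <- ifelse(nj > 1, dj * (nj - dj) / (nj - 1), 0)
  for (g in seq_len(k)) {
    for (h in g:k) {
      vgh <- sum(mult * pj[, g] * ((g == h) - pj[, h]))
      V[g, h] <- vgh; V[h, g] <- vgh
    }
  }
  u <- U[-k]; vv <- V[-k, -k, drop = FALSE]
  if (k == 2L) {
    stat <- if (vv[1, 1] > 0) u[1]^2 / vv[1, 1] else 0
    return(c(statistic = stat, df = 1))
  }
  # generalized inverse for safety against degenerate strata
  sv <- svd(vv)
  pos <- sv$d > max(sv$d) * 1e-10
  if (!any(pos)) return(c(statistic = 0, df = k - 1))
  vinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  stat <- as.numeric(t(u) %*% vinv %*% u)
  c(statistic = stat, df = k - 1)
}

#' k-sample log-rank test
#'
#' Standard log-rank chi-square on 2 or 3 groups with k-1 degrees of
#' freedom, computed by direct summation of observed-minus-expected event
#' counts over distinct event times. Groups with no at-risk observation
#' are excluded with a warning; fewer than two usable groups is an error.
#'
#' @param records data.frame with time, event, group.
#' @param k_groups expected number of groups (2 or 3); checked against the
#'   data.
#' @return list(statistic, df, p, n = per-group sizes).
#' @export
logrank <- function(records, k_groups = 2L) {
  stop_cols(records, c("time", "event", "group"), "survival records")
  tab <- table(records$group)
  usable <- names(tab)[tab > 0]
  if (length(usable) < length(tab))
    warning("dropping group(s) with no at-risk records: ",
            paste(setdiff(names(tab), usable), collapse = ", "))
  records <- records[records$group %in% usable, , drop = FALSE]
  if (length(usable) < 2L) stop("need at least two usable groups", call. = FALSE)
  if (length(usable) != k_groups)
    warning(sprintf("expected %d groups, found %d", k_groups, length(usable)))
  gi <- match(records$group, usable)
  st <- logrank_stat(records$time, records$event, gi, length(usable))
  df <- as.integer(st["df"])
  stat <- as.numeric(st["statistic"])
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       n = tab[usable])
}

#' Prognostic scan over a set of gene pairs
#'
#' For each pair, patients are grouped by the pair's status (via
#' `groupings_builder`), the scheme's groups are compared by log-rank, and
#' the number of pairs significant at `alpha` is counted. The two-group
#' scheme uses only the extreme groups (MM vs WW or AA vs NN); the
#' three-group scheme uses all three. Pairs with any required group below
#' `min_group` are skipped (recorded in the result).
#'
#' @param pairs data.frame with gene_a, gene_b.
#' @param groupings_builder function(gene_a, gene_b) returning a character
#'   vector of group labels named by sample barcode.
#' @param clinical data.frame with sample, time, event.
#' @param scheme "two_group" or "three_group".
#' @param alpha significance level (default 0.05).
#' @param min_group minimum per-arm size (default 5).
#' @return list(per_pair = data.frame(pair, p, tested, reason),
#'   n_significant, n_tested).
#' @export
pair_prognostic_scan <- function(pairs, groupings_builder, clinical,
                                 scheme = c("two_group", "three_group"),
                                 alpha = 0.05, min_group = 5L) {
  scheme <- match.arg(scheme)
  stop_cols(clinical, c("sample", "time", "event"), "clinical table")
  n_pairs <- nrow(pairs)
  out <- data.frame(pair = if (n_pairs) pair_key(pairs$gene_a, pairs$gene_b)
                           else character(0),
                    p = rep(NA_real_, n_pairs), tested = rep(FALSE, n_pairs),
                    reason = rep("", n_pairs), stringsAsFactors = FALSE)
  cs <- clinical$sample
  for (i in seq_len(nrow(pairs))) {
    grp <- groupings_builder(pairs$gene_a[i], pairs$gene_b[i])
    lv <- scheme_levels(grp)
    keep_lv <- if (scheme == "two_group") lv[c(1, length(lv))] else lv
    gi <- match(grp, keep_lv)
    idx <- match(names(grp), cs)
    ok <- !is.na(gi) & !is.na(idx)
    gi <- gi[ok]; idx <- idx[ok]
    sizes <- tabulate(gi, nbins = length(keep_lv))
    if (any(sizes < min_group)) {
      out$reason[i] <- sprintf("group below min size (%s)",
                               paste(sizes, collapse = "/"))
      next
    }
    st <- logrank_stat(clinical$time[idx], clinical$event[idx],
                       gi, length(keep_lv))
    out$p[i] <- stats::pchisq(st["statistic"], st["df"], lower.tail = FALSE)
    out$tested[i] <- TRUE
  }
  list(per_pair = out,
       n_significant = sum(out$tested & out$p < alpha, na.rm = TRUE),
       n_tested = sum(out$tested))
}

#' Empirical p-value from a null distribution
#'
#' Proportion of null statistics at least as large as the observed one.
#' With `plus_one = TRUE`, the conservative (obs-included) variant
#' `(#{null >= obs} + 1) / (B + 1)` is used instead.
#'
#' @param observed numeric scalar.
#' @param null_stats numeric vector of B null draws.
#' @param plus_one logical (default FALSE).
#' @return numeric scalar in [0, 1].
#' @export
empirical_pvalue <- function(observed, null_stats, plus_one = FALSE) {
  B <- length(null_stats)
  if (!B) stop("empty null distribution", call. = FALSE)
  hits <- sum(null_stats >= observed)
  if (plus_one) (hits + 1) / (B + 1) else hits / B
}

# Sample m distinct unordered pairs uniformly from `universe`, avoiding
# the keys in `excluded` (a character set of pair_key()s).
sample_null_pairs <- function(universe, m, excluded) {
  n <- length(universe)
  if (n < 2L || choose(n, 2) - length(excluded) < m)
    stop("gene universe too small to sample ", m,
         " distinct non-excluded pairs", call. = FALSE)
  got <- character(0)
  a <- character(m); b <- character(m)
  k <- 0L
  while (k < m) {
    g <- sample(universe, 2L)
    key <- pair_key(g[1], g[2])
    if (key %in% excluded || key %in% got) next
    k <- k + 1L
    got <- c(got, key)
    a[k] <- min(g); b[k] <- max(g)
  }
  data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
}

#' Randomization test of pair-set prognostic significance
#'
#' Compares the observed prognostic statistic of the SL pair set against
#' B random pair sets of equal size sampled uniformly (without
#' replacement) from the gene universe, excluding the SL catalog itself.
#' The default statistic is the count of pairs significant at `alpha`;
#' `stat = "mean_nlp"` uses the mean -log10(p) over tested pairs
#' (continuous, tie-free alternative).
#'
#' @param observed_pairs data.frame with gene_a, gene_b.
#' @param gene_universe character vector of candidate genes.
#' @param excluded_pairs data.frame with gene_a, gene_b (typically the SL
#'   catalog) never sampled into null sets; may be empty.
#' @param clinical data.frame sample, time, event.
#' @param groupings_builder function(gene_a, gene_b) -> named group labels.
#' @param B number of randomizations (default 1000).
#' @param seed integer seed; fixed seed gives a bit-identical result.
#' @param scheme "two_group" or "three_group".
#' @param alpha per-pair significance level (default 0.05).
#' @param min_group minimum per-arm size (default 5).
#' @param stat "count" (default) or "mean_nlp".
#' @param plus_one passed to [empirical_pvalue()].
#' @return object of class `sl_randomization`: list(observed_stat,
#'   null_stats, empirical_p, B, seed, scheme, stat, n_pairs).
#' @export
randomization_test <- function(observed_pairs, gene_universe, excluded_pairs,
                               clinical, groupings_builder, B = 1000L,
                               seed = 1L, scheme = c("two_group", "three_group"),
                               alpha = 0.05, min_group = 5L,
                               stat = c("count", "mean_nlp"),
                               plus_one = FALSE) {
  scheme <- match.arg(scheme)
  stat <- match.arg(stat)
  m <- nrow(observed_pairs)
  excluded <- unique(pair_key(excluded_pairs$gene_a %||% character(0),
                              excluded_pairs$gene_b %||% character(0)))
  if (length(gene_universe) < 2L ||
      choose(length(gene_universe), 2) - length(excluded) < m)
    stop("gene universe too small for the randomization test", call. = FALSE)
  stat_of <- function(prs) {
    scan <- pair_prognostic_scan(prs, groupings_builder, clinical,
                                 scheme = scheme, alpha = alpha,
                                 min_group = min_group)
    if (stat == "count") scan$n_significant
    else {
      p <- scan$per_pair$p[scan$per_pair$tested]
      if (!length(p)) 0 else mean(-log10(pmax(p, 1e-300)))
    }
  }
  observed_stat <- stat_of(observed_pairs)
  null_stats <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      stat_of(sample_null_pairs(gene_universe, m, excluded))
    }, numeric(1))
  })
  res <- list(observed_stat = observed_stat, null_stats = null_stats,
              empirical_p = empirical_pvalue(observed_stat, null_stats,
                                             plus_one = plus_one),
              B = as.integer(B), seed = as.integer(seed), scheme = scheme,
              stat = stat, n_pairs = m)
  class(res) <- "sl_randomization"
  res
}

#' @export
print.sl_randomization <- function(x, ...) {
  cat(sprintf("randomization test (%s, %s): observed = %.4g, B = %d, empirical p = %.3f\n",
              x$scheme, x$stat, x$observed_stat, x$B, x$empirical_p))
  invisible(x)
}
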