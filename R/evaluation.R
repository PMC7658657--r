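# Simulation studies of the pipeline's operating characteristics:
# end-to-end planted-pair recovery, log-rank calibration, randomization
# self-consistency and power, and DE-engine recovery. These drive both
# the package's acceptance checks and reproducible benchmarking from the
# command line; problem sizes are documented in the methods vignette.

#' Convert a planted truth's SL pairs into a catalog table
#'
#' @param truth an `sl_truth` object.
#' @return catalog data.frame (canonical order, orig_* metadata).
#' @export
truth_catalog <- function(truth) {
  as_catalog(data.frame(gene_a = truth$sl_pairs$gene_a,
                        gene_b = truth$sl_pairs$gene_b,
                        sources = truth$sl_pairs$sources,
                        yeast_score = truth$sl_pairs$yeast_score,
                        stringsAsFactors = FALSE))
}

#' End-to-end recovery of planted combined-screen pairs
#'
#' For each seed: generate a pan-cancer dataset (20 cancers, 500 genes,
#' 10 planted combined pairs with mutation rate 0.10 against a 0.005
#' background and |log2FC| = 2.5 planted in 12 cancers; negative-binomial
#' dispersion 0.1; 60 tumor / 30 normal expression samples and a
#' 150-sample mutation cohort per cancer), run the mutation and
#' expression screens and the combined screen, and compare the recovered
#' pairs with the planted ones.
#'
#' @param seed integer base seed.
#' @param n_seeds number of independent replicate datasets (default 20).
#' @param n_genes,n_cancers,n_samples_mut,n_tumor,n_normal study sizes.
#' @return data.frame with one row per seed: precision, recall,
#'   n_recovered.
#' @export
evaluate_combined_recovery <- function(seed = 1L, n_seeds = 20L,
                                       n_genes = 500L, n_cancers = 20L,
                                       n_samples_mut = 150L, n_tumor = 60L,
                                       n_normal = 30L) {
  cfg <- sl_sim_config(n_genes = n_genes, n_cancers = n_cancers,
                       n_background_pairs = 30L, n_combined_signal = 10L,
                       mut_rate_signal = 0.10, mut_rate_background = 0.005,
                       n_mut_cancers = 6L, de_effect_signal = 2.5,
                       n_de_cancers = 12L)
  out <- lapply(seq_len(n_seeds), function(r) {
    s <- child_seed(seed, paste0("recovery/", r))
    truth <- generate_truth(cfg, s)
    gm <- generate_mutations(truth, n_samples_mut, s)
    freqs <- mutation_frequency(gm$calls,
                                lengths(gm$cohorts)[truth$cancers])
    counts <- generate_counts(truth, n_tumor, n_normal, dispersion = 0.1,
                              seed = s)
    de <- lapply(truth$cancers, function(cc)
      de_test(counts[[cc]]$counts, counts[[cc]]$condition, cancer = cc))
    dys <- build_dysregulation_matrix(de)
    combined <- select_combined_pairs(truth_catalog(truth), freqs, dys)
    got <- unique(pair_key(combined$gene_a, combined$gene_b))
    planted <- pair_key(
      truth$sl_pairs$gene_a[truth$sl_pairs$signal == "combined"],
      truth$sl_pairs$gene_b[truth$sl_pairs$signal == "combined"])
    data.frame(seed = s,
               precision = if (length(got)) mean(got %in% planted) else 1,
               recall = mean(planted %in% got),
               n_recovered = length(got))
  })
  do.call(rbind, out)
}

#' Type-I calibration of the two-group log-rank test
#'
#' Null survival (hazard ratio 1, exponential times, ~30% censoring) with
#' `n_per_arm` patients per arm; reports the empirical rejection rate at
#' alpha = 0.05 and a Kolmogorov-Smirnov uniformity p-value for the
#' p-value distribution.
#'
#' @param seed integer base seed.
#' @param n_reps replicates (default 2000).
#' @param n_per_arm patients per arm (default 100).
#' @return list(reject_rate, ks_p, pvalues).
#' @export
evaluate_logrank_calibration <- function(seed = 1L, n_reps = 2000L,
                                         n_per_arm = 100L) {
  labels <- stats::setNames(rep(c("MM", "WW"), each = n_per_arm),
                            sprintf("s%04d", seq_len(2 * n_per_arm)))
  lambda <- 1 / 500
  censor <- lambda * 3 / 7            # ~30% censored under the null
  p <- vapply(seq_len(n_reps), function(r) {
    cl <- generate_clinical(labels, baseline_hazard = lambda,
                            censor_rate = censor,
                            seed = child_seed(seed, paste0("cal/", r)))
    logrank(data.frame(time = cl$time, event = cl$event, group = cl$group),
            2L)$p
  }, numeric(1))
  list(reject_rate = mean(p < 0.05),
       ks_p = stats::ks.test(p, "punif")$p.value,
       pvalues = p)
}

# shared builder: MM/MW/WW labels from a logical gene x sample matrix
mutation_builder <- function(M) {
  samples <- colnames(M)
  function(a, b) {
    stats::setNames(c("WW", "MW", "MM")[1L + M[a, ] + M[b, ]], samples)
  }
}

#' Self-consistency of the randomization empirical p-value
#'
#' When the "observed" pairs are themselves drawn from the null universe
#' (mutations independent of survival, hazard ratio 1), the empirical p
#' must be approximately uniform over replicates. Uses the continuous
#' mean -log10(p) statistic, under which the uniformity property is
#' well-posed (the count statistic is a small tied integer).
#'
#' @param seed integer base seed.
#' @param n_outer outer replicates (default 200).
#' @param B randomizations per replicate (default 99).
#' @param n_genes,n_samples,n_pairs study sizes.
#' @return list(ks_p, empirical_p = vector over replicates).
#' @export
evaluate_randomization_uniformity <- function(seed = 1L, n_outer = 200L,
                                              B = 99L, n_genes = 60L,
                                              n_samples = 400L,
                                              n_pairs = 10L) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  samples <- sprintf("s%04d", seq_len(n_samples))
  ep <- vapply(seq_len(n_outer), function(r) {
    s <- child_seed(seed, paste0("unif/", r))
    with_seed(s, {
      M <- matrix(stats::runif(n_genes * n_samples) < 0.25, n_genes,
                  n_samples, dimnames = list(genes, samples))
      obs <- sample_null_pairs(genes, n_pairs, character(0))
    })
    labels <- stats::setNames(rep("WW", n_samples), samples)
    cl <- generate_clinical(labels, baseline_hazard = 1 / 500,
                            censor_rate = 1 / 2000, seed = s)
    clinical <- data.frame(sample = cl$sample, time = cl$time,
                           event = cl$event)
    randomization_test(obs, genes, obs, clinical, mutation_builder(M),
                       B = B, seed = s, scheme = "two_group",
                       stat = "mean_nlp")$empirical_p
  }, numeric(1))
  # the empirical p lives on the grid {0..B}/B, so exact-tie warnings from
  # ks.test are expected and harmless
  list(ks_p = suppressWarnings(stats::ks.test(ep, "punif")$p.value),
       empirical_p = ep)
}

#' Power of the randomization test under planted prognostic structure
#'
#' Ten SL pairs whose MM group (200 patients) carries hazard ratio
#' `hr` against 200 WW patients; null pair sets are drawn from background
#' genes whose mutations are independent of survival. Reports the
#' empirical p per seed.
#'
#' @param seed integer base seed.
#' @param n_seeds replicate datasets (default 10).
#' @param B randomizations (default 1000).
#' @param hr planted hazard ratio (default 3).
#' @return numeric vector of empirical p-values, one per seed.
#' @export
evaluate_randomization_power <- function(seed = 1L, n_seeds = 10L,
                                         B = 1000L, hr = 3) {
  n_case <- 200L; n_ctrl <- 200L
  n_bg <- 40L; n_sig <- 20L
  samples <- sprintf("s%04d", seq_len(n_case + n_ctrl))
  sig_genes <- sprintf("SIG%02d", seq_len(n_sig))
  bg_genes <- sprintf("BG%02d", seq_len(n_bg))
  vapply(seq_len(n_seeds), function(r) {
    s <- child_seed(seed, paste0("power/", r))
    M <- with_seed(s, {
      Mb <- matrix(stats::runif(n_bg * length(samples)) < 0.25, n_bg,
                   length(samples), dimnames = list(bg_genes, samples))
      Ms <- matrix(FALSE, n_sig, length(samples),
                   dimnames = list(sig_genes, samples))
      Ms[, seq_len(n_case)] <- TRUE    # signal genes mutated in all cases
      rbind(Ms, Mb)
    })
    obs <- data.frame(gene_a = sig_genes[seq(1, n_sig, 2)],
                      gene_b = sig_genes[seq(2, n_sig, 2)])
    group <- stats::setNames(
      rep(c("MM", "WW"), c(n_case, n_ctrl)), samples)
    cl <- generate_clinical(group, hr = c(MM = hr, WW = 1),
                            baseline_hazard = 1 / 500,
                            censor_rate = 1 / 2000, seed = s)
    clinical <- data.frame(sample = cl$sample, time = cl$time,
                           event = cl$event)
    randomization_test(obs, bg_genes, obs, clinical, mutation_builder(M),
                       B = B, seed = s, scheme = "two_group")$empirical_p
  }, numeric(1))
}

#' Recovery of planted log2 fold changes by the DE engine
#'
#' 200 genes with base means log-uniform in 100..1000, ten planted at
#' log2FC +2 and ten at -2, negative-binomial dispersion 0.1, 100 + 100
#' samples.
#'
#' @param seed integer seed.
#' @return list(mean_up, mean_down = mean estimated log2FC of each planted
#'   group, status_ok = all planted statuses called correctly, results).
#' @export
evaluate_de_recovery <- function(seed = 1L) {
  with_seed(child_seed(seed, "de_recovery"), {
    n <- 100L
    mu <- exp(stats::runif(200, log(100), log(1000)))
    lfc <- rep(0, 200)
    lfc[1:10] <- 2; lfc[11:20] <- -2
    tum <- matrix(stats::rnbinom(200 * n, mu = mu * 2^lfc, size = 10), 200, n)
    nor <- matrix(stats::rnbinom(200 * n, mu = mu, size = 10), 200, n)
    m <- cbind(tum, nor)
    rownames(m) <- sprintf("g%03d", 1:200)
    res <- de_test(m, rep(c("tumor", "normal"), c(n, n)))
    list(mean_up = mean(res$log2FC[1:10]),
         mean_down = mean(res$log2FC[11:20]),
         status_ok = all(res$status[1:10] == "up") &&
           all(res$status[11:20] == "down"),
         results = res)
  })
}

#' False-discovery proportion of the DE engine under BH
#'
#' Replicated small experiments (100 genes, 20 with a strong planted
#' effect split evenly between directions, 10 + 10 samples); the FDP is
#' the share of null genes among the padj < 0.05 discoveries. Effects are
#' balanced because median-of-ratios normalization assumes DE is not
#' heavily one-sided; strongly asymmetric DE biases the size factors and
#' is a documented limitation of the engine.
#'
#' @param seed integer base seed.
#' @param n_reps replicates (default 500).
#' @return list(mean_fdp, fdp = per-replicate vector).
#' @export
evaluate_null_fdp <- function(seed = 1L, n_reps = 500L) {
  fdp <- vapply(seq_len(n_reps), function(r) {
    with_seed(child_seed(seed, paste0("fdp/", r)), {
      n <- 10L
      mu <- rep(300, 100)
      lfc <- c(rep(3, 10), rep(-3, 10), rep(0, 80))
      tum <- matrix(stats::rnbinom(100 * n, mu = mu * 2^lfc, size = 10),
                    100, n)
      nor <- matrix(stats::rnbinom(100 * n, mu = mu, size = 10), 100, n)
      m <- cbind(tum, nor)
      rownames(m) <- sprintf("g%03d", 1:100)
      res <- de_test(m, rep(c("tumor", "normal"), c(n, n)))
      disc <- res$padj < 0.05
      sum(disc[21:100]) / max(sum(disc), 1)
    })
  }, numeric(1))
  list(mean_fdp = mean(fdp), fdp = fdp)
}
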