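# Synthetic-data generator with planted, recorded ground truth.
#
# Every pipeline input (mutation calls, count matrices, clinical tables,
# isomiR tables, target maps, drug responses, characteristic sets, pair
# lists) can be generated from one PlantedTruth object, so the full
# screening cascade is testable end to end without external cohorts. A
# single global seed fans out to per-generator child streams via
# child_seed(), so adding one generator never perturbs another's draws.

#' Generator configuration
#'
#' Defaults describe a small but realistic study: a modest gene universe,
#' a dozen cancer types, sparse background mutation (0.5% of samples),
#' strong planted signals sized so the screening thresholds (frequency
#' > 2% in >= 5 cancers; |log2FC| > 1.5 with padj < 0.05 in >= 11 cancers)
#' are met by construction for signal pairs and essentially never by
#' background.
#'
#' @param n_genes number of genes in the universe (>= 20).
#' @param n_cancers number of cancer types.
#' @param n_background_pairs SL catalog pairs with no planted signal.
#' @param n_mutation_signal pairs with BOTH genes recurrently mutated.
#' @param n_expression_signal pairs with BOTH genes recurrently
#'   dysregulated.
#' @param n_combined_signal pairs with one mutated gene and an
#'   up-regulated partner (the combined-screen ground truth).
#' @param mut_rate_signal per-sample mutation probability of signal genes
#'   in their signal cancers (default 0.10).
#' @param mut_rate_background background mutation probability
#'   (default 0.005).
#' @param n_mut_cancers number of cancers carrying a signal gene's
#'   elevated rate (default 6; must be >= 5 when mutation-type signal is
#'   requested).
#' @param de_effect_signal planted |log2 fold change| for
#'   expression-signal genes (default 2.5).
#' @param n_de_cancers number of cancers carrying a planted expression
#'   effect (default 12; must be >= 11 when expression-type signal is
#'   requested).
#' @param n_prognostic number of SL pairs with planted group-dependent
#'   survival hazards.
#' @param prognostic_hr hazard ratio of the MM (or AA) group vs WW/NN
#'   (default 3; the middle group gets sqrt(hr)).
#' @param n_mirnas number of miRNA loci.
#' @param isomirs_per_locus isomiRs per locus (>= 1).
#' @param dominant_prop proportion of the planted dominant isomiR
#'   (must strictly exceed every other proportion).
#' @param n_down_mirnas miRNAs planted down-regulated.
#' @param n_mirna_down_cancers cancers carrying the miRNA down-shift
#'   (default 4).
#' @param mirna_de_effect planted miRNA log2 fold change (default -2).
#' @param targets_per_mirna genes targeted per miRNA.
#' @param n_drugs drugs in the response matrix.
#' @param n_drug_signal (pair, drug) combinations with a planted response
#'   shift.
#' @param drug_effect planted mean response shift on the [0, 1] scale
#'   (default 0.3).
#' @param base_mean_range range of per-gene normal-sample mean counts
#'   (log-uniform; default 50..1000).
#' @param characteristic_coverage per-set membership probability for the
#'   seven gene-characteristic sets (default 0.15).
#' @return list of class `sl_sim_config`.
#' @export
sl_sim_config <- function(n_genes = 120L, n_cancers = 12L,
                          n_background_pairs = 30L,
                          n_mutation_signal = 0L, n_expression_signal = 0L,
                          n_combined_signal = 0L,
                          mut_rate_signal = 0.10, mut_rate_background = 0.005,
                          n_mut_cancers = 6L,
                          de_effect_signal = 2.5, n_de_cancers = 12L,
                          n_prognostic = 0L, prognostic_hr = 3,
                          n_mirnas = 8L, isomirs_per_locus = 3L,
                          dominant_prop = 0.7, n_down_mirnas = 0L,
                          n_mirna_down_cancers = 4L, mirna_de_effect = -2,
                          targets_per_mirna = 3L, n_drugs = 6L,
                          n_drug_signal = 0L, drug_effect = 0.3,
                          base_mean_range = c(50, 1000),
                          characteristic_coverage = 0.15) {
  cfg <- as.list(environment())
  class(cfg) <- "sl_sim_config"
  cfg
}

#' Generate a PlantedTruth object
#'
#' Deterministic for fixed (config, seed). Signal pairs satisfy the
#' screening thresholds by construction; with zero signal pairs every
#' planted effect is null (all mutation rates at background, all
#' expression effects zero).
#'
#' @param config an [sl_sim_config()] list.
#' @param seed integer seed.
#' @return object of class `sl_truth`; see the package vignette for the
#'   field-by-field description.
#' @export
generate_truth <- function(config, seed) {
  cfg <- config
  if (cfg$n_genes < 20L) stop("need n_genes >= 20", call. = FALSE)
  if (cfg$n_cancers < 1L) stop("need n_cancers >= 1", call. = FALSE)
  n_pairs <- cfg$n_background_pairs + cfg$n_mutation_signal +
    cfg$n_expression_signal + cfg$n_combined_signal
  if (n_pairs < 1L) stop("need at least one pair", call. = FALSE)
  if (cfg$n_mutation_signal > 0L && cfg$n_cancers < 5L)
    stop("mutation-signal pairs need n_cancers >= 5 (screen unreachable)",
         call. = FALSE)
  if ((cfg$n_expression_signal > 0L || cfg$n_combined_signal > 0L) &&
      cfg$n_cancers < 11L)
    stop("expression-signal pairs need n_cancers >= 11 (screen unreachable)",
         call. = FALSE)
  uses_mut <- cfg$n_mutation_signal > 0L || cfg$n_combined_signal > 0L
  uses_de <- cfg$n_expression_signal > 0L || cfg$n_combined_signal > 0L
  if ((uses_mut && cfg$n_mut_cancers > cfg$n_cancers) ||
      (uses_de && cfg$n_de_cancers > cfg$n_cancers))
    stop("signal cancer counts exceed n_cancers", call. = FALSE)
  if (cfg$isomirs_per_locus > 1L &&
      cfg$dominant_prop <= (1 - cfg$dominant_prop) / (cfg$isomirs_per_locus - 1))
    stop("dominant_prop must strictly exceed the other proportions",
         call. = FALSE)

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  cancers <- sprintf("CA%02d", seq_len(cfg$n_cancers))
  mirnas <- sprintf("mir-%03d", seq_len(cfg$n_mirnas))

  with_seed(child_seed(seed, "truth"), {
    # --- carve the gene universe into signal roles -----------------------
    need <- 2L * (cfg$n_mutation_signal + cfg$n_expression_signal +
                    cfg$n_combined_signal)
    if (need + 2L > cfg$n_genes)
      stop("gene universe too small for the requested signal pairs",
           call. = FALSE)
    pool <- sample(genes)  # random role assignment
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    mut_pairs <- if (cfg$n_mutation_signal)
      matrix(take(2L * cfg$n_mutation_signal), ncol = 2) else
        matrix(character(0), ncol = 2)
    expr_pairs <- if (cfg$n_expression_signal)
      matrix(take(2L * cfg$n_expression_signal), ncol = 2) else
        matrix(character(0), ncol = 2)
    comb_pairs <- if (cfg$n_combined_signal)
      matrix(take(2L * cfg$n_combined_signal), ncol = 2) else
        matrix(character(0), ncol = 2)  # col1 mutated, col2 up partner

    # background pairs among the remaining genes, distinct, non-signal
    bg <- list()
    seen <- character(0)
    while (length(bg) < cfg$n_background_pairs) {
      g2 <- sample(pool, 2L)
      key <- pair_key(g2[1], g2[2])
      if (key %in% seen) next
      seen <- c(seen, key)
      bg[[length(bg) + 1L]] <- g2
    }
    bg <- if (length(bg)) do.call(rbind, bg) else matrix(character(0), ncol = 2)

    all_pairs <- rbind(comb_pairs, mut_pairs, expr_pairs, bg)
    signal_type <- c(rep("combined", nrow(comb_pairs)),
                     rep("mutation", nrow(mut_pairs)),
                     rep("expression", nrow(expr_pairs)),
                     rep("background", nrow(bg)))
    # provenance: yeast-predicted background pairs get a score <= -0.35
    src <- sample(c("human_predicted", "human_validated"), nrow(all_pairs),
                  replace = TRUE)
    yeast_idx <- which(signal_type == "background")
    yeast_idx <- yeast_idx[seq_len(min(length(yeast_idx),
                                       ceiling(nrow(all_pairs) / 4)))]
    src[yeast_idx] <- "yeast_predicted"
    score <- rep(NA_real_, nrow(all_pairs))
    score[yeast_idx] <- -round(stats::runif(length(yeast_idx), 0.35, 0.80), 3)
    sl_pairs <- data.frame(gene_a = all_pairs[, 1], gene_b = all_pairs[, 2],
                           sources = src, yeast_score = score,
                           signal = signal_type, stringsAsFactors = FALSE)

    # --- planted mutation frequencies ------------------------------------
    mutation_freq <- matrix(cfg$mut_rate_background, cfg$n_genes,
                            cfg$n_cancers, dimnames = list(genes, cancers))
    # mutation-signal pairs share one cancer set per pair: the screen
    # requires BOTH genes above threshold in the same >= 5 cancers
    mut_cancer_sets <- list()
    for (i in seq_len(nrow(mut_pairs))) {
      cs <- sort(sample(cancers, cfg$n_mut_cancers))
      for (g in mut_pairs[i, ]) {
        mut_cancer_sets[[g]] <- cs
        mutation_freq[g, cs] <- cfg$mut_rate_signal
      }
    }
    for (g in comb_pairs[, 1]) {
      cs <- sort(sample(cancers, cfg$n_mut_cancers))
      mut_cancer_sets[[g]] <- cs
      mutation_freq[g, cs] <- cfg$mut_rate_signal
    }

    # --- planted expression effects --------------------------------------
    de_effect <- matrix(0, cfg$n_genes, cfg$n_cancers,
                        dimnames = list(genes, cancers))
    de_cancer_sets <- list()
    for (g in as.vector(expr_pairs)) {
      cs <- sort(sample(cancers, cfg$n_de_cancers))
      de_cancer_sets[[g]] <- cs
      de_effect[g, cs] <- sample(c(-1, 1), 1) * cfg$de_effect_signal
    }
    for (g in comb_pairs[, 2]) {  # combined partners are up-regulated
      cs <- sort(sample(cancers, cfg$n_de_cancers))
      de_cancer_sets[[g]] <- cs
      de_effect[g, cs] <- abs(cfg$de_effect_signal)
    }

    # --- characteristic sets ---------------------------------------------
    characteristic_sets <- lapply(CHARACTERISTIC_NAMES, function(nm)
      genes[stats::runif(cfg$n_genes) < cfg$characteristic_coverage])
    names(characteristic_sets) <- CHARACTERISTIC_NAMES

    # --- prognostic structure --------------------------------------------
    n_prog <- min(cfg$n_prognostic, nrow(sl_pairs))
    prognostic_pairs <- if (n_prog) data.frame(
      pair = pair_key(sl_pairs$gene_a[seq_len(n_prog)],
                      sl_pairs$gene_b[seq_len(n_prog)]),
      hr_extreme = cfg$prognostic_hr, hr_mid = sqrt(cfg$prognostic_hr),
      stringsAsFactors = FALSE) else
        data.frame(pair = character(0), hr_extreme = numeric(0),
                   hr_mid = numeric(0))

    # --- isomiR profiles and target map ----------------------------------
    k <- cfg$isomirs_per_locus
    isomir_profile <- lapply(mirnas, function(mi) {
      len <- sample(20:23, 1)
      seqs <- unique(replicate(k + 2, paste(sample(c("A", "C", "G", "U"),
                                                   len, replace = TRUE),
                                            collapse = "")))[seq_len(k)]
      props <- if (k == 1) 1 else {
        rest <- (1 - cfg$dominant_prop) *
          (seq(k - 1, 1) / sum(seq_len(k - 1)))
        c(cfg$dominant_prop, rest)
      }
      dom <- sample.int(k, 1)
      ord <- seq_len(k)
      # place the dominant proportion at a random position
      props_placed <- numeric(k)
      props_placed[dom] <- props[1]
      props_placed[-dom] <- props[-1]
      list(sequences = seqs, proportions = props_placed, dominant = dom)
    })
    names(isomir_profile) <- mirnas

    # target maps lean toward the combined-signal genes (target databases
    # are queried for the screened genes, so hits there are expected)
    sig_genes <- unique(as.vector(comb_pairs))
    target_map <- lapply(mirnas, function(mi) {
      n_t <- min(cfg$targets_per_mirna, cfg$n_genes)
      n_sig <- min(length(sig_genes), ceiling(n_t / 2))
      t1 <- if (n_sig) sample(sig_genes, n_sig) else character(0)
      t2 <- sample(setdiff(genes, t1), n_t - length(t1))
      sort(unique(c(t1, t2)))
    })
    names(target_map) <- mirnas

    mirna_de_effect <- matrix(0, cfg$n_mirnas, cfg$n_cancers,
                              dimnames = list(mirnas, cancers))
    n_dn <- min(cfg$n_down_mirnas, cfg$n_mirnas)
    down_mirnas <- if (n_dn) sample(mirnas, n_dn) else character(0)
    for (mi in down_mirnas) {
      cs <- sample(cancers, min(cfg$n_mirna_down_cancers, cfg$n_cancers))
      mirna_de_effect[mi, cs] <- cfg$mirna_de_effect
    }

    # --- drug effects ----------------------------------------------------
    drugs <- sprintf("drug%02d", seq_len(cfg$n_drugs))
    n_ds <- min(cfg$n_drug_signal, nrow(sl_pairs) * cfg$n_drugs)
    # drug effects attach to mutation-signal pairs first: those are the
    # pairs whose MM groups are large enough to test
    pref <- c(which(signal_type == "mutation"), which(signal_type == "combined"),
              which(!signal_type %in% c("mutation", "combined")))
    drug_effects <- if (n_ds) {
      pi <- pref[((seq_len(n_ds) - 1) %% length(pref)) + 1]
      data.frame(
        pair = pair_key(sl_pairs$gene_a[pi], sl_pairs$gene_b[pi]),
        drug = drugs[((seq_len(n_ds) - 1) %/% length(pref)) + 1],
        shift = cfg$drug_effect, stringsAsFactors = FALSE)
    } else
      data.frame(pair = character(0), drug = character(0), shift = numeric(0))

    # per-gene base means, log-uniform over the configured range
    base_mean <- exp(stats::runif(cfg$n_genes, log(cfg$base_mean_range[1]),
                                  log(cfg$base_mean_range[2])))
    names(base_mean) <- genes

    truth <- list(gene_universe = genes, cancers = cancers, drugs = drugs,
                  sl_pairs = sl_pairs,
                  characteristic_sets = characteristic_sets,
                  mutation_freq = mutation_freq, de_effect = de_effect,
                  mut_cancer_sets = mut_cancer_sets,
                  de_cancer_sets = de_cancer_sets,
                  prognostic_pairs = prognostic_pairs,
                  isomir_profile = isomir_profile, target_map = target_map,
                  mirna_de_effect = mirna_de_effect,
                  down_mirnas = sort(down_mirnas),
                  drug_effects = drug_effects, base_mean = base_mean,
                  config = cfg, seed = as.integer(seed))
    class(truth) <- "sl_truth"
    validate_truth(truth)
    truth
  })
}

#' Validate PlantedTruth invariants
#'
#' Checks that every named gene is in the universe, all rates are in
#' [0, 1], isomiR proportion vectors sum to 1 (1e-9) with the planted
#' dominant index strictly largest.
#'
#' @param truth an `sl_truth` object.
#' @return `truth`, invisibly; errors on violation.
#' @export
validate_truth <- function(truth) {
  named <- c(truth$sl_pairs$gene_a, truth$sl_pairs$gene_b,
             unlist(truth$characteristic_sets), unlist(truth$target_map))
  if (!all(named %in% truth$gene_universe))
    stop("truth names gene(s) outside the universe", call. = FALSE)
  if (any(truth$mutation_freq < 0 | truth$mutation_freq > 1))
    stop("mutation rates outside [0, 1]", call. = FALSE)
  for (mi in names(truth$isomir_profile)) {
    p <- truth$isomir_profile[[mi]]
    if (abs(sum(p$proportions) - 1) > 1e-9)
      stop("isomiR proportions of ", mi, " do not sum to 1", call. = FALSE)
    dom <- p$dominant
    if (length(p$proportions) > 1 &&
        any(p$proportions[-dom] >= p$proportions[dom]))
      stop("planted dominant isomiR of ", mi, " is not strictly largest",
           call. = FALSE)
  }
  if (any(truth$sl_pairs$gene_a == truth$sl_pairs$gene_b))
    stop("self-pair in planted SL pairs", call. = FALSE)
  invisible(truth)
}

#' @export
print.sl_truth <- function(x, ...) {
  cat(sprintf(paste0("planted truth: %d genes, %d cancers, %d SL pairs ",
                     "(%d signal), %d miRNA loci, seed %d\n"),
              length(x$gene_universe), length(x$cancers), nrow(x$sl_pairs),
              sum(x$sl_pairs$signal != "background"),
              length(x$isomir_profile), x$seed))
  invisible(x)
}

#' Generate mutation calls
#'
#' Per cancer and sample, gene g mutates with probability
#' `mutation_freq[g, cancer]`; each call draws a variant class from the
#' configured categorical distribution (missense-dominant by default,
#' matching the composition typical of tumor cohorts).
#'
#' @param truth `sl_truth` object.
#' @param n_samples_per_cancer cohort size per cancer type.
#' @param seed integer seed.
#' @param variant_probs named categorical distribution over
#'   missense, nonsense, frameshift, splice, other.
#' @return list(calls = data.frame(sample, gene, cancer, variant_class),
#'   cohorts = named list cancer -> sample barcodes).
#' @export
generate_mutations <- function(truth, n_samples_per_cancer, seed,
                               variant_probs = c(missense = 0.6, nonsense = 0.1,
                                                 frameshift = 0.1, splice = 0.1,
                                                 other = 0.1)) {
  if (n_samples_per_cancer < 1L) stop("need n_samples_per_cancer >= 1", call. = FALSE)
  stopifnot(abs(sum(variant_probs) - 1) < 1e-9,
            all(names(variant_probs) == VARIANT_CLASSES))
  genes <- truth$gene_universe
  calls <- list()
  cohorts <- list()
  for (cc in truth$cancers) {
    samples <- sprintf("%s_S%04d", cc, seq_len(n_samples_per_cancer))
    cohorts[[cc]] <- samples
    rates <- truth$mutation_freq[, cc]
    with_seed(child_seed(seed, paste0("mutations/", cc)), {
      hit <- matrix(stats::runif(length(genes) * n_samples_per_cancer),
                    nrow = length(genes)) < rates
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx)) {
        vc <- sample(VARIANT_CLASSES, nrow(idx), replace = TRUE,
                     prob = variant_probs)
        calls[[cc]] <- data.frame(sample = samples[idx[, 2]],
                                  gene = genes[idx[, 1]], cancer = cc,
                                  variant_class = vc, stringsAsFactors = FALSE)
      }
    })
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample = character(0), gene = character(0),
               cancer = character(0), variant_class = character(0))
  rownames(calls) <- NULL
  list(calls = calls, cohorts = cohorts)
}

#' Generate per-cancer count matrices
#'
#' Negative-binomial counts: per-gene normal-sample mean from the truth's
#' base means, tumor-sample mean scaled by `2^de_effect[g, cancer]`,
#' common gene-level dispersion.
#'
#' @param truth `sl_truth` object.
#' @param n_tumor,n_normal samples per condition (>= 2 each).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2;
#'   default 0.1).
#' @param seed integer seed.
#' @return named list per cancer: list(counts = gene x sample integer
#'   matrix, condition = "tumor"/"normal" per column).
#' @export
generate_counts <- function(truth, n_tumor, n_normal, dispersion = 0.1,
                            seed = 1L) {
  if (n_tumor < 2L || n_normal < 2L)
    stop("need at least 2 tumor and 2 normal samples", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  genes <- truth$gene_universe
  size <- 1 / dispersion
  out <- list()
  for (cc in truth$cancers) {
    mu_n <- truth$base_mean
    mu_t <- mu_n * 2^truth$de_effect[, cc]
    with_seed(child_seed(seed, paste0("counts/", cc)), {
      tum <- matrix(stats::rnbinom(length(genes) * n_tumor, mu = mu_t,
                                   size = size), nrow = length(genes))
      nor <- matrix(stats::rnbinom(length(genes) * n_normal, mu = mu_n,
                                   size = size), nrow = length(genes))
      m <- cbind(tum, nor)
      rownames(m) <- genes
      colnames(m) <- c(sprintf("%s_T%03d", cc, seq_len(n_tumor)),
                       sprintf("%s_N%03d", cc, seq_len(n_normal)))
      out[[cc]] <- list(counts = m,
                        condition = c(rep("tumor", n_tumor),
                                      rep("normal", n_normal)))
    })
  }
  out
}

#' Generate a clinical survival table
#'
#' Event times are exponential with hazard `baseline_hazard * hr[group]`;
#' censoring is an independent exponential with rate `censor_rate`
#' (0 = no censoring). Times are in days, strictly positive.
#'
#' @param group_labels character vector of group labels named by sample
#'   barcode.
#' @param hr named numeric hazard ratio per group label; missing groups
#'   default to 1.
#' @param baseline_hazard events per day (default 1/500).
#' @param censor_rate censoring events per day (default 1/2000).
#' @param seed integer seed.
#' @param cancer optional cancer code column.
#' @return data.frame sample, cancer, time, event, group.
#' @export
generate_clinical <- function(group_labels, hr = NULL, baseline_hazard = 1/500,
                              censor_rate = 1/2000, seed = 1L,
                              cancer = NA_character_) {
  stopifnot(baseline_hazard > 0, censor_rate >= 0)
  hr_of <- function(g) {
    v <- if (!is.null(hr) && g %in% names(hr)) hr[[g]] else 1
    v
  }
  rates <- baseline_hazard * vapply(as.character(group_labels), hr_of, numeric(1))
  with_seed(child_seed(seed, "clinical"), {
    t_event <- stats::rexp(length(rates), rate = rates)
    t_cens <- if (censor_rate > 0)
      stats::rexp(length(rates), rate = censor_rate) else Inf
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    data.frame(sample = names(group_labels), cancer = cancer, time = time,
               event = event, group = as.character(group_labels),
               stringsAsFactors = FALSE)
  })
}

#' Generate per-cancer isomiR count tables
#'
#' Per sample and locus, the locus total is negative-binomial around
#' `locus_total_mean` (scaled by `2^mirna_de_effect[locus, cancer]` in
#' tumor samples); isomiR counts are multinomial with the truth's planted
#' proportion vector, so per-sample isomiR counts sum to the locus total.
#'
#' @param truth `sl_truth` object.
#' @param n_tumor,n_normal samples per condition.
#' @param locus_total_mean mean locus total count (default 2000).
#' @param dispersion NB dispersion of locus totals (default 0.1).
#' @param seed integer seed.
#' @return named list per cancer: list(table = data.frame(locus, sequence,
#'   per-sample counts), condition).
#' @export
generate_isomirs <- function(truth, n_tumor, n_normal,
                             locus_total_mean = 2000, dispersion = 0.1,
                             seed = 1L) {
  stopifnot(locus_total_mean > 0, dispersion > 0)
  loci <- names(truth$isomir_profile)
  if (any(vapply(truth$isomir_profile, function(p) length(p$sequences) < 1L,
                 logical(1))))
    stop("each locus needs at least one isomiR", call. = FALSE)
  size <- 1 / dispersion
  out <- list()
  for (cc in truth$cancers) {
    n <- n_tumor + n_normal
    cond <- c(rep("tumor", n_tumor), rep("normal", n_normal))
    snames <- c(sprintf("%s_T%03d", cc, seq_len(n_tumor)),
                sprintf("%s_N%03d", cc, seq_len(n_normal)))
    with_seed(child_seed(seed, paste0("isomirs/", cc)), {
      rows <- lapply(loci, function(mi) {
        prof <- truth$isomir_profile[[mi]]
        mu <- locus_total_mean *
          ifelse(cond == "tumor", 2^truth$mirna_de_effect[mi, cc], 1)
        totals <- stats::rnbinom(n, mu = mu, size = size)
        cnt <- vapply(seq_len(n), function(j) {
          if (totals[j] == 0) integer(length(prof$proportions))
          else as.integer(stats::rmultinom(1, totals[j], prof$proportions))
        }, integer(length(prof$proportions)))
        cnt <- matrix(cnt, nrow = length(prof$proportions))
        df <- data.frame(locus = mi, sequence = prof$sequences,
                         stringsAsFactors = FALSE)
        cbind(df, as.data.frame(stats::setNames(as.data.frame(cnt), snames)))
      })
      tab <- do.call(rbind, rows)
      names(tab) <- c("locus", "sequence", snames)
      out[[cc]] <- list(table = tab, condition = cond)
    })
  }
  out
}

#' Generate a sample x drug response matrix
#'
#' Responses live on a min-max-normalized [0, 1] scale:
#' `Normal(base + shift * I(group == MM), noise_sd)` truncated to [0, 1],
#' where the shift is the truth's planted effect for (pair, drug) (0 when
#' none is planted).
#'
#' @param truth `sl_truth` object.
#' @param group_labels group labels named by sample barcode (MM/MW/WW).
#' @param pair list with gene_a, gene_b identifying the pair whose planted
#'   drug effects apply.
#' @param noise_sd response noise (default 0.05).
#' @param base_response mean response of the reference group (default 0.5).
#' @param seed integer seed.
#' @return numeric sample x drug matrix with values in [0, 1].
#' @export
generate_drug_response <- function(truth, group_labels, pair, noise_sd = 0.05,
                                   base_response = 0.5, seed = 1L) {
  stopifnot(noise_sd > 0)
  key <- pair_key(pair$gene_a, pair$gene_b)
  shifts <- stats::setNames(rep(0, length(truth$drugs)), truth$drugs)
  de <- truth$drug_effects[truth$drug_effects$pair == key, , drop = FALSE]
  shifts[de$drug] <- de$shift
  n <- length(group_labels)
  with_seed(child_seed(seed, paste0("drugs/", key)), {
    m <- vapply(truth$drugs, function(d) {
      mu <- base_response + shifts[[d]] * (group_labels == "MM")
      pmin(pmax(stats::rnorm(n, mu, noise_sd), 0), 1)
    }, numeric(n))
    m <- matrix(m, nrow = n,
                dimnames = list(names(group_labels), truth$drugs))
    m
  })
}
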