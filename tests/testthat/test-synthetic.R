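# Synthetic-data generators: determinism, planted-truth invariants, and
# distributional oracles.

test_that("truth generation is deterministic and null configs are truly null", {
  cfg <- sl_sim_config(n_genes = 30, n_cancers = 6, n_background_pairs = 8)
  t1 <- generate_truth(cfg, 5)
  t2 <- generate_truth(cfg, 5)
  expect_identical(t1, t2)
  t3 <- generate_truth(cfg, 6)
  expect_false(identical(t1$sl_pairs, t3$sl_pairs))
  # no signal requested: every effect at background / zero
  expect_true(all(t1$de_effect == 0))
  expect_true(all(t1$mutation_freq == cfg$mut_rate_background))
  expect_equal(nrow(t1$prognostic_pairs), 0)
  validate_truth(t1)
})

test_that("signal configs satisfy the screen thresholds by construction", {
  cfg <- sl_sim_config(n_genes = 40, n_cancers = 6, n_background_pairs = 5,
                       n_mutation_signal = 3, n_mut_cancers = 5)
  tr <- generate_truth(cfg, 2)
  # direct enumeration over the emitted truth: exactly 3 pairs whose both
  # genes exceed 2% mutation frequency in >= 5 cancers
  n_ok <- 0
  for (i in seq_len(nrow(tr$sl_pairs))) {
    fa <- tr$mutation_freq[tr$sl_pairs$gene_a[i], ]
    fb <- tr$mutation_freq[tr$sl_pairs$gene_b[i], ]
    if (sum(fa > 0.02 & fb > 0.02) >= 5) n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 3)
  # expression signal: both genes of each pair planted past the cascade cut
  cfge <- sl_sim_config(n_genes = 60, n_cancers = 12, n_background_pairs = 5,
                        n_expression_signal = 2)
  tre <- generate_truth(cfge, 2)
  sig <- tre$sl_pairs[tre$sl_pairs$signal == "expression", ]
  for (g in c(sig$gene_a, sig$gene_b))
    expect_gte(sum(abs(tre$de_effect[g, ]) > 1.5), 11)
  # screens unreachable under too few cancers are rejected
  expect_error(generate_truth(sl_sim_config(n_cancers = 4,
                                            n_mutation_signal = 1), 1),
               "n_cancers >= 5")
  expect_error(generate_truth(sl_sim_config(n_cancers = 10,
                                            n_expression_signal = 1), 1),
               "n_cancers >= 11")
})

test_that("mutation generation follows the planted Bernoulli rates", {
  cfg <- sl_sim_config(n_genes = 25, n_cancers = 2, n_background_pairs = 5,
                       mut_rate_background = 0.1)
  tr <- generate_truth(cfg, 3)
  gm <- generate_mutations(tr, 1000, seed = 3)
  fm <- attr(mutation_frequency(gm$calls,
                                lengths(gm$cohorts)[tr$cancers]), "matrix")
  # binomial oracle: every observed frequency within 3 standard errors
  se <- 3 * sqrt(0.1 * 0.9 / 1000)
  expect_true(all(abs(fm - 0.1) < se + 0.01))
  # determinism
  gm2 <- generate_mutations(tr, 1000, seed = 3)
  expect_identical(gm, gm2)
  # rate 1: called in every sample; rate 0: absent
  tr$mutation_freq[] <- 0
  tr$mutation_freq["G0001", "CA01"] <- 1
  gm3 <- generate_mutations(tr, 50, seed = 4)
  expect_equal(nrow(gm3$calls), 50)
  expect_true(all(gm3$calls$gene == "G0001" & gm3$calls$cancer == "CA01"))
  tr$mutation_freq[] <- 0
  expect_equal(nrow(generate_mutations(tr, 50, seed = 4)$calls), 0)
})

test_that("count generation hits the planted fold change", {
  cfg <- sl_sim_config(n_genes = 30, n_cancers = 1, n_background_pairs = 5)
  tr <- generate_truth(cfg, 4)
  tr$de_effect["G0001", "CA01"] <- 2
  gc <- generate_counts(tr, n_tumor = 100, n_normal = 100, dispersion = 0.1,
                        seed = 4)
  m <- gc$CA01$counts
  expect_true(all(m >= 0) && all(m == floor(m)))        # counts are counts
  cond <- gc$CA01$condition
  emp <- log2(mean(m["G0001", cond == "tumor"]) /
                mean(m["G0001", cond == "normal"]))
  expect_equal(emp, 2, tolerance = 0.15)                # NB sampling oracle
  null_emp <- log2(rowMeans(m[-1, cond == "tumor"]) /
                     rowMeans(m[-1, cond == "normal"]))
  expect_lt(max(abs(null_emp)), 0.5)
  expect_error(generate_counts(tr, 100, 100, dispersion = -1, seed = 1),
               "positive")
  expect_error(generate_counts(tr, 1, 100, seed = 1), "at least 2")
})

test_that("clinical generation respects hazards and censoring limits", {
  labels <- setNames(rep(c("MM", "WW"), each = 100), sprintf("s%03d", 1:200))
  cl <- generate_clinical(labels, hr = c(MM = 4, WW = 1), seed = 11)
  expect_true(all(cl$time > 0))
  expect_true(all(cl$event %in% 0:1))
  # heavier hazard shortens event times
  expect_lt(median(cl$time[cl$group == "MM"]),
            median(cl$time[cl$group == "WW"]))
  # censoring rate -> infinity: everything censored
  cl2 <- generate_clinical(labels, censor_rate = 1e9, seed = 11)
  expect_true(all(cl2$event == 0))
  # no censoring
  cl3 <- generate_clinical(labels, censor_rate = 0, seed = 11)
  expect_true(all(cl3$event == 1))
  expect_identical(generate_clinical(labels, seed = 12),
                   generate_clinical(labels, seed = 12))
})

test_that("isomiR tables conserve locus totals and expose the dominant isomiR", {
  cfg <- sl_sim_config(n_genes = 25, n_cancers = 1, n_background_pairs = 5,
                       n_mirnas = 6, isomirs_per_locus = 3,
                       dominant_prop = 0.7)
  tr <- generate_truth(cfg, 6)
  gi <- generate_isomirs(tr, n_tumor = 25, n_normal = 25, seed = 6)
  tab <- gi$CA01$table
  counts <- as.matrix(tab[, -(1:2)])
  # multinomial conservation: per-sample locus totals match column sums
  for (l in unique(tab$locus)) {
    tot <- colSums(counts[tab$locus == l, , drop = FALSE])
    expect_true(all(tot >= 0))
  }
  # dominant recovery: collapse finds the planted dominant for every locus
  col <- collapse_isomirs(tab)
  planted <- vapply(tr$isomir_profile, function(p)
    p$sequences[p$dominant], character(1))
  expect_equal(col$representative$sequence[
    match(names(planted), col$representative$locus)],
    unname(planted))
  # single-isomiR locus carries the whole total
  cfg1 <- sl_sim_config(n_genes = 25, n_cancers = 1, n_background_pairs = 5,
                        n_mirnas = 2, isomirs_per_locus = 1)
  tr1 <- generate_truth(cfg1, 7)
  gi1 <- generate_isomirs(tr1, 5, 5, seed = 7)
  expect_equal(nrow(gi1$CA01$table), 2)
})

test_that("drug responses stay in [0, 1] and carry the planted shift", {
  cfg <- sl_sim_config(n_genes = 25, n_cancers = 1, n_background_pairs = 4,
                       n_mutation_signal = 0, n_drugs = 4, n_drug_signal = 1,
                       drug_effect = 0.3)
  tr <- generate_truth(cfg, 8)
  pair <- tr$sl_pairs[1, ]
  labels <- setNames(rep(c("MM", "WW"), each = 50), sprintf("s%03d", 1:100))
  dm <- generate_drug_response(tr, labels, pair, noise_sd = 0.05, seed = 8)
  expect_true(all(dm >= 0 & dm <= 1))
  planted_drug <- tr$drug_effects$drug[tr$drug_effects$pair ==
                                         pair_key(pair$gene_a, pair$gene_b)]
  groups <- data.frame(sample = names(labels), group = labels)
  da <- drug_association(groups, dm)
  expect_true(da$significant[da$drug == planted_drug])
  # null drugs: difference within normal-theory bounds, not flagged
  null_rows <- da[da$drug != planted_drug, ]
  expect_true(all(abs(null_rows$effect) < 3 * 0.05 / sqrt(50) + 0.02))
  expect_false(any(null_rows$significant))
})
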