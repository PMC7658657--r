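# Kaplan-Meier, log-rank (vs the survival-package oracle), prognostic
# scan, and the randomization empirical null.

test_that("KM estimate matches closed forms and the product-limit oracle", {
  rec <- data.frame(time = c(5, 9, 14), event = 0, group = "all")
  km <- km_estimate(rec)
  expect_true(all(km$surv == 1))                      # no events
  rec2 <- data.frame(time = c(1, 2), event = 1, group = "all")
  km2 <- km_estimate(rec2)
  expect_equal(km2$surv, c(0.5, 0))                   # 1 -> 0.5 -> 0
  withr::with_seed(61, {
    for (rep in 1:5) {
      n <- 40
      rec3 <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1, 0.7),
                         group = "all")
      km3 <- km_estimate(rec3)
      orc <- oracle_km(rec3$time, rec3$event)
      got <- km3[km3$n_event > 0, c("time", "surv")]
      expect_equal(got$time, orc$time)
      expect_equal(got$surv, orc$surv, tolerance = 1e-12)
    }
  })
  expect_error(km_estimate(data.frame(time = -1, event = 1, group = "g")),
               "positive")
})

test_that("log-rank agrees with survival::survdiff to numerical precision", {
  # two identical groups: statistic exactly 0
  d <- data.frame(time = rep(c(3, 7, 11), 2), event = rep(c(1, 1, 0), 2),
                  group = rep(c("A", "B"), each = 3))
  lr <- logrank(d, 2)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p, 1)
  # hand example: all A events before all B events
  d2 <- data.frame(time = c(1, 2, 3, 4), event = 1,
                   group = c("A", "A", "B", "B"))
  lr2 <- logrank(d2, 2)
  sd2 <- survival::survdiff(survival::Surv(time, event) ~ group, data = d2)
  expect_equal(lr2$statistic, sd2$chisq, tolerance = 1e-10)
  withr::with_seed(62, {
    for (rep in 1:20) {
      k <- sample(2:3, 1)
      n <- sample(20:60, 1)
      d3 <- data.frame(time = round(rexp(n, 0.1), 1) + 0.1,  # forces ties
                       event = rbinom(n, 1, 0.7),
                       group = sample(LETTERS[1:k], n, replace = TRUE))
      if (length(unique(d3$group)) < k) next
      lr3 <- logrank(d3, k)
      sd3 <- survival::survdiff(survival::Surv(time, event) ~ group, data = d3)
      expect_equal(lr3$statistic, sd3$chisq, tolerance = 1e-8)
      expect_equal(lr3$df, k - 1)
    }
  })
  expect_error(logrank(data.frame(time = 1, event = 1, group = "A"), 2),
               "two usable groups")
})

test_that("empirical p-value equals its counting definition", {
  expect_equal(empirical_pvalue(2, c(1, 5, 2, 0)), 0.5)  # 5 and 2 qualify
  expect_equal(empirical_pvalue(10, c(1, 5, 2, 0)), 0)   # above every null
  expect_equal(empirical_pvalue(0, c(1, 5, 2, 0)), 1)
  # invariant under permutation of the null vector
  withr::with_seed(63, {
    null <- rpois(50, 3)
    p <- empirical_pvalue(4, null)
    expect_equal(empirical_pvalue(4, sample(null)), p)
    # adding a strictly smaller null draw never increases it
    expect_lte(empirical_pvalue(4, c(null, 0)), p)
  })
  # the conservative variant
  expect_equal(empirical_pvalue(10, c(1, 5, 2, 0), plus_one = TRUE), 1 / 5)
})

test_that("prognostic scan counts significant pairs and skips small arms", {
  withr::with_seed(64, {
    samples <- sprintf("s%03d", 1:400)
    genes <- sprintf("G%02d", 1:30)
    M <- matrix(runif(30 * 400) < 0.25, 30, 400,
                dimnames = list(genes, samples))
    builder <- function(a, b) {
      ga <- M[a, ]; gb <- M[b, ]
      setNames(ifelse(ga & gb, "MM", ifelse(ga | gb, "MW", "WW")), samples)
    }
    clinical <- data.frame(sample = samples, time = rexp(400, 1/500),
                           event = rbinom(400, 1, 0.8))
    pairs <- data.frame(gene_a = genes[seq(1, 29, 2)],
                        gene_b = genes[seq(2, 30, 2)])
    scan <- pair_prognostic_scan(pairs, builder, clinical, "two_group")
    expect_equal(scan$n_tested, sum(scan$per_pair$tested))
    # null data: roughly alpha x n_tested significant (generous bound)
    expect_lte(scan$n_significant, max(3, 0.3 * scan$n_tested))
    # three-group scheme tests the same pairs with df 2
    scan3 <- pair_prognostic_scan(pairs, builder, clinical, "three_group")
    expect_equal(nrow(scan3$per_pair), nrow(pairs))
    # empty pair list
    scan0 <- pair_prognostic_scan(pairs[0, ], builder, clinical, "two_group")
    expect_equal(scan0$n_significant, 0)
    # a pair whose MM arm is tiny gets skipped with a reason
    M["G01", ] <- FALSE; M["G01", 1:2] <- TRUE
    M["G02", ] <- TRUE
    scan_skip <- pair_prognostic_scan(data.frame(gene_a = "G01",
                                                 gene_b = "G02"),
                                      builder, clinical, "two_group")
    expect_equal(scan_skip$n_tested, 0)
    expect_match(scan_skip$per_pair$reason, "min size")
  })
})

test_that("a planted hazard ratio is detected by the scan", {
  withr::with_seed(65, {
    samples <- sprintf("s%03d", 1:400)
    M <- matrix(FALSE, 2, 400, dimnames = list(c("G01", "G02"), samples))
    M[, 1:200] <- TRUE                       # MM = first 200 samples
    builder <- function(a, b) {
      ga <- M[a, ]; gb <- M[b, ]
      setNames(ifelse(ga & gb, "MM", ifelse(ga | gb, "MW", "WW")), samples)
    }
    grp <- builder("G01", "G02")
    clin <- generate_clinical(grp, hr = c(MM = 3, MW = sqrt(3), WW = 1),
                              censor_rate = 1/2000, seed = 65)
    scan <- pair_prognostic_scan(data.frame(gene_a = "G01", gene_b = "G02"),
                                 builder, clin, "two_group")
    expect_equal(scan$n_significant, 1)
  })
})

test_that("randomization test is deterministic and respects its contract", {
  withr::with_seed(66, {
    samples <- sprintf("s%03d", 1:200)
    genes <- sprintf("G%02d", 1:20)
    M <- matrix(runif(20 * 200) < 0.3, 20, 200,
                dimnames = list(genes, samples))
    builder <- function(a, b) {
      ga <- M[a, ]; gb <- M[b, ]
      setNames(ifelse(ga & gb, "MM", ifelse(ga | gb, "MW", "WW")), samples)
    }
    clinical <- data.frame(sample = samples, time = rexp(200, 1/500),
                           event = rbinom(200, 1, 0.8))
    obs <- data.frame(gene_a = c("G01", "G03"), gene_b = c("G02", "G04"))
    r1 <- randomization_test(obs, genes, obs, clinical, builder, B = 25,
                             seed = 7, scheme = "two_group")
    r2 <- randomization_test(obs, genes, obs, clinical, builder, B = 25,
                             seed = 7, scheme = "two_group")
    expect_identical(r1, r2)                       # fixed seed, bit-identical
    expect_equal(length(r1$null_stats), 25)
    expect_equal(r1$empirical_p,
                 empirical_pvalue(r1$observed_stat, r1$null_stats))
    # excluded universe too small -> error before iterating
    expect_error(randomization_test(obs, c("G01", "G02"), obs, clinical,
                                    builder, B = 5, seed = 1),
                 "too small")
    # the continuous statistic mode returns a mean -log10 p
    r3 <- randomization_test(obs, genes, obs, clinical, builder, B = 10,
                             seed = 7, stat = "mean_nlp")
    expect_true(is.finite(r3$observed_stat))
  })
})
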