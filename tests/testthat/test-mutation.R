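# Mutation screen: frequencies, pair selection, grouping, composition,
# drug association.

test_that("mutation frequency deduplicates samples and matches brute force", {
  calls <- data.frame(
    sample = c("s1", "s2", "s3", "s4", "s5", "s1"),
    gene = c("A", "A", "A", "A", "A", "A"),
    cancer = "CA01",
    variant_class = c("missense", "missense", "splice", "missense",
                      "nonsense", "frameshift"))
  fr <- mutation_frequency(calls, c(CA01 = 100))
  expect_equal(fr$frequency[fr$gene == "A"], 0.05)  # 5 distinct of 100
  expect_error(mutation_frequency(calls, c(CA99 = 10)), "cohort size")
  withr::with_seed(21, {
    for (rep in 1:5) {
      rc <- random_calls(300, sprintf("G%02d", 1:15), c("CA01", "CA02", "CA03"),
                         40)
      sizes <- c(CA01 = 40, CA02 = 40, CA03 = 40)
      fm <- attr(mutation_frequency(rc, sizes), "matrix")
      for (g in rownames(fm)) for (cc in colnames(fm)) {
        brute <- length(unique(rc$sample[rc$gene == g & rc$cancer == cc])) / 40
        expect_equal(fm[g, cc], brute)
      }
    }
  })
})

test_that("recurrently mutated pair screen enforces both-gene thresholds", {
  cancers <- sprintf("CA%02d", 1:6)
  fm <- matrix(0, 3, 6, dimnames = list(c("A", "B", "C"), cancers))
  fm["A", 1:5] <- 0.03; fm["B", 1:5] <- 0.03   # both over 2% in 5 cancers
  fm["C", 1:4] <- 0.03; fm["C", 6] <- 0.03     # C alone in a 5th cancer
  catalog <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "C"),
                        sources = "human_predicted", yeast_score = NA,
                        orig_a = c("A", "A"), orig_b = c("B", "C"))
  sel <- select_mutated_pairs(catalog, fm)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$gene_b, "B")
  expect_equal(sel$n_qualifying, 5)
  # exactly at the frequency threshold does not qualify (strict >)
  fm2 <- fm; fm2["A", 1:5] <- 0.02
  expect_equal(nrow(select_mutated_pairs(catalog, fm2)), 0)
  # randomized instances against the double-loop oracle + monotonicity
  withr::with_seed(22, {
    for (rep in 1:5) {
      genes <- sprintf("G%02d", 1:20)
      fm3 <- matrix(runif(20 * 8, 0, 0.05), 20, 8,
                    dimnames = list(genes, sprintf("CA%02d", 1:8)))
      cat3 <- random_catalog(25, genes)
      sel3 <- select_mutated_pairs(cat3, fm3, 0.02, 3)
      keep <- oracle_mutated_pairs(cat3, fm3, 0.02, 3)
      expect_equal(pair_key_df(sel3), pair_key_df(cat3[keep, ]))
      # lowering either threshold never removes a retained pair
      loose1 <- select_mutated_pairs(cat3, fm3, 0.01, 3)
      loose2 <- select_mutated_pairs(cat3, fm3, 0.02, 2)
      expect_true(all(pair_key_df(sel3) %in% pair_key_df(loose1)))
      expect_true(all(pair_key_df(sel3) %in% pair_key_df(loose2)))
    }
  })
})

test_that("MM/MW/WW assignment partitions the cohort", {
  calls <- data.frame(sample = c("s1", "s1", "s2"),
                      gene = c("A", "B", "A"),
                      cancer = "CA01",
                      variant_class = "missense")
  grp <- assign_mutation_groups(list(gene_a = "A", gene_b = "B"), calls,
                                "CA01", c("s1", "s2", "s3"))
  expect_equal(grp$group, c("MM", "MW", "WW"))
  expect_equal(nrow(grp), 3)           # exhaustive
  expect_equal(anyDuplicated(grp$sample), 0)  # exclusive
})

test_that("variant-class composition tallies calls touching the pair", {
  calls <- data.frame(sample = sprintf("s%d", 1:4), gene = c("A", "A", "A", "B"),
                      cancer = "CA01",
                      variant_class = c("missense", "missense", "missense",
                                        "nonsense"))
  comp <- mutation_type_composition(list(gene_a = "A", gene_b = "B"), calls)
  expect_equal(unname(comp), c(0.75, 0.25, 0, 0, 0))
  expect_equal(sum(comp), 1)
  expect_error(mutation_type_composition(list(gene_a = "X", gene_b = "Y"),
                                         calls), "no mutation calls")
})

test_that("drug association applies the dual effect/p threshold", {
  groups <- data.frame(sample = sprintf("s%03d", 1:100),
                       group = rep(c("MM", "WW"), each = 50))
  withr::with_seed(31, {
    # identical distributions: effect ~ 0, not significant
    dm <- matrix(runif(100), 100, 1, dimnames = list(groups$sample, "d1"))
    da <- drug_association(groups, dm)
    expect_lt(abs(da$effect), 0.2)
    expect_false(da$significant)
    # planted shift 0.3, noise 0.05: flagged
    dm2 <- matrix(pmin(pmax(rnorm(100, 0.4 + 0.3 * (groups$group == "MM"),
                                  0.05), 0), 1),
                  100, 1, dimnames = list(groups$sample, "d2"))
    da2 <- drug_association(groups, dm2)
    expect_true(da2$significant)
    expect_equal(da2$effect, 0.3, tolerance = 0.05)
    # effect 0.08 with tiny p: fails the |effect| > 0.10 arm
    dm3 <- matrix(pmin(pmax(rnorm(100, 0.4 + 0.08 * (groups$group == "MM"),
                                  0.01), 0), 1),
                  100, 1, dimnames = list(groups$sample, "d3"))
    da3 <- drug_association(groups, dm3)
    expect_lt(da3$pvalue, 0.001)
    expect_false(da3$significant)
    # antisymmetry under group exchange
    da_rev <- drug_association(groups, dm2, group_pair = c("WW", "MM"))
    expect_equal(da_rev$effect, -da2$effect)
    # undersized group: drug skipped with a reason
    small <- groups[c(1:2, 51:100), ]
    das <- drug_association(small, dm2)
    expect_equal(nrow(das), 0)
    expect_match(attr(das, "skipped")$reason, "minimum size")
  })
})
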