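# Catalog construction: yeast screen, ortholog transfer, merge, degrees,
# annotation.

write_yeast <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("yeast pair loading applies the score screen and canonicalizes", {
  path <- write_yeast(data.frame(
    gene_a = c("a1", "a2", "a3", "a3", "a5"),
    gene_b = c("b1", "b2", "b3", "b3", "a5"),
    score = c(-0.50, -0.20, -0.40, -0.60, -0.9)))
  out <- load_yeast_pairs(path)
  # -0.50 retained, -0.20 dropped, duplicate collapses to -0.60 (the
  # stronger interaction), self-pair dropped
  expect_equal(nrow(out), 2)
  expect_equal(out$score[out$gene_a == "a1"], -0.50)
  expect_equal(out$score[out$gene_a == "a3"], -0.60)
  # boundary: exactly at the threshold is retained (score <= -0.35)
  p2 <- write_yeast(data.frame(gene_a = "x", gene_b = "y", score = -0.35))
  expect_equal(nrow(load_yeast_pairs(p2)), 1)
  # unordered duplicate given in both orders collapses to one record
  p3 <- write_yeast(data.frame(gene_a = c("A", "B"), gene_b = c("B", "A"),
                               score = c(-0.4, -0.6)))
  out3 <- load_yeast_pairs(p3)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$score, -0.6)
})

test_that("malformed yeast rows fail hard with a line number", {
  path <- write_yeast(data.frame(gene_a = c("a", "b"), gene_b = c("x", "y"),
                                 score = c("-0.5", "oops")))
  expect_error(load_yeast_pairs(path), "line 2")
})

test_that("ortholog transfer expands Cartesian products and counts drops", {
  yp <- data.frame(gene_a = c("ya", "yc", "yd"), gene_b = c("yb", "yb", "yd2"),
                   score = c(-0.5, -0.7, -0.4), stringsAsFactors = FALSE)
  map <- list(ya = c("A1", "A2"), yb = "B1", yd = "X", yd2 = "X")
  out <- map_orthologs(yp, map)
  # (ya,yb) -> {(A1,B1),(A2,B1)}; (yc,yb) unmapped; (yd,yd2) self-pair
  expect_equal(nrow(out), 2)
  expect_setequal(out$gene_a, c("A1", "A2"))
  expect_true(all(out$gene_b == "B1"))
  expect_true(all(out$sources == "yeast_predicted"))
  expect_true(all(out$yeast_score == -0.5))
  drops <- attr(out, "dropped")
  expect_equal(drops$unmapped, 1)
  expect_equal(drops$self, 1)
  # invariant: no yeast_predicted pair without a score at or under -0.35
  expect_true(all(out$yeast_score <= -0.35))
})

test_that("catalog merge unions pairs, merges sources, and is idempotent", {
  y <- data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
                  sources = "yeast_predicted", yeast_score = c(-0.5, -0.4),
                  orig_a = c("A", "C"), orig_b = c("B", "D"),
                  stringsAsFactors = FALSE)
  h <- data.frame(gene_a = c("A", "E", "F"), gene_b = c("B", "F", "G"),
                  source = c("human_validated", "human_predicted",
                             "human_predicted"), stringsAsFactors = FALSE)
  cat <- merge_catalog(y, h)
  expect_equal(nrow(cat), 4)  # AB shared, CD, EF, FG
  ab <- cat[cat$gene_a == "A", ]
  expect_equal(ab$sources, "human_validated;yeast_predicted")
  expect_equal(ab$yeast_score, -0.5)
  s <- attr(cat, "summary")
  expect_setequal(s$genes_common, c("A", "B"))
  expect_setequal(s$genes_yeast_only, c("C", "D"))
  expect_setequal(s$genes_human_only, c("E", "F", "G"))
  # merging a catalog with itself is the identity
  again <- merge_catalog(cat, cat)
  expect_equal(again[names(cat)], cat, ignore_attr = TRUE)
  # self-merge gene partition: everything common
  s2 <- attr(again, "summary")
  expect_equal(length(s2$genes_yeast_only), 0)
  expect_equal(length(s2$genes_human_only), 0)
  expect_setequal(s2$genes_common, unique(c(cat$gene_a, cat$gene_b)))
})

test_that("degree distribution matches a brute-force recount", {
  single <- random_catalog(1, c("A", "B"))
  dd <- degree_distribution(single)
  expect_equal(unname(dd$degree), c(1, 1))
  expect_equal(dd$bins$fraction[dd$bins$bin == "1"], 1.0)
  # a star with 12 partners falls in the 11-50 bin
  star <- data.frame(gene_a = "HUB", gene_b = sprintf("P%02d", 1:12))
  db <- degree_distribution(star)
  expect_equal(unname(db$degree["HUB"]), 12)
  expect_equal(db$bins$n_genes[db$bins$bin == "11-50"], 1)
  withr::with_seed(7, {
    for (rep in 1:5) {
      cat <- random_catalog(200, sprintf("G%03d", 1:60))
      dd <- degree_distribution(cat)
      expect_equal(dd$degree, oracle_degrees(cat))
      # degree conservation: sum of degrees = 2 x pair count
      expect_equal(sum(dd$degree), 2 * nrow(cat))
      expect_equal(sum(dd$bins$fraction), 1)
    }
  })
})

test_that("gene annotation counts characteristics and screens core genes", {
  sets <- list(hallmark = c("A", "B"), cgc = c("A", "B"), essential = c("A", "B"),
               oncogene = c("A", "B", "C"), tsg = c("A"), actionable = c("A", "B"),
               drug_target = c("A", "B"))
  ann <- annotate_genes(c("A", "B", "C", "Z"), sets)
  expect_equal(ann$n_characteristics, c(7L, 6L, 1L, 0L))
  expect_equal(select_core_genes(ann, 4), c("A", "B"))
  expect_equal(select_core_genes(ann, 0), c("A", "B", "C", "Z"))
  expect_error(annotate_genes("A", c(sets, list(bogus = "A"))), "unknown")
  expect_error(annotate_genes("A", sets[-1]), "missing")
  # coverage fractions match brute force on a random instance
  withr::with_seed(11, {
    genes <- sprintf("G%02d", 1:40)
    rsets <- lapply(1:7, function(i) sample(genes, sample(0:20, 1)))
    names(rsets) <- names(sets)
    ann <- annotate_genes(genes, rsets)
    brute <- sapply(genes, function(g)
      sum(vapply(rsets, function(s) g %in% s, logical(1))))
    expect_equal(ann$n_characteristics, unname(brute))
    keep <- genes[brute >= 3]
    expect_equal(select_core_genes(ann, 3), keep[order(-brute[keep], keep)])
  })
})
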