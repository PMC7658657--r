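# isomiR collapse, down-regulated miRNA screen, and network assembly.

iso_table <- function(locus, seqs, counts) {
  data.frame(locus = locus, sequence = seqs, counts,
             stringsAsFactors = FALSE, check.names = FALSE)
}

test_that("isomiR collapse picks the dominant sequence with a stable tie-break", {
  tab <- iso_table(
    c("mir-1", "mir-1", "mir-1", "mir-2"),
    c("ACGUACGU", "ACGUACGA", "ACGUACGG", "UUUGGGCC"),
    rbind(c(60, 40), c(30, 10), c(4, 3), c(9, 9)))
  names(tab)[3:4] <- c("s1", "s2")
  out <- collapse_isomirs(tab)
  expect_equal(out$representative$sequence[out$representative$locus == "mir-1"],
               "ACGUACGU")                     # totals 100 > 40 > 7
  expect_equal(unname(out$expression["mir-1", ]), c(60, 40))
  # single-isomiR locus is its own representative
  expect_equal(out$representative$sequence[out$representative$locus == "mir-2"],
               "UUUGGGCC")
  # tie on totals: lexicographically smallest sequence wins
  tie <- iso_table(c("mir-3", "mir-3"), c("ACGU", "ACGA"),
                   rbind(c(25, 25), c(30, 20)))
  names(tie)[3:4] <- c("s1", "s2")
  out2 <- collapse_isomirs(tie)
  expect_equal(out2$representative$sequence, "ACGA")
  # DNA letters are accepted and normalized to RNA
  dna <- iso_table("mir-4", "ACGTACGT", rbind(c(5, 5)))
  names(dna)[3:4] <- c("s1", "s2")
  expect_equal(collapse_isomirs(dna)$representative$sequence, "ACGUACGU")
  expect_error(collapse_isomirs(iso_table("m", "ACGX", rbind(c(1, 1)))),
               "invalid RNA")
  # all-zero locus collapses by tie-break and is flagged
  zero <- iso_table(c("mir-5", "mir-5"), c("GGGG", "AAAA"),
                    rbind(c(0, 0), c(0, 0)))
  names(zero)[3:4] <- c("s1", "s2")
  out3 <- collapse_isomirs(zero)
  expect_true(out3$representative$all_zero)
  expect_equal(out3$representative$sequence, "AAAA")
})

test_that("isomiR collapse is idempotent", {
  withr::with_seed(71, {
    n <- 10
    tab <- do.call(rbind, lapply(1:6, function(i) {
      k <- sample(1:4, 1)
      iso_table(sprintf("mir-%02d", i),
                replicate(k, paste(sample(c("A", "C", "G", "U"), 21,
                                          replace = TRUE), collapse = "")),
                matrix(rpois(k * n, 50), k, n))
    }))
    names(tab)[-(1:2)] <- sprintf("s%02d", 1:n)
    once <- collapse_isomirs(tab)
    redo_tab <- data.frame(locus = once$representative$locus,
                           sequence = once$representative$sequence,
                           once$expression, check.names = FALSE)
    twice <- collapse_isomirs(redo_tab)
    expect_equal(twice$expression, once$expression)
    expect_equal(twice$representative$sequence, once$representative$sequence)
  })
})

test_that("down-regulated miRNA screen counts cancers strictly", {
  de <- rbind(
    data.frame(gene = "mir-1", cancer = sprintf("CA%02d", 1:4), status = "down"),
    data.frame(gene = "mir-2", cancer = sprintf("CA%02d", 1:3), status = "down"),
    data.frame(gene = "mir-3", cancer = sprintf("CA%02d", 1:6), status = "up"))
  expect_equal(select_down_mirnas(de), "mir-1")       # 4 yes, 3 no, up no
  expect_setequal(select_down_mirnas(de, 0), c("mir-1", "mir-2", "mir-3"))
})

test_that("network assembly respects types, excludes outside targets", {
  net <- build_network(genes = c("A", "B"),
                       sl_edges = data.frame(gene_a = "A", gene_b = "B"),
                       target_map = list("mir-1" = c("A", "B", "OUTSIDE")),
                       selected_mirnas = "mir-1")
  expect_equal(igraph::vcount(net), 3)
  ty <- igraph::edge_attr(net, "edge_type")
  expect_equal(sum(ty == "sl"), 1)
  expect_equal(sum(ty == "targets"), 2)
  expect_equal(igraph::graph_attr(net, "dropped_target_edges"), 1)
  deg <- network_degrees(net)
  expect_equal(unname(deg$mirna_out_degree["mir-1"]), 2)
  expect_equal(sum(deg$mirna_out_degree), sum(ty == "targets"))
  # empty miRNA selection: mRNA-only network
  net2 <- build_network(c("A", "B"), data.frame(gene_a = "A", gene_b = "B"),
                        list(), character(0))
  expect_equal(igraph::vcount(net2), 2)
  expect_equal(igraph::ecount(net2), 1)
})

test_that("network node/edge counts match a constructive oracle", {
  withr::with_seed(72, {
    for (rep in 1:5) {
      genes <- sprintf("G%02d", 1:12)
      mirnas <- sprintf("mir-%02d", 1:5)
      sl <- random_catalog(8, genes)
      tm <- lapply(mirnas, function(m) sample(sprintf("G%02d", 1:20), 4))
      names(tm) <- mirnas
      sel <- sample(mirnas, 3)
      net <- build_network(genes, sl, tm, sel)
      exp_targets <- sum(vapply(sel, function(m)
        length(intersect(tm[[m]], genes)), integer(1)))
      expect_equal(igraph::vcount(net), length(genes) + length(sel))
      expect_equal(igraph::ecount(net), nrow(sl) + exp_targets)
      # structural invariants hold after every build
      el <- igraph::as_edgelist(net)
      ty <- igraph::edge_attr(net, "edge_type")
      expect_true(all(el[ty == "targets", 1] %in% sel))
      expect_true(all(el[ty == "targets", 2] %in% genes))
      expect_false(any(el[, 1] == el[, 2]))
    }
  })
})

test_that("network summary reports pathway coverage", {
  net <- build_network(sprintf("G%02d", 1:12),
                       data.frame(gene_a = "G01", gene_b = "G02"),
                       list(), character(0))
  sets <- list(cell_cycle = sprintf("G%02d", 1:7),
               unrelated = c("X1", "X2"))
  ns <- network_summary(net, sets)
  cc <- ns$pathways[ns$pathways$pathway == "cell_cycle", ]
  expect_equal(cc$n_in_set, 7)                       # seven of 12
  expect_equal(cc$n_network_genes, 12)
  expect_equal(ns$pathways$n_in_set[ns$pathways$pathway == "unrelated"], 0)
})

test_that("network exports write readable GraphML and SIF", {
  net <- build_network(c("A", "B"), data.frame(gene_a = "A", gene_b = "B"),
                       list("mir-1" = "A"), "mir-1")
  gpath <- tempfile(fileext = ".graphml")
  spath <- tempfile(fileext = ".sif")
  write_graphml(net, gpath)
  write_sif(net, spath)
  back <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  sif <- readLines(spath)
  expect_setequal(sif, c("A\tsl\tB", "mir-1\ttargets\tA"))
})
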