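# isomiR collapse, miRNA differential expression, down-regulated miRNA
# screening, and assembly of the miRNA-mRNA-SL regulatory network.
#
# An isomiR table is a data.frame with columns locus, sequence, then one
# numeric column per sample. A miRNA locus expresses multiple sequence
# variants (isomiRs); the locus is summarised by its dominant (most
# abundant) isomiR.

# Normalise an RNA sequence: uppercase, T -> U, validate alphabet.
normalize_rna <- function(seq) {
  s <- chartr("t", "u", chartr("T", "U", toupper(seq)))
  bad <- grepl("[^ACGU]", s)
  if (any(bad))
    stop("invalid RNA sequence(s): ", paste(utils::head(seq[bad], 3), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(s))) stop("empty isomiR sequence", call. = FALSE)
  s
}

#' Collapse isomiR tables to the dominant sequence per locus
#'
#' The representative of each miRNA locus is the isomiR with the largest
#' total count across the cohort; ties break to the lexicographically
#' smallest sequence. The representative's per-sample counts become the
#' locus expression vector. Loci whose isomiRs are all zero are collapsed
#' by the tie-break and flagged.
#'
#' @param records data.frame with columns locus, sequence, then per-sample
#'   count columns. T is accepted in sequences and normalized to U.
#' @return list with `expression` (locus x sample numeric matrix),
#'   `representative` (data.frame locus, sequence, total, all_zero).
#' @export
collapse_isomirs <- function(records) {
  stop_cols(records, c("locus", "sequence"), "isomiR table")
  samples <- setdiff(names(records), c("locus", "sequence"))
  if (!length(samples)) stop("isomiR table has no sample columns", call. = FALSE)
  records$sequence <- normalize_rna(records$sequence)
  counts <- as.matrix(records[, samples, drop = FALSE])
  if (any(counts < 0)) stop("negative isomiR counts", call. = FALSE)
  totals <- rowSums(counts)
  loci <- unique(records$locus)
  rep_idx <- vapply(loci, function(l) {
    idx <- which(records$locus == l)
    best <- idx[totals[idx] == max(totals[idx])]
    best[order(records$sequence[best])][1]
  }, integer(1))
  expr <- counts[rep_idx, , drop = FALSE]
  rownames(expr) <- loci
  list(expression = expr,
       representative = data.frame(locus = loci,
                                   sequence = records$sequence[rep_idx],
                                   total = totals[rep_idx],
                                   all_zero = totals[rep_idx] == 0,
                                   row.names = NULL, stringsAsFactors = FALSE))
}

#' Differential expression of collapsed miRNA loci
#'
#' Thin delegation to [de_test()] on the dominant-isomiR expression
#' matrix, with the same contracts and thresholds.
#'
#' @param collapsed locus x sample matrix (from [collapse_isomirs()]
#'   `$expression`, or equivalent).
#' @param labels "tumor"/"normal" per column.
#' @param ... passed to [de_test()] (fc_cut, alpha, cancer).
#' @return data.frame as from [de_test()].
#' @export
mirna_de <- function(collapsed, labels, ...) {
  de_test(collapsed, labels, ...)
}

#' Select miRNAs down-regulated in several cancer types
#'
#' @param de row-bound miRNA DE results across cancers (gene = locus).
#' @param min_down_cancers minimum cancers with status "down" (default 4).
#' @return sorted character vector of miRNA loci.
#' @export
select_down_mirnas <- function(de, min_down_cancers = 4L) {
  stop_cols(de, c("gene", "cancer", "status"), "miRNA DE results")
  n_down <- tapply(de$status == "down", de$gene, sum)
  sort(names(n_down)[n_down >= min_down_cancers])
}

#' Assemble the miRNA-mRNA-SL regulatory network
#'
#' Typed graph: mRNA nodes (the screened genes) joined by undirected `sl`
#' edges, and miRNA nodes (the selected down-regulated miRNAs) joined to
#' their target genes by directed `targets` edges. Target edges pointing
#' outside the screened gene list are excluded and counted; self-loops
#' and duplicate typed edges never occur by construction.
#'
#' @param genes character vector of screened mRNA gene symbols.
#' @param sl_edges data.frame gene_a, gene_b (must lie within `genes`;
#'   rows outside are dropped and counted).
#' @param target_map named list: miRNA -> character vector of target genes.
#' @param selected_mirnas character vector of miRNAs to include.
#' @param annotations optional data.frame from [annotate_genes()]; flags
#'   are attached as node attributes.
#' @param status_matrix optional `sl_dysreg` object; each gene node gets a
#'   per-cancer expression-status string attribute.
#' @return igraph object with vertex attributes `node_type`
#'   ("mRNA"/"miRNA"), `essential`, `n_characteristics`, `expr_status`,
#'   and edge attribute `edge_type` ("sl"/"targets"); graph attribute
#'   `dropped_target_edges` counts excluded target edges.
#' @export
build_network <- function(genes, sl_edges, target_map, selected_mirnas,
                          annotations = NULL, status_matrix = NULL) {
  genes <- unique(genes)
  sl <- sl_edges[sl_edges$gene_a %in% genes & sl_edges$gene_b %in% genes &
                   sl_edges$gene_a != sl_edges$gene_b, , drop = FALSE]
  sl_keys <- unique(pair_key(sl$gene_a, sl$gene_b))
  dropped <- 0L
  tgt <- list()
  for (mi in intersect(selected_mirnas, names(target_map))) {
    targets <- unique(target_map[[mi]])
    inside <- targets[targets %in% genes]
    dropped <- dropped + length(targets) - length(inside)
    if (length(inside))
      tgt[[mi]] <- data.frame(from = mi, to = inside, stringsAsFactors = FALSE)
  }
  mirnas <- intersect(selected_mirnas, names(target_map))
  edges_sl <- if (length(sl_keys)) do.call(rbind, strsplit(sl_keys, "|", fixed = TRUE))
  tgt_df <- if (length(tgt)) do.call(rbind, tgt)
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(genes), name = genes, node_type = "mRNA")
  g <- igraph::add_vertices(g, length(mirnas), name = mirnas, node_type = "miRNA")
  if (!is.null(edges_sl)) {
    # sl edges are undirected in meaning; stored once, canonical direction
    g <- igraph::add_edges(g, as.vector(t(edges_sl)), edge_type = "sl")
  }
  if (!is.null(tgt_df))
    g <- igraph::add_edges(g, as.vector(t(as.matrix(tgt_df))),
                           edge_type = "targets")
  if (!is.null(annotations)) {
    idx <- match(genes, annotations$gene)
    ess <- annotations$essential[idx]
    nch <- annotations$n_characteristics[idx]
    g <- igraph::set_vertex_attr(g, "essential",
                                 index = genes, value = ifelse(is.na(ess), FALSE, ess))
    g <- igraph::set_vertex_attr(g, "n_characteristics",
                                 index = genes, value = ifelse(is.na(nch), 0L, nch))
  }
  if (!is.null(status_matrix)) {
    st <- status_matrix$status
    val <- vapply(genes, function(gn) {
      if (gn %in% rownames(st))
        paste(paste0(colnames(st), ":", st[gn, ]), collapse = ";")
      else ""
    }, character(1))
    g <- igraph::set_vertex_attr(g, "expr_status", index = genes, value = val)
  }
  g <- igraph::set_graph_attr(g, "dropped_target_edges", dropped)
  stopifnot(all(igraph::degree(g, mode = "all") >= 0))
  assert_network_invariants(g)
  g
}

# Structural invariants of a regulatory network: sl edges between mRNA
# nodes only, targets edges miRNA -> mRNA only, no self-loops, no
# duplicate typed edges.
assert_network_invariants <- function(g) {
  if (!igraph::ecount(g)) return(invisible(TRUE))
  el <- igraph::as_edgelist(g)
  ty <- igraph::edge_attr(g, "edge_type")
  ntype <- stats::setNames(igraph::vertex_attr(g, "node_type"),
                           igraph::vertex_attr(g, "name"))
  if (any(el[, 1] == el[, 2])) stop("network has self-loops", call. = FALSE)
  sl <- ty == "sl"
  if (any(ntype[el[sl, 1]] != "mRNA" | ntype[el[sl, 2]] != "mRNA"))
    stop("sl edge touching a non-mRNA node", call. = FALSE)
  tg <- ty == "targets"
  if (any(ntype[el[tg, 1]] != "miRNA" | ntype[el[tg, 2]] != "mRNA"))
    stop("targets edge must run miRNA -> mRNA", call. = FALSE)
  key <- paste(ty, ifelse(sl, pair_key(el[, 1], el[, 2]),
                          paste(el[, 1], el[, 2], sep = "|")))
  if (anyDuplicated(key)) stop("duplicate typed edge", call. = FALSE)
  invisible(TRUE)
}

#' Pathway coverage and characteristic tallies of a network
#'
#' @param net igraph object from [build_network()].
#' @param pathway_sets named list of gene sets (e.g. KEGG memberships read
#'   from GMT; membership is an input, not computed here).
#' @return list(pathways = data.frame(pathway, n_in_set, n_network_genes,
#'   genes), characteristics = named tally over mRNA node flags).
#' @export
network_summary <- function(net, pathway_sets) {
  nm <- igraph::vertex_attr(net, "name")
  mrna <- nm[igraph::vertex_attr(net, "node_type") == "mRNA"]
  path <- do.call(rbind, lapply(names(pathway_sets), function(p) {
    hit <- sort(intersect(mrna, pathway_sets[[p]]))
    data.frame(pathway = p, n_in_set = length(hit),
               n_network_genes = length(mrna),
               genes = paste(hit, collapse = ";"), stringsAsFactors = FALSE)
  }))
  ess <- igraph::vertex_attr(net, "essential")
  tallies <- c(n_mrna = length(mrna),
               n_mirna = sum(igraph::vertex_attr(net, "node_type") == "miRNA"),
               n_essential = if (is.null(ess)) NA_integer_ else
                 sum(ess[igraph::vertex_attr(net, "node_type") == "mRNA"],
                     na.rm = TRUE))
  list(pathways = path, characteristics = tallies)
}

#' Degree report of a regulatory network
#'
#' @param net igraph object from [build_network()].
#' @return list(mirna_out_degree, gene_in_degree): named integer vectors
#'   counting `targets` edges only.
#' @export
network_degrees <- function(net) {
  if (!igraph::ecount(net)) {
    return(list(mirna_out_degree = integer(0), gene_in_degree = integer(0)))
  }
  el <- igraph::as_edgelist(net)
  ty <- igraph::edge_attr(net, "edge_type")
  tg <- el[ty == "targets", , drop = FALSE]
  list(mirna_out_degree = if (nrow(tg)) table(tg[, 1]) else integer(0),
       gene_in_degree = if (nrow(tg)) table(tg[, 2]) else integer(0))
}
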