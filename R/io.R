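# Readers and writers for the pipeline's plain-text interchange formats.
# All tables are tab-separated; pipeline outputs carry "#"-prefixed header
# lines stamping the active config hash and seed.

#' Write a table as stamped TSV
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param stamp optional named list written as `# key=value` header lines
#'   (config hash, seed, active thresholds).
#' @return `path`, invisibly.
#' @export
write_stamped_tsv <- function(df, path, stamp = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(stamp))
    writeLines(sprintf("# %s=%s", names(stamp),
                       vapply(stamp, function(v) paste(format(v), collapse = ","),
                              character(1))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a (possibly stamped) TSV
#'
#' @param path file path; `#` lines are treated as comments.
#' @return data.frame.
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read named gene sets from a GMT file
#'
#' Standard Gene Matrix Transposed format: one set per line, fields
#' name, description, then members, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  fgsea::gmtPathways(path)
}

#' Write named gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of per-set descriptions
#'   (defaults to "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene x sample count matrix with its condition sidecar
#'
#' The matrix TSV has a `gene` column then one column per sample; the
#' sidecar TSV has columns `sample`, `condition` with condition in
#' {tumor, normal}.
#'
#' @param counts_path matrix TSV.
#' @param sidecar_path condition sidecar TSV.
#' @return list with `counts` (integer matrix, genes x samples) and
#'   `condition` (character vector aligned to columns).
#' @export
read_count_matrix <- function(counts_path, sidecar_path) {
  tab <- read_tsv_file(counts_path)
  stop_cols(tab, "gene", "count matrix")
  m <- as.matrix(tab[, setdiff(names(tab), "gene"), drop = FALSE])
  rownames(m) <- tab$gene
  storage.mode(m) <- "double"
  side <- read_tsv_file(sidecar_path)
  stop_cols(side, c("sample", "condition"), "condition sidecar")
  if (!all(colnames(m) %in% side$sample))
    stop("condition sidecar does not cover all samples", call. = FALSE)
  cond <- side$condition[match(colnames(m), side$sample)]
  if (!all(cond %in% c("tumor", "normal")))
    stop("conditions must be 'tumor' or 'normal'", call. = FALSE)
  list(counts = m, condition = cond)
}

#' Write a count matrix and its condition sidecar
#'
#' @param counts genes x samples matrix with dimnames.
#' @param condition character vector per column.
#' @param counts_path,sidecar_path output files.
#' @param stamp optional header stamp (see [write_stamped_tsv()]).
#' @return `counts_path`, invisibly.
#' @export
write_count_matrix <- function(counts, condition, counts_path, sidecar_path,
                               stamp = NULL) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write_stamped_tsv(df, counts_path, stamp)
  write_stamped_tsv(data.frame(sample = colnames(counts), condition = condition),
                    sidecar_path, stamp)
  invisible(counts_path)
}

#' Export a regulatory network in SIF format
#'
#' One interaction per line: `source <edge_type> target`. SL edges are
#' written once per unordered pair; targets edges as miRNA -> gene.
#'
#' @param net an igraph object as built by [build_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  el <- igraph::as_edgelist(net)
  ty <- igraph::edge_attr(net, "edge_type")
  writeLines(paste(el[, 1], ty, el[, 2], sep = "\t"), path)
  invisible(path)
}

#' Export a regulatory network as GraphML
#'
#' @param net an igraph object as built by [build_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
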