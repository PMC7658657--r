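# Pipeline orchestration: run the full screening cascade from a YAML (or
# list) configuration, emit stamped outputs and a per-stage record-count
# report, and build the packaged synthetic fixture with a brute-force
# reference manifest.

#' Default pipeline thresholds
#'
#' The screening defaults: yeast score <= -0.35; mutation frequency > 0.02
#' in >= 5 cancers; |log2FC| > 1.5 with padj < 0.05, dysregulated in
#' >= 11 cancers; drug effect > 0.10 at p < 0.05 with FDR < 0.10;
#' randomization B = 1000; miRNAs down in >= 4 cancers; high-mutation cut
#' 0.03; core genes with >= 4 characteristics.
#'
#' @return named list of threshold values.
#' @export
default_thresholds <- function() {
  list(yeast_score = -0.35, min_freq = 0.02, min_mut_cancers = 5L,
       fc_cut = 1.5, alpha = 0.05, min_dysreg_cancers = 11L,
       effect_cut = 0.10, fdr_cut = 0.10, B = 1000L,
       min_down_cancers = 4L, high_freq = 0.03, min_characteristics = 4L,
       z_cut = 1.96, min_group = 5L)
}

#' Read a MAF-subset mutation file
#'
#' Columns Hugo_Symbol, Tumor_Sample_Barcode, Variant_Classification,
#' cancer_type are mapped to the internal call schema.
#'
#' @param path MAF-subset TSV.
#' @return data.frame sample, gene, cancer, variant_class.
#' @export
read_maf <- function(path) {
  tab <- read_tsv_file(path)
  stop_cols(tab, c("Hugo_Symbol", "Tumor_Sample_Barcode",
                   "Variant_Classification", "cancer_type"), "MAF file")
  data.frame(sample = tab$Tumor_Sample_Barcode, gene = tab$Hugo_Symbol,
             cancer = tab$cancer_type,
             variant_class = tab$Variant_Classification,
             stringsAsFactors = FALSE)
}

#' Write mutation calls as a MAF-subset TSV
#'
#' @param calls data.frame sample, gene, cancer, variant_class.
#' @param path output TSV.
#' @param stamp optional header stamp.
#' @return `path`, invisibly.
#' @export
write_maf <- function(calls, path, stamp = NULL) {
  write_stamped_tsv(data.frame(Hugo_Symbol = calls$gene,
                               Tumor_Sample_Barcode = calls$sample,
                               Variant_Classification = calls$variant_class,
                               cancer_type = calls$cancer,
                               stringsAsFactors = FALSE),
                    path, stamp)
}

stage_report_row <- function(stage, records_in, records_out, thresholds,
                             runtime) {
  data.frame(stage = stage, records_in = records_in,
             records_out = records_out,
             thresholds = paste(names(thresholds), unlist(thresholds),
                                sep = "=", collapse = ";"),
             runtime_seconds = runtime, stringsAsFactors = FALSE)
}

#' Run the full screening pipeline
#'
#' Stages, in dependency order: catalog construction (yeast transfer +
#' human merge), gene annotation and core-gene screen, mutation screen,
#' per-cancer differential expression and the dysregulation screen, the
#' combined screen with positional and high-mutation summaries, optional
#' survival scan / randomization / drug association, and the miRNA
#' network. Every output is stamped with the config hash and seed; rerun
#' with identical config and inputs is byte-identical (per-stage runtimes
#' live only in the returned report, not in any file).
#'
#' @param config a list, or path to a YAML file, with elements `seed`,
#'   `out_dir`, `inputs` (file paths), and optionally `thresholds`
#'   (defaults from [default_thresholds()]) and `run` (stage switches:
#'   survival, randomization_B, drugs, network).
#' @return list with the result objects of each stage and `report`
#'   (data.frame of StageReport rows). Output files are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  thr <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  run <- utils::modifyList(list(survival = TRUE, randomization_B = 0L,
                                drugs = TRUE, network = TRUE),
                           config$run %||% list())
  seed <- config$seed %||% 1L
  inp <- config$inputs
  required <- c("yeast_pairs", "ortholog_map", "human_pairs",
                "characteristics_gmt", "maf", "cohort_sizes", "counts_dir")
  for (f in required)
    if (is.null(inp[[f]])) stop("config$inputs$", f, " is missing", call. = FALSE)
  paths <- unlist(inp[vapply(inp, is.character, logical(1))])
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out_dir <- config$out_dir %||% stop("config$out_dir is missing", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = config_hash(config[c("inputs", "thresholds", "seed")]),
                seed = seed)
  report <- list()
  tic <- function() proc.time()[["elapsed"]]
  res <- list()

  # --- stage: catalog ----------------------------------------------------
  t0 <- tic()
  yeast <- load_yeast_pairs(inp$yeast_pairs, score_threshold = thr$yeast_score)
  ortho <- read_tsv_file(inp$ortholog_map)
  transferred <- map_orthologs(yeast, ortho)
  human <- read_tsv_file(inp$human_pairs)
  catalog <- merge_catalog(transferred, human)
  write_stamped_tsv(catalog, file.path(out_dir, "catalog.tsv"), stamp)
  report$catalog <- stage_report_row("catalog",
                                     nrow(yeast) + nrow(human), nrow(catalog),
                                     thr["yeast_score"], tic() - t0)
  res$catalog <- catalog

  # --- stage: annotation -------------------------------------------------
  t0 <- tic()
  sets <- read_gmt(inp$characteristics_gmt)
  genes <- sort(unique(c(catalog$gene_a, catalog$gene_b)))
  ann <- annotate_genes(genes, sets)
  core <- select_core_genes(ann, thr$min_characteristics)
  write_stamped_tsv(data.frame(gene = core, stringsAsFactors = FALSE),
                    file.path(out_dir, "core_genes.tsv"), stamp)
  report$annotation <- stage_report_row("annotation", length(genes),
                                        length(core),
                                        thr["min_characteristics"], tic() - t0)
  res$annotations <- ann
  res$core_genes <- core
  res$degree <- degree_distribution(catalog)

  # --- stage: mutation screen --------------------------------------------
  t0 <- tic()
  calls <- read_maf(inp$maf)
  cs_tab <- read_tsv_file(inp$cohort_sizes)
  stop_cols(cs_tab, c("cancer", "n"), "cohort size table")
  cohort_sizes <- stats::setNames(as.integer(cs_tab$n), cs_tab$cancer)
  freqs <- mutation_frequency(calls, cohort_sizes)
  mutated <- select_mutated_pairs(catalog, freqs, thr$min_freq,
                                  thr$min_mut_cancers)
  write_stamped_tsv(freqs, file.path(out_dir, "mutation_frequencies.tsv"), stamp)
  write_stamped_tsv(mutated, file.path(out_dir, "mutated_pairs.tsv"), stamp)
  report$mutation_screen <- stage_report_row("mutation_screen", nrow(catalog),
                                             nrow(mutated),
                                             thr[c("min_freq", "min_mut_cancers")],
                                             tic() - t0)
  res$calls <- calls
  res$freqs <- freqs
  res$mutated_pairs <- mutated

  # --- stage: expression screen ------------------------------------------
  t0 <- tic()
  count_files <- sort(list.files(inp$counts_dir, pattern = "_counts\\.tsv$",
                                 full.names = TRUE))
  if (!length(count_files))
    stop("no *_counts.tsv files under ", inp$counts_dir, call. = FALSE)
  de_all <- lapply(count_files, function(f) {
    cc <- sub("_counts\\.tsv$", "", basename(f))
    cm <- read_count_matrix(f, file.path(inp$counts_dir,
                                         paste0(cc, "_conditions.tsv")))
    de_test(cm$counts, cm$condition, fc_cut = thr$fc_cut, alpha = thr$alpha,
            cancer = cc)
  })
  dys <- build_dysregulation_matrix(de_all)
  dys_genes <- select_dysregulated_genes(dys, thr$min_dysreg_cancers)
  dys_pairs <- select_dysregulated_pairs(catalog, dys_genes)
  write_stamped_tsv(data.frame(gene = rownames(dys$status), dys$status,
                               check.names = FALSE),
                    file.path(out_dir, "dysregulation_matrix.tsv"), stamp)
  write_stamped_tsv(data.frame(gene = dys_genes),
                    file.path(out_dir, "dysregulated_genes.tsv"), stamp)
  write_stamped_tsv(dys_pairs, file.path(out_dir, "dysregulated_pairs.tsv"),
                    stamp)
  report$expression_screen <- stage_report_row(
    "expression_screen", nrow(catalog), nrow(dys_pairs),
    thr[c("fc_cut", "alpha", "min_dysreg_cancers")], tic() - t0)
  res$de <- do.call(rbind, de_all)
  res$dysregulation <- dys
  res$dysregulated_genes <- dys_genes
  res$dysregulated_pairs <- dys_pairs

  # --- stage: combined screen --------------------------------------------
  t0 <- tic()
  combined <- select_combined_pairs(catalog, freqs, dys, thr$min_freq,
                                    thr$min_mut_cancers, thr$min_dysreg_cancers)
  pos <- positional_summary(combined, dys)
  high <- high_mutation_subset(combined, freqs, thr$high_freq)
  write_stamped_tsv(combined, file.path(out_dir, "combined_pairs.tsv"), stamp)
  write_stamped_tsv(high, file.path(out_dir, "high_mutation_pairs.tsv"), stamp)
  report$combined_screen <- stage_report_row(
    "combined_screen", nrow(catalog), nrow(combined),
    thr[c("min_freq", "min_mut_cancers", "min_dysreg_cancers")], tic() - t0)
  res$combined_pairs <- combined
  res$positional <- pos
  res$high_mutation_pairs <- high

  # --- stage: survival (optional) ----------------------------------------
  if (isTRUE(run$survival) && !is.null(inp$clinical)) {
    t0 <- tic()
    clinical <- read_tsv_file(inp$clinical)
    surv_cancer <- config$survival_cancer %||% clinical$cancer[1]
    cl <- clinical[clinical$cancer == surv_cancer, , drop = FALSE]
    cohort <- cl$sample
    builder <- function(a, b) {
      grp <- assign_mutation_groups(list(gene_a = a, gene_b = b), calls,
                                    surv_cancer, cohort)
      stats::setNames(grp$group, grp$sample)
    }
    scan_pairs <- if (nrow(mutated)) mutated else catalog
    scan <- pair_prognostic_scan(scan_pairs, builder, cl,
                                 scheme = config$survival_scheme %||% "two_group",
                                 alpha = thr$alpha, min_group = thr$min_group)
    write_stamped_tsv(scan$per_pair, file.path(out_dir, "survival_scan.tsv"),
                      stamp)
    report$survival <- stage_report_row("survival", nrow(scan_pairs),
                                        scan$n_significant,
                                        thr[c("alpha", "min_group")], tic() - t0)
    res$survival_scan <- scan
    B <- as.integer(run$randomization_B %||% 0L)
    if (B > 0L && nrow(scan_pairs)) {
      t0 <- tic()
      rnd <- randomization_test(scan_pairs, genes, catalog, cl, builder,
                                B = B, seed = seed,
                                scheme = config$survival_scheme %||% "two_group",
                                alpha = thr$alpha, min_group = thr$min_group)
      jsonlite::write_json(list(observed = rnd$observed_stat, B = rnd$B,
                                seed = rnd$seed, scheme = rnd$scheme,
                                empirical_p = rnd$empirical_p,
                                null_mean = mean(rnd$null_stats),
                                null_max = max(rnd$null_stats)),
                           file.path(out_dir, "randomization.json"),
                           auto_unbox = TRUE, digits = NA)
      report$randomization <- stage_report_row("randomization", nrow(scan_pairs),
                                               rnd$B, thr["alpha"], tic() - t0)
      res$randomization <- rnd
    }
  }

  # --- stage: drug association (optional) --------------------------------
  if (isTRUE(run$drugs) && !is.null(inp$drug_matrix) &&
      (!is.null(config$drug_pair) || nrow(mutated))) {
    t0 <- tic()
    dm_tab <- read_tsv_file(inp$drug_matrix)
    dm <- as.matrix(dm_tab[, -1, drop = FALSE])
    rownames(dm) <- dm_tab[[1]]
    drug_cancer <- config$drug_cancer %||% calls$cancer[1]
    cohort <- rownames(dm)
    pair <- if (!is.null(config$drug_pair))
      list(gene_a = config$drug_pair[[1]], gene_b = config$drug_pair[[2]])
    else mutated[1, ]
    grp <- assign_mutation_groups(pair, calls, drug_cancer, cohort)
    da <- drug_association(grp, dm, c("MM", "WW"), thr$effect_cut,
                           thr$alpha, thr$fdr_cut)
    write_stamped_tsv(da, file.path(out_dir, "drug_association.tsv"), stamp)
    report$drugs <- stage_report_row("drug_association", ncol(dm),
                                     sum(da$significant),
                                     thr[c("effect_cut", "alpha", "fdr_cut")],
                                     tic() - t0)
    res$drug_association <- da
  }

  # --- stage: miRNA network (optional) -----------------------------------
  if (isTRUE(run$network) && !is.null(inp$isomir_dir) &&
      !is.null(inp$target_map)) {
    t0 <- tic()
    iso_files <- sort(list.files(inp$isomir_dir, pattern = "_isomirs\\.tsv$",
                                 full.names = TRUE))
    mirna_de_all <- lapply(iso_files, function(f) {
      cc <- sub("_isomirs\\.tsv$", "", basename(f))
      tab <- read_tsv_file(f)
      side <- read_tsv_file(file.path(inp$isomir_dir,
                                      paste0(cc, "_conditions.tsv")))
      collapsed <- collapse_isomirs(tab)
      cond <- side$condition[match(colnames(collapsed$expression), side$sample)]
      mirna_de(collapsed$expression, cond, fc_cut = thr$fc_cut,
               alpha = thr$alpha, cancer = cc)
    })
    mirna_de_tab <- do.call(rbind, mirna_de_all)
    down <- select_down_mirnas(mirna_de_tab, thr$min_down_cancers)
    tm_tab <- read_tsv_file(inp$target_map)
    stop_cols(tm_tab, c("mirna", "gene"), "target map")
    target_map <- split(tm_tab$gene, tm_tab$mirna)
    net_pairs <- if (nrow(high)) high else combined
    net_genes <- unique(c(net_pairs$gene_a, net_pairs$gene_b))
    net <- build_network(net_genes, net_pairs, target_map, down,
                         annotations = ann, status_matrix = dys)
    write_graphml(net, file.path(out_dir, "network.graphml"))
    write_sif(net, file.path(out_dir, "network.sif"))
    write_stamped_tsv(data.frame(mirna = down),
                      file.path(out_dir, "down_mirnas.tsv"), stamp)
    if (!is.null(inp$pathways_gmt)) {
      ns <- network_summary(net, read_gmt(inp$pathways_gmt))
      write_stamped_tsv(ns$pathways,
                        file.path(out_dir, "network_summary.tsv"), stamp)
      res$network_summary <- ns
    }
    report$network <- stage_report_row("mirna_network",
                                       length(net_genes) + length(down),
                                       igraph::ecount(net),
                                       thr["min_down_cancers"], tic() - t0)
    res$mirna_de <- mirna_de_tab
    res$down_mirnas <- down
    res$network <- net
  }

  report <- do.call(rbind, report)
  rownames(report) <- NULL
  # runtimes stay out of the written report so reruns are byte-identical
  write_stamped_tsv(report[, setdiff(names(report), "runtime_seconds")],
                    file.path(out_dir, "stage_report.tsv"), stamp)
  res$report <- report
  invisible(res)
}
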