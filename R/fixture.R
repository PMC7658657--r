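# Packaged synthetic fixture: a complete small dataset generated with
# planted truth, written as plain-text pipeline inputs together with a
# manifest of expected stage counts. The manifest is frozen at build time
# from an independent brute-force reference run (explicit loops,
# stats::t.test / survival::survdiff primitives), not from the pipeline's
# own code paths, so the fixture regression test is a genuine dual route.

# ---- reference implementations (loops, deliberately naive) -------------

ref_read_pairskey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

ref_catalog_keys <- function(yeast_path, ortho_path, human_path, score_thr) {
  y <- utils::read.delim(yeast_path, comment.char = "#")
  o <- utils::read.delim(ortho_path, comment.char = "#")
  h <- utils::read.delim(human_path, comment.char = "#")
  keys <- character(0)
  for (i in seq_len(nrow(y))) {
    if (y$score[i] > score_thr || y$gene_a[i] == y$gene_b[i]) next
    ha <- o$human_gene[o$yeast_gene == y$gene_a[i]]
    hb <- o$human_gene[o$yeast_gene == y$gene_b[i]]
    for (ga in ha) for (gb in hb)
      if (ga != gb) keys <- c(keys, ref_read_pairskey(ga, gb))
  }
  for (i in seq_len(nrow(h)))
    if (h$gene_a[i] != h$gene_b[i])
      keys <- c(keys, ref_read_pairskey(h$gene_a[i], h$gene_b[i]))
  unique(keys)
}

ref_core_genes <- function(genes, gmt_path, min_char) {
  lines <- readLines(gmt_path)
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  n <- vapply(genes, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), integer(1))
  genes[n >= min_char]
}

ref_freq_matrix <- function(maf_path, cohort_path) {
  maf <- utils::read.delim(maf_path, comment.char = "#")
  coh <- utils::read.delim(cohort_path, comment.char = "#")
  genes <- sort(unique(maf$Hugo_Symbol))
  m <- matrix(0, length(genes), nrow(coh),
              dimnames = list(genes, coh$cancer))
  for (g in genes) for (cc in coh$cancer) {
    sub <- maf[maf$Hugo_Symbol == g & maf$cancer_type == cc, ]
    m[g, cc] <- length(unique(sub$Tumor_Sample_Barcode)) /
      coh$n[coh$cancer == cc]
  }
  m
}

ref_de_status <- function(counts_path, cond_path, fc_cut, alpha) {
  tab <- utils::read.delim(counts_path, comment.char = "#", check.names = FALSE)
  side <- utils::read.delim(cond_path, comment.char = "#")
  m <- as.matrix(tab[, -1]); rownames(m) <- tab$gene
  cond <- side$condition[match(colnames(m), side$sample)]
  # size factors, naive median-of-ratios
  ref <- apply(m, 1, function(r) all(r > 0))
  geo <- apply(m[ref, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  sf <- apply(m[ref, , drop = FALSE], 2, function(col) stats::median(col / geo))
  norm <- sweep(m, 2, sf, "/")
  lg <- log2(norm + 1)
  p <- numeric(nrow(m)); fc <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    xt <- lg[i, cond == "tumor"]; xn <- lg[i, cond == "normal"]
    fc[i] <- log2((mean(norm[i, cond == "tumor"]) + 1) /
                    (mean(norm[i, cond == "normal"]) + 1))
    p[i] <- if (stats::sd(xt) == 0 && stats::sd(xn) == 0) {
      if (abs(mean(xt) - mean(xn)) < 1e-12) 1 else 0
    } else stats::t.test(xt, xn)$p.value
  }
  padj <- stats::p.adjust(p, "BH")
  status <- rep("normal", nrow(m))
  status[fc > fc_cut & padj < alpha] <- "up"
  status[fc < -fc_cut & padj < alpha] <- "down"
  stats::setNames(status, rownames(m))
}

ref_collapse_status <- function(iso_path, cond_path, fc_cut, alpha) {
  tab <- utils::read.delim(iso_path, comment.char = "#", check.names = FALSE)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  rows <- list()
  for (l in unique(tab$locus)) {
    sub <- tab[tab$locus == l, ]
    tot <- rowSums(sub[, -(1:2)])
    best <- which(tot == max(tot))
    best <- best[order(sub$sequence[best])][1]
    rows[[l]] <- data.frame(gene = l, sub[best, -(1:2)], check.names = FALSE)
  }
  collapsed <- do.call(rbind, rows)
  utils::write.table(collapsed, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ref_de_status(tmp, cond_path, fc_cut, alpha)
}

# ---- fixture builder ----------------------------------------------------

#' Build the packaged synthetic fixture
#'
#' Generates a complete small synthetic dataset (planted truth, all
#' pipeline input files, a ready-to-run YAML config) under `out_dir`, and
#' freezes a manifest of expected stage counts computed by an independent
#' brute-force reference pass over the written files.
#'
#' @param seed integer seed (default 1).
#' @param out_dir output directory (created if needed).
#' @return list(dir, config_path, manifest_path, manifest, truth),
#'   invisibly. `manifest` holds the frozen expected counts and the
#'   planted combined pairs.
#' @export
make_fixture <- function(seed = 1L, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "counts"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "isomirs"), showWarnings = FALSE)
  thr <- default_thresholds()

  cfg <- sl_sim_config(n_genes = 120L, n_cancers = 12L,
                       n_background_pairs = 25L, n_mutation_signal = 2L,
                       n_expression_signal = 2L, n_combined_signal = 3L,
                       mut_rate_signal = 0.30, mut_rate_background = 0.005,
                       n_mut_cancers = 6L, de_effect_signal = 2.5,
                       n_de_cancers = 12L, n_prognostic = 4L,
                       prognostic_hr = 3, n_mirnas = 8L,
                       isomirs_per_locus = 3L, dominant_prop = 0.7,
                       n_down_mirnas = 3L, n_mirna_down_cancers = 5L,
                       mirna_de_effect = -2, targets_per_mirna = 4L,
                       n_drugs = 6L, n_drug_signal = 2L, drug_effect = 0.3,
                       characteristic_coverage = 0.35)
  truth <- generate_truth(cfg, seed)

  # --- pair sources ------------------------------------------------------
  yp <- truth$sl_pairs[truth$sl_pairs$sources == "yeast_predicted", ]
  n_y <- nrow(yp)
  yeast <- data.frame(gene_a = sprintf("Y%03dA", seq_len(n_y)),
                      gene_b = sprintf("Y%03dB", seq_len(n_y)),
                      score = yp$yeast_score, stringsAsFactors = FALSE)
  ortho <- data.frame(
    yeast_gene = c(yeast$gene_a, yeast$gene_b, "Y900A"),
    human_gene = c(yp$gene_a, yp$gene_b, truth$gene_universe[1]),
    stringsAsFactors = FALSE)
  # decoys: a weak-score row (filtered) and a pair with an unmapped member
  yeast <- rbind(yeast,
                 data.frame(gene_a = "Y900A", gene_b = "Y900B", score = -0.10),
                 data.frame(gene_a = "Y901A", gene_b = "Y901B", score = -0.55))
  utils::write.table(yeast, file.path(out_dir, "yeast_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ortho, file.path(out_dir, "ortholog_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hp <- truth$sl_pairs[truth$sl_pairs$sources != "yeast_predicted", ]
  utils::write.table(data.frame(gene_a = hp$gene_a, gene_b = hp$gene_b,
                                source = hp$sources),
                     file.path(out_dir, "human_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(truth$characteristic_sets,
            file.path(out_dir, "characteristics.gmt"))

  # --- omics layers ------------------------------------------------------
  gm <- generate_mutations(truth, 120L, seed)
  write_maf(gm$calls, file.path(out_dir, "mutations.maf.tsv"))
  utils::write.table(data.frame(cancer = truth$cancers,
                                n = lengths(gm$cohorts)[truth$cancers]),
                     file.path(out_dir, "cohort_sizes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gc <- generate_counts(truth, n_tumor = 30L, n_normal = 20L,
                        dispersion = 0.1, seed = seed)
  for (cc in truth$cancers)
    write_count_matrix(gc[[cc]]$counts, gc[[cc]]$condition,
                       file.path(out_dir, "counts", paste0(cc, "_counts.tsv")),
                       file.path(out_dir, "counts", paste0(cc, "_conditions.tsv")))

  gi <- generate_isomirs(truth, n_tumor = 25L, n_normal = 15L,
                         locus_total_mean = 2000, seed = seed)
  for (cc in truth$cancers) {
    utils::write.table(gi[[cc]]$table,
                       file.path(out_dir, "isomirs", paste0(cc, "_isomirs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample = names(gi[[cc]]$table)[-(1:2)],
                                  condition = gi[[cc]]$condition),
                       file.path(out_dir, "isomirs",
                                 paste0(cc, "_conditions.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tm <- truth$target_map
  utils::write.table(data.frame(mirna = rep(names(tm), lengths(tm)),
                                gene = unlist(tm, use.names = FALSE)),
                     file.path(out_dir, "target_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- clinical + drugs around one mutation-signal pair ------------------
  mut_pair <- truth$sl_pairs[truth$sl_pairs$signal == "mutation", ][1, ]
  common <- intersect(truth$mut_cancer_sets[[mut_pair$gene_a]],
                      truth$mut_cancer_sets[[mut_pair$gene_b]])
  surv_cancer <- if (length(common)) common[1] else truth$cancers[1]
  cohort <- gm$cohorts[[surv_cancer]]
  grp <- assign_mutation_groups(mut_pair, gm$calls, surv_cancer, cohort)
  labels <- stats::setNames(grp$group, grp$sample)
  prog <- truth$prognostic_pairs
  key <- pair_key(mut_pair$gene_a, mut_pair$gene_b)
  hr_row <- prog[prog$pair == key, , drop = FALSE]
  hr <- if (nrow(hr_row)) c(MM = hr_row$hr_extreme[1], MW = hr_row$hr_mid[1],
                            WW = 1) else c(MM = 1, MW = 1, WW = 1)
  clin <- generate_clinical(labels, hr = hr, seed = seed,
                            cancer = surv_cancer)
  utils::write.table(clin[, c("sample", "cancer", "time", "event")],
                     file.path(out_dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dm <- generate_drug_response(truth, labels, mut_pair, seed = seed)
  utils::write.table(data.frame(sample = rownames(dm), dm,
                                check.names = FALSE),
                     file.path(out_dir, "drug_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- pathway sets over the combined-signal genes -----------------------
  comb_genes <- unique(unlist(
    truth$sl_pairs[truth$sl_pairs$signal == "combined", c("gene_a", "gene_b")]))
  pathways <- with_seed(child_seed(seed, "pathways"), list(
    cell_cycle = sort(unique(c(sample(comb_genes, min(4, length(comb_genes))),
                               sample(truth$gene_universe, 10)))),
    pathways_in_cancer = sort(sample(truth$gene_universe, 12))))
  write_gmt(pathways, file.path(out_dir, "pathways.gmt"))

  # --- config ------------------------------------------------------------
  pipe_cfg <- list(
    seed = as.integer(seed),
    out_dir = file.path(out_dir, "results"),
    survival_cancer = surv_cancer,
    survival_scheme = "two_group",
    drug_cancer = surv_cancer,
    drug_pair = list(mut_pair$gene_a, mut_pair$gene_b),
    thresholds = thr,
    run = list(survival = TRUE, randomization_B = 0L, drugs = TRUE,
               network = TRUE),
    inputs = list(
      yeast_pairs = file.path(out_dir, "yeast_pairs.tsv"),
      ortholog_map = file.path(out_dir, "ortholog_map.tsv"),
      human_pairs = file.path(out_dir, "human_pairs.tsv"),
      characteristics_gmt = file.path(out_dir, "characteristics.gmt"),
      maf = file.path(out_dir, "mutations.maf.tsv"),
      cohort_sizes = file.path(out_dir, "cohort_sizes.tsv"),
      counts_dir = file.path(out_dir, "counts"),
      clinical = file.path(out_dir, "clinical.tsv"),
      drug_matrix = file.path(out_dir, "drug_matrix.tsv"),
      isomir_dir = file.path(out_dir, "isomirs"),
      target_map = file.path(out_dir, "target_map.tsv"),
      pathways_gmt = file.path(out_dir, "pathways.gmt")))
  config_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(pipe_cfg, config_path)

  # --- brute-force reference manifest ------------------------------------
  keys <- ref_catalog_keys(pipe_cfg$inputs$yeast_pairs,
                           pipe_cfg$inputs$ortholog_map,
                           pipe_cfg$inputs$human_pairs, thr$yeast_score)
  cat_genes <- sort(unique(unlist(strsplit(keys, "|", fixed = TRUE))))
  core <- ref_core_genes(cat_genes, pipe_cfg$inputs$characteristics_gmt,
                         thr$min_characteristics)
  fm <- ref_freq_matrix(pipe_cfg$inputs$maf, pipe_cfg$inputs$cohort_sizes)
  getf <- function(g, cc) if (g %in% rownames(fm)) fm[g, cc] else 0
  n_mutated <- 0L
  mutated_keys <- character(0)
  for (k in keys) {
    g2 <- strsplit(k, "|", fixed = TRUE)[[1]]
    nq <- sum(vapply(colnames(fm), function(cc)
      getf(g2[1], cc) > thr$min_freq && getf(g2[2], cc) > thr$min_freq,
      logical(1)))
    if (nq >= thr$min_mut_cancers) {
      n_mutated <- n_mutated + 1L
      mutated_keys <- c(mutated_keys, k)
    }
  }
  status <- sapply(truth$cancers, function(cc)
    ref_de_status(file.path(out_dir, "counts", paste0(cc, "_counts.tsv")),
                  file.path(out_dir, "counts", paste0(cc, "_conditions.tsv")),
                  thr$fc_cut, thr$alpha))
  n_dys <- rowSums(status != "normal")
  n_up <- rowSums(status == "up")
  dys_genes <- sort(names(n_dys)[n_dys >= thr$min_dysreg_cancers])
  n_dys_pairs <- sum(vapply(keys, function(k) {
    g2 <- strsplit(k, "|", fixed = TRUE)[[1]]
    all(g2 %in% dys_genes)
  }, logical(1)))
  n_combined <- 0L; n_high <- 0L
  combined_keys <- character(0); high_keys <- character(0)
  for (k in keys) {
    g2 <- strsplit(k, "|", fixed = TRUE)[[1]]
    for (ori in list(g2, rev(g2))) {
      n_mc <- sum(vapply(colnames(fm), function(cc)
        getf(ori[1], cc) > thr$min_freq, logical(1)))
      n_uc <- if (ori[2] %in% rownames(status))
        sum(status[ori[2], ] == "up") else 0L
      if (n_mc >= thr$min_mut_cancers && n_uc >= thr$min_dysreg_cancers) {
        n_combined <- n_combined + 1L
        combined_keys <- unique(c(combined_keys, k))
        if (max(vapply(colnames(fm), function(cc) getf(ori[1], cc),
                       numeric(1))) > thr$high_freq) {
          n_high <- n_high + 1L
          high_keys <- unique(c(high_keys, k))
        }
      }
    }
  }
  mir_status <- sapply(truth$cancers, function(cc)
    ref_collapse_status(file.path(out_dir, "isomirs", paste0(cc, "_isomirs.tsv")),
                        file.path(out_dir, "isomirs",
                                  paste0(cc, "_conditions.tsv")),
                        thr$fc_cut, thr$alpha))
  n_down <- rowSums(mir_status == "down")
  down_mirnas <- sort(names(n_down)[n_down >= thr$min_down_cancers])

  # survival reference: survdiff per mutated pair, MM vs WW
  maf <- utils::read.delim(pipe_cfg$inputs$maf, comment.char = "#")
  clin_ref <- utils::read.delim(pipe_cfg$inputs$clinical, comment.char = "#")
  n_surv_tested <- 0L; n_surv_sig <- 0L
  for (k in mutated_keys) {
    g2 <- strsplit(k, "|", fixed = TRUE)[[1]]
    ma <- unique(maf$Tumor_Sample_Barcode[maf$Hugo_Symbol == g2[1] &
                                            maf$cancer_type == surv_cancer])
    mb <- unique(maf$Tumor_Sample_Barcode[maf$Hugo_Symbol == g2[2] &
                                            maf$cancer_type == surv_cancer])
    grp_ref <- ifelse(cohort %in% ma & cohort %in% mb, "MM",
                      ifelse(cohort %in% ma | cohort %in% mb, "MW", "WW"))
    sel <- grp_ref %in% c("MM", "WW")
    if (sum(grp_ref == "MM") < thr$min_group ||
        sum(grp_ref == "WW") < thr$min_group) next
    d <- data.frame(time = clin_ref$time[match(cohort[sel], clin_ref$sample)],
                    event = clin_ref$event[match(cohort[sel], clin_ref$sample)],
                    g = grp_ref[sel])
    sdout <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
    pv <- stats::pchisq(sdout$chisq, 1, lower.tail = FALSE)
    n_surv_tested <- n_surv_tested + 1L
    if (pv < thr$alpha) n_surv_sig <- n_surv_sig + 1L
  }

  # drug reference: wilcox per drug on the fixture's designated pair
  dm_ref <- utils::read.delim(pipe_cfg$inputs$drug_matrix, comment.char = "#",
                              check.names = FALSE)
  s_mm <- grp$sample[grp$group == "MM"]; s_ww <- grp$sample[grp$group == "WW"]
  eff <- pv <- numeric(0)
  for (d in setdiff(names(dm_ref), "sample")) {
    r1 <- dm_ref[[d]][dm_ref$sample %in% s_mm]
    r2 <- dm_ref[[d]][dm_ref$sample %in% s_ww]
    if (length(r1) < 3 || length(r2) < 3) next
    eff <- c(eff, mean(r1) - mean(r2))
    pv <- c(pv, suppressWarnings(stats::wilcox.test(r1, r2,
                                                    exact = FALSE)$p.value))
  }
  fdr <- stats::p.adjust(pv, "BH")
  n_drug_sig <- sum(abs(eff) > thr$effect_cut & pv < thr$alpha &
                      fdr < thr$fdr_cut)

  # network reference: constructive count (pipeline networks the
  # high-mutation subset when nonempty, else all combined pairs)
  net_keys <- if (length(high_keys)) high_keys else combined_keys
  net_genes <- sort(unique(unlist(strsplit(net_keys, "|", fixed = TRUE))))
  n_sl_edges <- length(net_keys)
  n_tgt_edges <- sum(vapply(down_mirnas, function(mi)
    length(intersect(truth$target_map[[mi]], net_genes)), integer(1)))

  planted_combined <- sort(pair_key(
    truth$sl_pairs$gene_a[truth$sl_pairs$signal == "combined"],
    truth$sl_pairs$gene_b[truth$sl_pairs$signal == "combined"]))
  manifest <- list(
    seed = as.integer(seed),
    counts = list(
      n_catalog_pairs = length(keys),
      n_catalog_genes = length(cat_genes),
      n_core_genes = length(core),
      n_mutated_pairs = n_mutated,
      n_dysregulated_genes = length(dys_genes),
      n_dysregulated_pairs = n_dys_pairs,
      n_combined_records = n_combined,
      n_high_mutation_records = n_high,
      n_down_mirnas = length(down_mirnas),
      n_surv_tested = n_surv_tested,
      n_surv_significant = n_surv_sig,
      n_drug_significant = n_drug_sig,
      n_network_nodes = length(net_genes) + length(down_mirnas),
      n_network_edges = n_sl_edges + n_tgt_edges),
    planted_combined_pairs = planted_combined,
    down_mirnas = down_mirnas)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(dir = out_dir, config_path = config_path,
                 manifest_path = manifest_path, manifest = manifest,
                 truth = truth))
}
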