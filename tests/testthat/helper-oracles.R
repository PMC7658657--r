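# Independent brute-force oracles and small-instance builders used across
# the suite. These deliberately avoid the package's own code paths.

# product-limit estimator by direct loop over sorted event times
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time[event == 1])
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in ut) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# random unordered pair catalog over a gene alphabet
random_catalog <- function(n_pairs, genes) {
  a <- character(0); b <- character(0); seen <- character(0)
  while (length(a) < n_pairs) {
    g <- sample(genes, 2)
    key <- paste(min(g), max(g))
    if (key %in% seen) next
    seen <- c(seen, key)
    a <- c(a, min(g)); b <- c(b, max(g))
  }
  data.frame(gene_a = a, gene_b = b, sources = "human_predicted",
             yeast_score = NA_real_, orig_a = a, orig_b = b,
             stringsAsFactors = FALSE)
}

# brute-force per-gene degree by double loop
oracle_degrees <- function(catalog) {
  genes <- sort(unique(c(catalog$gene_a, catalog$gene_b)))
  sapply(genes, function(g) {
    partners <- c(catalog$gene_b[catalog$gene_a == g],
                  catalog$gene_a[catalog$gene_b == g])
    length(unique(partners))
  })
}

# brute-force mutated-pair screen
oracle_mutated_pairs <- function(catalog, fm, min_freq, min_cancers) {
  keep <- logical(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    n_q <- 0
    for (cc in colnames(fm)) {
      fa <- if (catalog$gene_a[i] %in% rownames(fm)) fm[catalog$gene_a[i], cc] else 0
      fb <- if (catalog$gene_b[i] %in% rownames(fm)) fm[catalog$gene_b[i], cc] else 0
      if (fa > min_freq && fb > min_freq) n_q <- n_q + 1
    }
    keep[i] <- n_q >= min_cancers
  }
  keep
}

# brute-force combined screen returning "mutated>partner" orientation keys
oracle_combined <- function(catalog, fm, status, min_freq, min_mut, min_up) {
  out <- character(0)
  for (i in seq_len(nrow(catalog))) {
    orig <- c(catalog$orig_a[i], catalog$orig_b[i])
    for (k in 1:2) {
      mg <- orig[k]; pg <- orig[3 - k]
      n_mc <- if (mg %in% rownames(fm)) sum(fm[mg, ] > min_freq) else 0
      n_uc <- if (pg %in% rownames(status)) sum(status[pg, ] == "up") else 0
      if (n_mc >= min_mut && n_uc >= min_up)
        out <- c(out, paste(mg, pg, sep = ">"))
    }
  }
  sort(out)
}

# a small random mutation-call table plus its cohort
random_calls <- function(n_calls, genes, cancers, samples_per_cancer) {
  cancer <- sample(cancers, n_calls, replace = TRUE)
  data.frame(
    sample = paste0(cancer, "_S", sample.int(samples_per_cancer, n_calls,
                                             replace = TRUE)),
    gene = sample(genes, n_calls, replace = TRUE),
    cancer = cancer,
    variant_class = sample(c("missense", "nonsense", "frameshift", "splice",
                             "other"), n_calls, replace = TRUE),
    stringsAsFactors = FALSE)
}

# random dysregulation status matrix
random_status <- function(genes, cancers, p_up = 0.2, p_down = 0.1) {
  m <- matrix(sample(c("up", "down", "normal"), length(genes) * length(cancers),
                     replace = TRUE, prob = c(p_up, p_down, 1 - p_up - p_down)),
              length(genes), length(cancers),
              dimnames = list(genes, cancers))
  m
}

as_dysreg <- function(status) {
  obj <- list(status = status,
              n_dysregulated = rowSums(status != "normal"),
              n_up = rowSums(status == "up"),
              n_down = rowSums(status == "down"))
  class(obj) <- "sl_dysreg"
  obj
}

pair_key_df <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b)))
}
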