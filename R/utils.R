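# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical unordered-pair key
#'
#' Pairs are treated symmetrically throughout the pipeline; the canonical
#' key is the two symbols in lexicographic order joined by "|".
#'
#' @param a,b character vectors of gene symbols (recycled).
#' @return character vector of keys.
#' @keywords internal
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Reorder (a, b) so a < b lexicographically; returns list(a, b, swapped).
canonical_order <- function(a, b) {
  swapped <- a > b
  list(a = ifelse(swapped, b, a), b = ifelse(swapped, a, b), swapped = swapped)
}

# FNV-1a 32-bit hash of a string, done in doubles with explicit 16-bit
# splitting so every intermediate stays exactly representable.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (byte in utf8ToInt(x)) {
    h <- bitwXor32(h, byte %% 256)
    h <- mulmod32(h, 16777619)
  }
  h
}

bitwXor32 <- function(a, b) {
  # bitwXor works on 32-bit signed ints; route through two 16-bit halves
  a1 <- a %/% 65536; a0 <- a %% 65536
  b1 <- b %/% 65536; b0 <- b %% 65536
  bitwXor(a1, b1) * 65536 + bitwXor(a0, b0)
}

mulmod32 <- function(a, b) {
  a1 <- a %/% 65536; a0 <- a %% 65536
  (((a1 * b) %% 65536) * 65536 + a0 * b) %% 4294967296
}

#' Derive a child seed from a global seed and a stream label
#'
#' One global seed fans out to independent per-generator streams through a
#' fixed label-hash rule, so adding a generator never perturbs the draws of
#' another. Result is a valid 32-bit seed.
#'
#' @param seed integer global seed.
#' @param id character stream label (e.g. "mutations/CA03").
#' @return integer seed in [1, 2^31 - 2].
#' @export
child_seed <- function(seed, id) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- fnv1a32(as.character(id))
  as.integer((h + (seed %% 2147483647) * 1013 + 17) %% 2147483629 + 1)
}

# Evaluate expr with a local RNG state seeded at `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Hash a configuration list
#'
#' Stable content hash of a configuration (canonical YAML serialisation,
#' FNV-1a), stamped into every pipeline output header so silent threshold
#' drift shows up as an output diff.
#'
#' @param config a list.
#' @return character scalar (8 hex digits).
#' @export
config_hash <- function(config) {
  h <- fnv1a32(yaml::as.yaml(config))
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

stop_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
}
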