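# Internal helpers shared across modules.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values.
#' Order-preserving, monotone, and bounded in \[0, 1\]. This is the single
#' multiplicity correction used throughout the package (integration-site
#' clonal tracking, differential expression, enrichment, methylation).
#'
#' @param p Numeric vector of raw p-values, all in \[0, 1\]. `NA` values are
#'   propagated.
#' @return Numeric vector of adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

# Stable per-stage seed derived from a root seed, so adding a stage never
# perturbs the draws of another. Kept below 2^31 - 1.
derive_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root_seed) * 7919 + h) %% 2147483647)
}

# Positive integer check for config validation.
check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  invisible(as.integer(x))
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lo, hi))
  }
  invisible(as.numeric(x))
}

# Sample-id constructor shared by all generators.
sample_id <- function(vector, cell, timepoint, replicate) {
  paste(vector, cell, timepoint, paste0("r", replicate), sep = "_")
}
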