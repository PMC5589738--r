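#' @importFrom stats runif rnorm sd cor
#' @importFrom utils read.csv write.csv
NULL

# Derive a reproducible sub-seed from a top-level seed and a stage offset.
# Kept strictly below .Machine$integer.max so set.seed() always accepts it.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + 7919 * abs(offset)) %% (.Machine$integer.max - 1L)) + 1L
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bit-exact double <-> text: 17 significant digits round-trip IEEE doubles
# exactly; jsonlite's own digits = NA does not.
num_to_chr <- function(x) sprintf("%.17g", x)
chr_to_num <- function(s) as.numeric(s)
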