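#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 pmap map_dbl map_int imap
#' @importFrom Rcpp sourceCpp
#' @useDynLib emgimage, .registration = TRUE
NULL

# Run `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never disturb user RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# Deterministically combine a base seed with stream identifiers into a
# 31-bit seed. Multipliers are distinct odd constants; the modulus keeps the
# result a valid R integer seed.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in seq_along(ids)) {
    h <- (h * 48271 + as.double(ids[k]) * (2 * k + 1) + 104729) %% 2147483647
  }
  as.integer(h)
}

#' Round half away from zero
#'
#' Fixed-decimal rounding in which a trailing 5 always rounds up, matching
#' how accuracy tables are conventionally printed (base `round()` rounds
#' half to even). A tiny epsilon guards against values such as 95.55 that
#' are stored just below the halfway point in binary floating point.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded to `digits` decimals, halves upward.
#' @examples
#' round_half_up(c(90.25, 95.55), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

stopifnot_scalar_num <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}
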