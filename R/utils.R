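# Small shared helpers: seeding, rounding, count scaling.

#' Derive a child seed from a global seed and a stage label
#'
#' Every stochastic component in the package takes an explicit integer seed;
#' pipelines derive per-stage seeds deterministically from one global seed so
#' that a whole run is reproducible from a single integer. The derivation is a
#' simple 32-bit mix of the seed with a hash of the label, kept strictly below
#' `.Machine$integer.max`.
#'
#' @param seed Integer global seed.
#' @param key Character label of the consuming stage (e.g. `"cohort"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "cohort")
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483646)
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published clinical tables round half
#' up. Used only at presentation time -- internal metric values are kept at
#' full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Rescale class counts to a new total
#'
#' Largest-remainder apportionment of a count vector to a new total `n`,
#' preserving proportions as closely as integer counts allow. Used to scale a
#' reference cohort's class histogram to other cohort sizes.
#'
#' @param counts Named or unnamed non-negative integer vector.
#' @param n Target total.
#' @return Integer vector summing to `n`, same names as `counts`.
#' @export
#' @examples
#' scale_counts(c(6, 36, 206, 61), 100)
scale_counts <- function(counts, n) {
  stopifnot(all(counts >= 0), sum(counts) > 0, n >= 0)
  quota <- counts / sum(counts) * n
  base <- floor(quota)
  short <- n - sum(base)
  if (short > 0) {
    order_rem <- order(quota - base, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

# Internal: stop unless x is a single positive integer-ish number.
assert_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
    abort(glue::glue("`{what}` must be a single positive integer"))
  }
  invisible(as.integer(x))
}
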