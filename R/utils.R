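#' Round half away from zero
#'
#' Fixed-point rounding where ties go away from zero (0.05 -> 0.1), the
#' convention used for reported percentages, as opposed to [round()]'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Proportion as a percentage
#'
#' Express a count out of a total as a percentage, rounded half-up to a fixed
#' number of decimals (e.g. 10 affected animals of 26 is 38.5%).
#'
#' @param k count of events.
#' @param n total count; must be positive and at least `k`.
#' @param digits decimals to keep (default 1).
#' @return percentage in `[0, 100]`.
#' @examples
#' proportion_pct(10, 26) # 38.5
#' @export
proportion_pct <- function(k, n, digits = 1) {
  stopifnot(is.numeric(k), is.numeric(n), n > 0, k >= 0, k <= n)
  round_half_up(100 * k / n, digits)
}

#' Sidak multiple-comparison adjustment
#'
#' Adjust per-comparison p-values for `m` independent comparisons via
#' `p_adj = 1 - (1 - p)^m`, clipped to `[0, 1]`.
#'
#' @param p vector of raw p-values.
#' @param m number of comparisons; defaults to `length(p)`.
#' @return adjusted p-values.
#' @examples
#' sidak_adjust(0.01, m = 5) # 0.0490...
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a stream of child seeds from one integer seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
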