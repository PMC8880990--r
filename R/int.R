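#' Rank-based inverse normal transformation
#'
#' Maps values through their (tie-averaged) ranks to standard-normal
#' quantiles, forcing an approximately N(0, 1) marginal distribution. This is
#' applied to protein levels before model training and to projected scores
#' before disease-association modelling.
#'
#' With `n` non-missing observations and tie-averaged rank `r_i`, the
#' transformed value is `qnorm((r_i - offset) / (n - 2 * offset + 1))`. The
#' default `offset = 3/8` is the Blom constant, the usual choice in genetics
#' pipelines; 1/3 (Tukey) and 0 (van der Waerden) are the common alternatives.
#'
#' @param x Numeric vector. Missing values are excluded from ranking and
#'   propagate as missing in the output.
#' @param offset Rank offset in `[0, 0.5]`; Blom's 3/8 by default.
#' @return Numeric vector of the same length and order as `x`.
#' @examples
#' rank_inverse_normal(c(1, 5, 2))
#' @export
rank_inverse_normal <- function(x, offset = 3 / 8) {
  if (!is.numeric(x)) abort("rank_inverse_normal: input must be numeric")
  if (!is.numeric(offset) || length(offset) != 1 || offset < 0 || offset > 0.5) {
    abort("rank_inverse_normal: offset must be a single value in [0, 0.5]")
  }
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0) abort("rank_inverse_normal: all values missing")
  if (n < 2) abort("rank_inverse_normal: insufficient observations")
  if (any(!is.finite(x[ok]))) abort("rank_inverse_normal: non-finite values")
  out <- rep(NA_real_, length(x))
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}
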