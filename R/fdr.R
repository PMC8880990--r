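#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR-adjusted q-values via [stats::p.adjust()]. The adjustment is
#' order-preserving and satisfies `q >= p` elementwise.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (missing values
#'   propagate).
#' @param m Family size; defaults to `length(pvalues)`. Supplying a larger
#'   `m` fixes the testing family when some cells of a grid failed to yield
#'   a p-value.
#' @return Numeric vector of q-values, same order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04))
#' @export
bh_fdr <- function(pvalues, m = length(pvalues)) {
  if (!is.numeric(pvalues)) abort("bh_fdr: p-values must be numeric")
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("bh_fdr: p-values must lie in [0, 1]")
  }
  if (m < sum(ok)) abort("bh_fdr: family size m smaller than the number of p-values")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH", n = m)
  out
}
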