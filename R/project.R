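#' Project EpiScore weight sets onto a methylation matrix
#'
#' Computes each score as the weighted sum of standardized CpG values over
#' the weight CpGs present in the matrix. CpGs absent from the matrix
#' contribute zero — equivalent to mean imputation after standardization —
#' and the fraction of weight CpGs found is reported per score so users can
#' filter on coverage. A score with no overlapping CpGs at all yields a
#' missing-value column and a warning.
#'
#' @param data Methylation table (wide data frame or matrix). Raw beta
#'   values are standardized per (probe, set) first unless the table already
#'   carries the `standardized` flag from [standardize_columns()] or
#'   `standardize = FALSE`.
#' @param weights An [episcore_weights()] table.
#' @param sets Optional per-sample set labels (column name or vector),
#'   forwarded to [standardize_columns()].
#' @param standardize Standardize before projecting (default `TRUE`).
#' @return Tibble `sample_id` + one numeric column per episcore, with a
#'   `coverage` attribute: tibble of `episcore_id`, `probe_coverage`.
#' @examples
#' w <- episcore_weights(tibble::tibble(
#'   episcore_id = "P1", protein_id = "P1", panel = "somascan",
#'   cpg = c("cg01", "cg02"), weight = c(0.5, -0.2)))
#' beta <- tibble::tibble(sample_id = c("a", "b", "c"),
#'                        cg01 = c(0.2, 0.4, 0.6), cg02 = c(0.9, 0.5, 0.1))
#' project_episcores(beta, w)
#' @export
project_episcores <- function(data, weights, sets = NULL, standardize = TRUE) {
  if (!inherits(weights, "episcore_weights")) weights <- episcore_weights(weights)
  if (standardize && !is_standardized(data)) {
    data <- standardize_columns(data, sets = sets)
  }
  Z <- as_sample_matrix(data, "methylation matrix")

  ids <- unique(weights$episcore_id)
  scores <- matrix(NA_real_, nrow(Z), length(ids),
                   dimnames = list(rownames(Z), ids))
  cov <- numeric(length(ids))
  for (i in seq_along(ids)) {
    w <- weights[weights$episcore_id == ids[i], ]
    present <- w$cpg %in% colnames(Z)
    cov[i] <- mean(present)
    if (!any(present)) {
      warn(sprintf("project_episcores: no weight CpGs of '%s' present in the matrix; score set to NA",
                   ids[i]))
      next
    }
    wp <- w[present, ]
    scores[, i] <- drop(Z[, wp$cpg, drop = FALSE] %*% wp$weight)
  }
  out <- matrix_to_tibble(scores)
  attr(out, "coverage") <- tibble(episcore_id = ids, probe_coverage = cov)
  out
}
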