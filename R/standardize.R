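#' Standardize methylation columns to mean zero, variance one
#'
#' Centres and scales each probe column to mean 0 and unit sample variance
#' (n - 1 denominator), optionally within batch/set strata so that each
#' (probe, set) combination is standardized independently — the convention
#' used when a cohort's methylation was processed in separate sets.
#'
#' Missing beta values are mean-imputed within their (probe, set) stratum
#' before scaling, which is equivalent to a zero contribution after
#' standardization; per-probe missingness is reported. Probes that are
#' constant within a stratum are set to all-zero rather than erroring, so
#' that projection of externally trained weight sets never aborts; such
#' probes are listed in the `flagged_probes` attribute.
#'
#' @param data Wide data frame (first column sample IDs, remaining columns
#'   numeric probe values) or a numeric matrix with sample-ID rownames. Raw
#'   beta values are expected in `[0, 1]`.
#' @param sets Optional per-sample batch/set labels: either the name of a
#'   column of `data` or a vector with one label per sample. `NULL` treats
#'   all samples as one set.
#' @param check_range If `TRUE` (default), error when raw values fall outside
#'   `[0, 1]`. Disable to standardize already-transformed matrices.
#' @return A tibble of the same shape with standardized values, carrying
#'   attributes `standardized = TRUE`, `sets` (per-sample labels),
#'   `flagged_probes` (tibble of constant (probe, set) strata) and
#'   `missingness` (tibble of probes with any missing values).
#' @examples
#' beta <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
#'                        cg01 = c(0.2, 0.4, 0.6))
#' standardize_columns(beta)
#' @export
standardize_columns <- function(data, sets = NULL, check_range = TRUE) {
  set_col_dropped <- FALSE
  if (is.data.frame(data) && is.character(sets) && length(sets) == 1 &&
      sets %in% names(data)) {
    set_labels <- as.character(data[[sets]])
    data <- data[setdiff(names(data), sets)]
    set_col_dropped <- TRUE
  } else {
    set_labels <- sets
  }
  m <- as_sample_matrix(data, "methylation matrix")
  n <- nrow(m)
  if (is.null(set_labels)) set_labels <- rep("all", n)
  if (!set_col_dropped && length(set_labels) != n) {
    abort("standardize_columns: `sets` must supply one label per sample")
  }
  set_labels <- as.character(set_labels)
  if (check_range) {
    rng <- range(m, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      abort("standardize_columns: raw beta values outside [0, 1]; set check_range = FALSE for transformed input")
    }
  }

  flagged <- list()
  miss <- colMeans(is.na(m))
  out <- m
  for (s in unique(set_labels)) {
    idx <- which(set_labels == s)
    if (length(idx) < 2) {
      abort(sprintf("standardize_columns: set '%s' has a single sample; cannot scale within set", s))
    }
    block <- m[idx, , drop = FALSE]
    mu <- colMeans(block, na.rm = TRUE)
    centred <- sweep(block, 2, mu, "-")
    centred[is.na(centred)] <- 0        # mean imputation within (probe, set)
    sdv <- apply(centred, 2, sd)        # n - 1 denominator
    const <- !is.finite(sdv) | sdv == 0
    sdv[const] <- 1
    z <- sweep(centred, 2, sdv, "/")
    z[, const] <- 0
    out[idx, ] <- z
    if (any(const)) {
      flagged[[s]] <- tibble(probe = colnames(m)[const], set = s,
                             reason = "constant within set")
    }
  }

  res <- matrix_to_tibble(out)
  attr(res, "standardized") <- TRUE
  attr(res, "sets") <- set_labels
  attr(res, "flagged_probes") <-
    if (length(flagged)) dplyr::bind_rows(flagged) else
      tibble(probe = character(), set = character(), reason = character())
  attr(res, "missingness") <-
    tibble(probe = colnames(m), frac_missing = unname(miss)) |>
    dplyr::filter(.data$frac_missing > 0)
  res
}

is_standardized <- function(x) isTRUE(attr(x, "standardized"))
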