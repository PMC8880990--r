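#' Out-of-sample validation of one EpiScore
#'
#' Pearson correlation between projected scores and measured (residualized)
#' protein levels, with a two-sided p-value from the t-distribution on
#' `n - 2` degrees of freedom and a 95% confidence interval from the Fisher
#' z-transform.
#'
#' @param scores Either a data frame with columns `sample_id` and `score`,
#'   or a numeric vector paired positionally with `measured`.
#' @param measured Numeric vector of measured protein levels; when `scores`
#'   is a data frame, a named vector or a data frame with `sample_id` plus
#'   one value column is also accepted and matched by sample ID.
#' @param episcore_id,cohort Labels recorded on the output row.
#' @param probe_coverage Optional coverage fraction carried through from
#'   projection.
#' @return One-row tibble: `episcore_id`, `cohort`, `n_test`, `pearson_r`,
#'   `p_value`, `ci_lo`, `ci_hi`, `probe_coverage`, `selected` (`NA` until
#'   [select_episcores()] is applied).
#' @export
evaluate_episcore <- function(scores, measured, episcore_id = "score",
                              cohort = "test", probe_coverage = NA_real_) {
  if (is.data.frame(scores)) {
    ids <- as.character(scores[[1]])
    s <- scores[[if ("score" %in% names(scores)) "score" else names(scores)[2]]]
    names(s) <- ids
    if (is.data.frame(measured)) {
      m <- measured[[2]]
      names(m) <- as.character(measured[[1]])
    } else m <- measured
    if (!is.null(names(m))) {
      shared <- intersect(names(s), names(m))
      s <- s[shared]; m <- m[shared]
    }
  } else {
    s <- as.numeric(scores); m <- as.numeric(measured)
    if (length(s) != length(m)) abort("evaluate_episcore: length mismatch")
  }
  ok <- !is.na(s) & !is.na(m)
  s <- s[ok]; m <- m[ok]
  n <- length(s)
  if (n < 4) abort("evaluate_episcore: need >= 4 paired non-missing observations")
  if (sd(s) == 0 || sd(m) == 0) abort("evaluate_episcore: degenerate correlation (zero variance)")

  r <- cor(s, m)
  if (abs(r) >= 1) {
    p <- 0
    ci <- c(r, r)
  } else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    z <- atanh(r)
    hw <- qnorm(0.975) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  }
  tibble(episcore_id = episcore_id, cohort = cohort, n_test = n,
         pearson_r = r, p_value = p, ci_lo = ci[1], ci_hi = ci[2],
         probe_coverage = probe_coverage, selected = NA)
}

#' Validate projected scores against measured protein levels
#'
#' Applies [evaluate_episcore()] to every score column of a projection that
#' has a matching protein column in the measured table.
#'
#' @param scores Projection table from [project_episcores()] (`sample_id` +
#'   score columns).
#' @param proteins Measured (residualized) protein table.
#' @param cohort Test-cohort label.
#' @param protein_map Optional tibble (`episcore_id`, `protein_id`) when
#'   score and protein names differ; identity by default.
#' @return Tibble of validation rows, one per evaluable score; class
#'   `episcore_validation`.
#' @export
evaluate_episcores <- function(scores, proteins, cohort = "test",
                               protein_map = NULL) {
  S <- as_sample_matrix(scores, "score matrix")
  P <- as_sample_matrix(proteins, "protein matrix")
  coverage <- attr(scores, "coverage")
  map <- protein_map %||% tibble(episcore_id = colnames(S),
                                 protein_id = colnames(S))
  map <- map[map$episcore_id %in% colnames(S) & map$protein_id %in% colnames(P), ]
  al <- align_samples(S, P, "scores", "proteins")
  rows <- purrr::pmap(map, function(episcore_id, protein_id) {
    cov <- if (!is.null(coverage)) {
      coverage$probe_coverage[match(episcore_id, coverage$episcore_id)]
    } else NA_real_
    s <- al$a[, episcore_id]
    m <- al$b[, protein_id]
    ok <- !is.na(s) & !is.na(m)
    if (sum(ok) < 4 || sd(s[ok]) == 0 || sd(m[ok]) == 0) return(NULL)
    evaluate_episcore(s[ok], m[ok], episcore_id = episcore_id,
                      cohort = cohort, probe_coverage = cov)
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  class(out) <- c("episcore_validation", class(out))
  out
}

#' Apply the EpiScore selection rule
#'
#' A score is selected when its out-of-sample Pearson `r` strictly exceeds
#' `r_threshold` and its p-value is strictly below `p_threshold` in at least
#' one configured test set (or, with `require_any_test = FALSE`, in every
#' test set). Scores with no external validation row fall back to a holdout
#' validation row if one is supplied; otherwise they are an error.
#'
#' @param results Validation rows from [evaluate_episcores()], possibly
#'   pooled over several cohorts.
#' @param weights Optional [episcore_weights()] defining the universe of
#'   scores that must be adjudicated; defaults to the scores present in
#'   `results`.
#' @param r_threshold,p_threshold Strict selection thresholds (defaults 0.1
#'   and 0.05).
#' @param require_any_test If `TRUE` (default) one passing test set
#'   suffices; if `FALSE` all must pass.
#' @param holdout_results Optional validation rows from holdout samples used
#'   only for scores absent from `results`.
#' @return Tibble, one row per score: `episcore_id`, `selected`,
#'   `passing_cohort` (provenance of the passing test), `best_r`, `best_p`,
#'   `via` (`"external"` or `"holdout"`).
#' @export
select_episcores <- function(results, weights = NULL, r_threshold = 0.1,
                             p_threshold = 0.05, require_any_test = TRUE,
                             holdout_results = NULL) {
  universe <- if (!is.null(weights)) unique(weights$episcore_id) else
    unique(results$episcore_id)
  adjudicate <- function(rows) {
    pass <- rows$pearson_r > r_threshold & rows$p_value < p_threshold
    sel <- if (require_any_test) any(pass) else all(pass)
    best <- which.max(rows$pearson_r)
    tibble(selected = sel,
           passing_cohort = if (any(pass)) {
             rows$cohort[which(pass)[which.max(rows$pearson_r[pass])]]
           } else NA_character_,
           best_r = rows$pearson_r[best], best_p = rows$p_value[best])
  }
  out <- purrr::map(universe, function(id) {
    rows <- results[results$episcore_id == id, ]
    via <- "external"
    if (nrow(rows) == 0) {
      if (!is.null(holdout_results)) {
        rows <- holdout_results[holdout_results$episcore_id == id, ]
        via <- "holdout"
      }
      if (nrow(rows) == 0) {
        abort(sprintf("select_episcores: score '%s' has no validation results and no holdout fallback", id))
      }
    }
    dplyr::bind_cols(tibble(episcore_id = id), adjudicate(rows), tibble(via = via))
  })
  dplyr::bind_rows(out)
}
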