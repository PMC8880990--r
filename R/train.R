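#' Construct an EpiScore weight table
#'
#' The portable trained artifact: a sparse CpG-to-weight map per score, one
#' row per (episcore, CpG). Scores with no selected features are legal and
#' appear only in the `training_meta` attribute with `n_nonzero = 0`.
#'
#' @param weights Data frame with columns `episcore_id`, `protein_id`,
#'   `panel`, `cpg`, `weight`.
#' @param meta Optional per-score metadata tibble (cohort label, n_train,
#'   chosen lambda, ...).
#' @return Tibble of class `episcore_weights`.
#' @export
episcore_weights <- function(weights, meta = NULL) {
  need <- c("episcore_id", "protein_id", "panel", "cpg", "weight")
  if (!all(need %in% names(weights))) {
    abort(sprintf("episcore_weights: need columns %s", paste(need, collapse = ", ")))
  }
  w <- as_tibble(weights[need])
  if (nrow(w)) {
    if (any(!is.finite(w$weight))) abort("episcore_weights: non-finite weights")
    if (any(w$weight == 0)) abort("episcore_weights: zero weights must be omitted")
    dup <- duplicated(w[c("episcore_id", "cpg")])
    if (any(dup)) {
      abort(sprintf("episcore_weights: duplicate (episcore, cpg) pairs, e.g. %s/%s",
                    w$episcore_id[dup][1], w$cpg[dup][1]))
    }
  }
  attr(w, "training_meta") <- meta
  class(w) <- c("episcore_weights", class(w))
  w
}

#' @export
print.episcore_weights <- function(x, ...) {
  cat(sprintf("<episcore_weights> %d scores, %d CpG weights\n",
              dplyr::n_distinct(x$episcore_id), nrow(x)))
  NextMethod()
}

#' Train an EpiScore for one protein
#'
#' Cross-validates the elastic net on the (optionally holdout-reduced)
#' training samples, selects the penalty by the configured rule, refits at
#' that penalty on the full training sample, and returns the sparse weight
#' set. A model selecting zero CpGs returns an empty weight table flagged
#' `"no features selected"` rather than erroring — in practice a sizeable
#' fraction of proteins yield no methylation signal.
#'
#' @param methylation Standardized methylation table (see
#'   [standardize_columns()]) or matrix: samples x CpGs.
#' @param proteins Residualized protein table (see
#'   [residualize_proteins()]); must contain `protein_id`.
#' @param protein_id Column of `proteins` to train on.
#' @param config An [enet_config()].
#' @param holdout Optional holdout specification: a character vector of
#'   sample IDs, or a fraction in (0, 1) drawn at random (seeded) from the
#'   overlapping samples. Holdout samples are excluded from training and the
#'   trained score is evaluated on them (attached as `holdout_validation`).
#' @param cohort Training-cohort label stored in the weight metadata.
#' @return List with elements `weights` ([episcore_weights()]), `cv`
#'   (`enet_cv`), `fit` (`enet_fit`) and `holdout_validation` (a
#'   [evaluate_episcore()] row or `NULL`).
#' @export
train_episcore <- function(methylation, proteins, protein_id,
                           config = enet_config(), holdout = NULL,
                           cohort = "train") {
  M <- as_sample_matrix(methylation, "methylation matrix")
  P <- as_sample_matrix(proteins, "protein matrix")
  panel <- attr(proteins, "panel") %||% "unknown"
  if (!protein_id %in% colnames(P)) {
    abort(sprintf("train_episcore: protein '%s' not in protein table", protein_id))
  }
  al <- align_samples(M, P, "methylation", "proteins")
  ids <- rownames(al$a)

  hold_ids <- character(0)
  if (!is.null(holdout)) {
    if (is.character(holdout)) {
      hold_ids <- intersect(holdout, ids)
    } else if (is.numeric(holdout) && length(holdout) == 1 &&
               holdout > 0 && holdout < 1) {
      hold_ids <- with_seed(config$seed,
                            sample(ids, size = floor(holdout * length(ids))))
    } else {
      abort("train_episcore: holdout must be sample IDs or a fraction in (0, 1)")
    }
  }
  train_ids <- setdiff(ids, hold_ids)
  if (length(train_ids) < config$min_overlap) {
    abort(sprintf("train_episcore: %d overlapping training samples < min_overlap = %d",
                  length(train_ids), config$min_overlap))
  }

  X <- al$a[train_ids, , drop = FALSE]
  y <- al$b[train_ids, protein_id]
  cv <- cross_validate(X, y, config)
  fit <- fit_elastic_net(X, y, cv$chosen_lambda, config)

  nz <- fit$coefficients[fit$coefficients != 0]
  meta <- tibble(episcore_id = protein_id, protein_id = protein_id,
                 panel = panel, cohort = cohort,
                 n_train = length(train_ids),
                 chosen_lambda = cv$chosen_lambda,
                 n_nonzero = length(nz),
                 cv_error = cv$mean_cv_error[match(cv$chosen_lambda, cv$lambda_path)],
                 note = if (length(nz) == 0) "no features selected" else "")
  w <- episcore_weights(
    tibble(episcore_id = protein_id, protein_id = protein_id, panel = panel,
           cpg = names(nz), weight = unname(nz)),
    meta = meta)

  hv <- NULL
  if (length(hold_ids) >= 4 && length(nz) > 0) {
    sc <- drop(al$a[hold_ids, names(nz), drop = FALSE] %*% nz)
    hv <- evaluate_episcore(
      tibble(sample_id = hold_ids, score = sc), al$b[hold_ids, protein_id],
      episcore_id = protein_id, cohort = "holdout")
  }
  list(weights = w, cv = cv, fit = fit, holdout_validation = hv)
}

#' Train EpiScores for every protein in a table
#'
#' @inheritParams train_episcore
#' @param protein_ids Proteins to train; all columns by default.
#' @return An [episcore_weights()] table pooling all proteins, with
#'   per-protein training metadata in the `training_meta` attribute and any
#'   holdout validations in `holdout_validation`.
#' @export
train_episcores <- function(methylation, proteins, protein_ids = NULL,
                            config = enet_config(), holdout = NULL,
                            cohort = "train") {
  P <- as_sample_matrix(proteins, "protein matrix")
  protein_ids <- protein_ids %||% colnames(P)
  fits <- purrr::map(protein_ids, function(pid) {
    train_episcore(methylation, proteins, pid, config = config,
                   holdout = holdout, cohort = cohort)
  })
  w <- dplyr::bind_rows(purrr::map(fits, ~ as_tibble(.x$weights)))
  meta <- dplyr::bind_rows(purrr::map(fits, ~ attr(.x$weights, "training_meta")))
  out <- episcore_weights(w, meta = meta)
  hv <- purrr::compact(purrr::map(fits, "holdout_validation"))
  attr(out, "holdout_validation") <-
    if (length(hv)) dplyr::bind_rows(hv) else NULL
  out
}
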