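cox_result_row <- function(fit, score_term) {
  i <- match(score_term, names(fit$coefficients))
  b <- fit$coefficients[i]; se <- fit$se[i]
  z <- b / se
  tibble(log_hazard_ratio = unname(b), se = unname(se), z = unname(z),
         p_value = 2 * pnorm(abs(z), lower.tail = FALSE),
         hazard_ratio = exp(unname(b)),
         ci_lo = exp(unname(b) - qnorm(0.975) * unname(se)),
         ci_hi = exp(unname(b) + qnorm(0.975) * unname(se)),
         n_cases = fit$n_cases, n_controls = fit$n_controls)
}

fit_cell <- function(dat, score_term, covars, ties, frailty_by, min_cases) {
  n_cases <- sum(dat$event == 1, na.rm = TRUE)
  if (n_cases < min_cases) {
    return(list(row = NULL, status = sprintf("skipped: %d cases < %d", n_cases, min_cases)))
  }
  fit <- tryCatch(
    fit_cox(dat, terms = c(score_term, covars), frailty_by = frailty_by,
            ties = ties),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(row = NULL, status = paste0("nonconvergent: ", conditionMessage(fit))))
  }
  sch <- tryCatch(schoenfeld_ph_test(fit), error = function(e) NULL)
  row <- cox_result_row(fit, score_term)
  row$schoenfeld_p_term <- if (!is.null(sch)) sch$p_value[match(score_term, sch$term)] else NA_real_
  row$schoenfeld_p_global <- if (!is.null(sch)) sch$p_value[sch$term == "GLOBAL"] else NA_real_
  row$frailty_variance <- fit$frailty_variance
  list(row = row, status = "ok")
}

#' Nested Cox association grid for EpiScores and incident diseases
#'
#' Fits the basic-model Cox regression (score + basic covariates) for every
#' (score, disease) cell, applies Benjamini-Hochberg FDR across the full
#' grid family, refits the FDR-passing cells with the full covariate set,
#' and flags cells that pass the nested filter (basic-stage FDR q below
#' `fdr_threshold` AND full-model p below `p_threshold`). Optional extra
#' covariate layers (e.g. estimated immune-cell proportions, an epigenetic
#' aging score) are added cumulatively and refit on the surviving cells.
#'
#' Score columns are rank-inverse normalised before modelling (so hazard
#' ratios are per 1-SD of score), unless `rank_normalize = FALSE`. Cells
#' that fail to converge are reported with a status and never abort the
#' grid; the FDR family stays fixed at the full grid size regardless.
#'
#' @param scores Tibble `sample_id` + one column per score.
#' @param survival Long survival table: `sample_id`, `disease`,
#'   `time_years`, `event`, optional `family_id`.
#' @param covariates Tibble `sample_id` + covariate columns.
#' @param basic_covariates Covariate names for the basic model (default age,
#'   sex).
#' @param full_covariates Covariate names for the fully adjusted model
#'   (defaults to the basic set plus smoking, deprivation, BMI, education
#'   and alcohol columns when present).
#' @param extra_layers Named list of character vectors; each layer's columns
#'   are added cumulatively on top of the full model for sensitivity stages.
#' @param min_cases Minimum incident cases per cell (default 10).
#' @param fdr_threshold,p_threshold Nested filter thresholds (0.05, 0.05).
#' @param ties,frailty_by Passed to [fit_cox()].
#' @param rank_normalize Rank-inverse-normalise score columns first.
#' @return Tibble of class `association_table`, one row per (score, disease,
#'   stage), with Wald statistics, hazard ratios and CIs, Schoenfeld
#'   p-values, `fdr_q` (basic stage), `passes_nested` and a per-cell
#'   `status`.
#' @export
run_association_grid <- function(scores, survival, covariates,
                                 basic_covariates = c("age", "sex"),
                                 full_covariates = NULL,
                                 extra_layers = list(),
                                 min_cases = 10,
                                 fdr_threshold = 0.05, p_threshold = 0.05,
                                 ties = "efron", frailty_by = NULL,
                                 rank_normalize = TRUE) {
  S <- as_sample_matrix(scores, "score matrix")
  if (rank_normalize) {
    dn <- dimnames(S)
    S <- apply(S, 2, rank_inverse_normal)
    dimnames(S) <- dn
  }
  score_ids <- colnames(S)
  diseases <- unique(survival$disease)
  full_covariates <- full_covariates %||% unique(c(
    basic_covariates,
    intersect(c("smoking", "deprivation", "bmi", "education", "alcohol"),
              names(covariates))))

  base <- dplyr::left_join(matrix_to_tibble(S), covariates, by = "sample_id")

  cells <- tidyr::expand_grid(episcore_id = score_ids, disease = diseases)
  run_stage <- function(cell_tbl, stage, covars) {
    purrr::pmap(cell_tbl[c("episcore_id", "disease")], function(episcore_id, disease) {
      dat <- dplyr::inner_join(
        base, survival[survival$disease == disease, ], by = "sample_id")
      res <- fit_cell(dat, episcore_id, covars, ties, frailty_by, min_cases)
      out <- tibble(episcore_id = episcore_id, disease = disease,
                    stage = stage, status = res$status)
      if (!is.null(res$row)) out <- dplyr::bind_cols(out, res$row)
      out
    }) |> dplyr::bind_rows()
  }

  basic <- run_stage(cells, "basic", basic_covariates)
  m_family <- nrow(cells)
  basic$fdr_q <- bh_fdr(if ("p_value" %in% names(basic)) basic$p_value else
    rep(NA_real_, nrow(basic)), m = m_family)

  survivors <- basic[!is.na(basic$fdr_q) & basic$fdr_q < fdr_threshold, ]
  stages <- list(basic)
  prev <- NULL
  if (nrow(survivors)) {
    full <- run_stage(survivors, "full", full_covariates)
    full$passes_nested <- !is.na(full$p_value) & full$p_value < p_threshold
    stages <- c(stages, list(full))
    prev <- full[full$passes_nested %in% TRUE, ]
    covars_so_far <- full_covariates
    for (ln in names(extra_layers)) {
      if (!nrow(prev)) break
      covars_so_far <- unique(c(covars_so_far, extra_layers[[ln]]))
      layer <- run_stage(prev, ln, covars_so_far)
      layer$passes_nested <- !is.na(layer$p_value) & layer$p_value < p_threshold
      stages <- c(stages, list(layer))
      prev <- layer[layer$passes_nested %in% TRUE, ]
    }
  }
  out <- dplyr::bind_rows(stages)
  # propagate the basic-stage q and the nested flag onto every cell's rows
  qmap <- basic[c("episcore_id", "disease", "fdr_q")]
  out$fdr_q <- qmap$fdr_q[match(paste(out$episcore_id, out$disease),
                                paste(qmap$episcore_id, qmap$disease))]
  if (!"passes_nested" %in% names(out)) out$passes_nested <- FALSE
  nmap <- out[out$stage == "full", c("episcore_id", "disease", "passes_nested")]
  key <- paste(out$episcore_id, out$disease)
  out$passes_nested <- dplyr::coalesce(
    nmap$passes_nested[match(key, paste(nmap$episcore_id, nmap$disease))], FALSE)
  class(out) <- c("association_table", class(out))
  out
}

#' Hazard ratios across truncated follow-up horizons
#'
#' Sensitivity analysis for proportional-hazards violations: events after a
#' horizon `h` are recoded as censored at `h` and the Cox model refit, giving
#' the hazard ratio as a function of maximum follow-up. Under proportional
#' hazards the estimates are stable across horizons.
#'
#' @param data Data frame with time, event and term columns (as
#'   [fit_cox()]).
#' @param terms Design columns; the first is the reported term.
#' @param horizons Numeric vector of truncation horizons in years (e.g.
#'   `1:14`).
#' @inheritParams fit_cox
#' @return Tibble: `horizon`, `n_events`, log HR, se, p, hazard ratio with
#'   CI, `status` (`"ok"` or `"no events"`).
#' @export
followup_truncation <- function(data, terms, horizons,
                                time = "time_years", event = "event",
                                ties = "efron", frailty_by = NULL) {
  purrr::map(horizons, function(h) {
    d <- data
    over <- d[[time]] > h
    d[[event]][over] <- 0
    d[[time]][over] <- h
    if (sum(d[[event]] == 1, na.rm = TRUE) == 0) {
      return(tibble(horizon = h, n_events = 0L, status = "no events"))
    }
    fit <- tryCatch(fit_cox(d, terms, time = time, event = event,
                            ties = ties, frailty_by = frailty_by),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble(horizon = h, n_events = sum(d[[event]] == 1, na.rm = TRUE),
                    status = paste0("nonconvergent: ", conditionMessage(fit))))
    }
    dplyr::bind_cols(tibble(horizon = h, n_events = fit$n_cases, status = "ok"),
                     cox_result_row(fit, fit$design_names[1]))
  }) |> dplyr::bind_rows()
}

#' Logistic association of scores with a binary outcome
#'
#' Per-score logistic regression of a binary outcome on the (standardized or
#' rank-normalised) score plus covariates, with Bonferroni correction at
#' `0.05 / n_scores`. Complete separation is flagged per score rather than
#' erroring.
#'
#' @param scores Tibble `sample_id` + score columns.
#' @param outcome Data frame with `sample_id` and a 0/1 outcome column.
#' @param covariates Tibble `sample_id` + covariates (e.g. age at testing,
#'   sex).
#' @param outcome_col Name of the outcome column (default the second column
#'   of `outcome`).
#' @param covariate_cols Covariates to adjust for; all columns of
#'   `covariates` by default.
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param alpha Family-wise level (0.05).
#' @return Tibble: `episcore_id`, `log_odds_ratio`, `se`, `z`, `p_value`,
#'   `odds_ratio` with CI, `n`, `separated`, `p_threshold`, `significant`.
#' @export
logistic_assoc <- function(scores, outcome, covariates = NULL,
                           outcome_col = NULL, covariate_cols = NULL,
                           correction = c("bonferroni", "none"), alpha = 0.05) {
  correction <- match.arg(correction)
  S <- as_sample_matrix(scores, "score matrix")
  outcome_col <- outcome_col %||% setdiff(names(outcome), "sample_id")[1]
  y <- outcome[[outcome_col]]
  names(y) <- as.character(outcome$sample_id)
  if (!all(y %in% c(0, 1, NA))) abort("logistic_assoc: outcome must be 0/1")
  if (length(unique(stats::na.omit(y))) < 2) {
    abort("logistic_assoc: outcome needs both classes")
  }
  base <- matrix_to_tibble(S)
  if (!is.null(covariates)) {
    covariate_cols <- covariate_cols %||% setdiff(names(covariates), "sample_id")
    base <- dplyr::left_join(base, covariates, by = "sample_id")
  } else covariate_cols <- character(0)
  base$.y <- unname(y[base$sample_id])

  n_scores <- ncol(S)
  thr <- if (correction == "bonferroni") alpha / n_scores else alpha
  rows <- purrr::map(colnames(S), function(id) {
    dat <- base[complete.cases(base[c(id, covariate_cols, ".y")]), ]
    fml <- stats::as.formula(paste(
      ".y ~", paste(sprintf("`%s`", c(id, covariate_cols)), collapse = " + ")))
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(fml, data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    b <- sm[2, 1]; se <- sm[2, 2]
    if (!sep && (abs(b) > 10 || se > 10)) sep <- TRUE
    tibble(episcore_id = id, log_odds_ratio = b, se = se, z = b / se,
           p_value = sm[2, 4], odds_ratio = exp(b),
           ci_lo = exp(b - qnorm(0.975) * se), ci_hi = exp(b + qnorm(0.975) * se),
           n = nrow(dat), separated = sep)
  })
  out <- dplyr::bind_rows(rows)
  out$p_threshold <- thr
  out$significant <- !out$separated & out$p_value < thr
  out
}
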