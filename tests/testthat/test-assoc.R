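# A compact target cohort with one planted score-disease effect, used by
# several association-grid tests.
make_assoc_fixture <- function(n = 600, n_scores = 4, log_hr = 0.6, seed = 31) {
  set.seed(seed)
  ids <- sprintf("t%04d", 1:n)
  S <- matrix(rnorm(n * n_scores), n, n_scores,
              dimnames = list(ids, sprintf("S%02d", 1:n_scores)))
  scores <- episcore:::matrix_to_tibble(S)
  covars <- tibble::tibble(sample_id = ids, age = rnorm(n, 50, 10),
                           sex = rbinom(n, 1, 0.5),
                           bmi = rnorm(n, 27, 4), smoking = rnorm(n))
  mk_surv <- function(disease, lp) {
    t_ev <- rexp(n, 0.03 * exp(lp))
    cens <- pmin(14, runif(n, 2, 25))
    tibble::tibble(sample_id = ids, disease = disease,
                   time_years = pmax(pmin(t_ev, cens), 1e-6),
                   event = as.integer(t_ev <= cens))
  }
  surv <- dplyr::bind_rows(
    mk_surv("planted", log_hr * S[, 1]),
    mk_surv("nullcond", 0 * S[, 1]))
  list(scores = scores, covars = covars, surv = surv)
}

test_that("the association grid keeps the full FDR family and nests stages", {
  fx <- make_assoc_fixture()
  out <- run_association_grid(fx$scores, fx$surv, fx$covars,
                              basic_covariates = c("age", "sex"),
                              full_covariates = c("age", "sex", "bmi", "smoking"))
  basic <- out[out$stage == "basic", ]
  # one basic row per (score, disease) cell
  expect_equal(nrow(basic), 4 * 2)
  expect_equal(sum(!is.na(basic$fdr_q)), 8)

  # the planted cell survives the nested filter
  planted <- out[out$episcore_id == "S01" & out$disease == "planted", ]
  expect_true(any(planted$stage == "full"))
  expect_true(all(planted$passes_nested))
  full <- out[out$stage == "full", ]
  # nested flag is exactly (basic q < 0.05) & (full p < 0.05)
  expect_equal(full$passes_nested,
               full$fdr_q < 0.05 & !is.na(full$p_value) & full$p_value < 0.05)

  # determinism: identical inputs give identical tables
  out2 <- run_association_grid(fx$scores, fx$surv, fx$covars,
                               basic_covariates = c("age", "sex"),
                               full_covariates = c("age", "sex", "bmi", "smoking"))
  expect_identical(out$log_hazard_ratio, out2$log_hazard_ratio)
})

test_that("cells below the case minimum are recorded, never fatal", {
  fx <- make_assoc_fixture(n = 300)
  # a disease with almost no events
  rare <- fx$surv[fx$surv$disease == "nullcond", ]
  rare$disease <- "rare"
  rare$event <- 0L
  rare$event[1:3] <- 1L
  surv <- dplyr::bind_rows(fx$surv, rare)
  out <- run_association_grid(fx$scores, surv, fx$covars, min_cases = 10)
  rare_rows <- out[out$disease == "rare" & out$stage == "basic", ]
  expect_true(all(grepl("skipped", rare_rows$status)))
  # skipped cells still occupy the FDR family (q present on tested cells only)
  expect_equal(nrow(out[out$stage == "basic", ]), 4 * 3)
})

test_that("extra covariate layers refit only surviving cells cumulatively", {
  fx <- make_assoc_fixture()
  fx$covars$nk_cells <- rnorm(nrow(fx$covars))
  out <- run_association_grid(fx$scores, fx$surv, fx$covars,
                              full_covariates = c("age", "sex", "bmi"),
                              extra_layers = list(cells = "nk_cells"))
  cell_rows <- out[out$stage == "cells", ]
  expect_gt(nrow(cell_rows), 0)
  nested_cells <- unique(paste(out$episcore_id, out$disease)[
    out$stage == "full" & out$passes_nested])
  expect_setequal(paste(cell_rows$episcore_id, cell_rows$disease), nested_cells)
})

test_that("scores are rank-normalised before modelling", {
  fx <- make_assoc_fixture(n = 400)
  skewed <- fx$scores
  skewed$S01 <- exp(skewed$S01)                  # monotone distortion
  out_raw <- run_association_grid(fx$scores, fx$surv, fx$covars)
  out_skew <- run_association_grid(skewed, fx$surv, fx$covars)
  b1 <- out_raw[out_raw$stage == "basic" & out_raw$episcore_id == "S01" &
                  out_raw$disease == "planted", ]
  b2 <- out_skew[out_skew$stage == "basic" & out_skew$episcore_id == "S01" &
                   out_skew$disease == "planted", ]
  # INT is rank-based, so a monotone transform leaves the fit unchanged
  expect_equal(b1$log_hazard_ratio, b2$log_hazard_ratio, tolerance = 1e-10)
})

test_that("follow-up truncation recovers the untruncated fit at the horizon", {
  fx <- make_assoc_fixture(n = 500)
  d <- dplyr::inner_join(fx$scores,
                         fx$surv[fx$surv$disease == "planted", ],
                         by = "sample_id")
  d <- dplyr::left_join(d, fx$covars, by = "sample_id")
  full <- fit_cox(d, c("S01", "age", "sex"))
  tr <- followup_truncation(d, c("S01", "age", "sex"),
                            horizons = c(2, 5, 10, 14, 20))
  expect_equal(tr$log_hazard_ratio[tr$horizon == 20],
               unname(full$coefficients["S01"]), tolerance = 1e-10)
  expect_true(all(tr$status == "ok"))
  expect_true(all(diff(tr$n_events) >= 0))
})

test_that("an effect confined to early follow-up shrinks with the horizon", {
  set.seed(33)
  n <- 3000
  ids <- sprintf("s%05d", 1:n)
  x <- rnorm(n)
  # strong effect during years 0-3, none afterwards
  l0 <- 0.03
  t1 <- rexp(n, l0 * exp(0.8 * x))
  t_ev <- ifelse(t1 < 3, t1, 3 + rexp(n, l0))
  d <- data.frame(sample_id = ids, time_years = pmin(t_ev, 14),
                  event = as.integer(t_ev <= 14), x = x)
  tr <- followup_truncation(d, "x", horizons = c(3, 14))
  expect_gt(tr$log_hazard_ratio[tr$horizon == 3],
            tr$log_hazard_ratio[tr$horizon == 14])
})

test_that("logistic mode estimates odds ratios and flags separation", {
  set.seed(34)
  n <- 1000
  ids <- sprintf("s%04d", 1:n)
  S <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, c("A", "B", "C")))
  scores <- episcore:::matrix_to_tibble(S)
  covars <- tibble::tibble(sample_id = ids, age = rnorm(n, 55, 8),
                           sex = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-1 + 0.4 * S[, 1]))
  outcome <- tibble::tibble(sample_id = ids, outcome = y)
  res <- logistic_assoc(scores, outcome, covars)
  expect_equal(res$p_threshold, rep(0.05 / 3, 3))
  a <- res[res$episcore_id == "A", ]
  expect_gt(a$log_odds_ratio, 0.2)
  expect_true(a$significant)
  # null scores: |log OR| within 3 se
  for (id in c("B", "C")) {
    r <- res[res$episcore_id == id, ]
    expect_lt(abs(r$log_odds_ratio), 3 * r$se)
  }

  # deterministic outcome -> separation flag
  det <- tibble::tibble(sample_id = ids,
                        outcome = as.integer(S[, 1] > median(S[, 1])))
  res2 <- logistic_assoc(scores, det, covars)
  expect_true(res2$separated[res2$episcore_id == "A"])

  expect_error(logistic_assoc(scores,
                              tibble::tibble(sample_id = ids, outcome = 1L),
                              covars),
               "both classes")
})
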