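# broom-style tidiers for the package's fitted objects.

#' Tidy an elastic-net fit
#'
#' @param x An `enet_fit` from [fit_elastic_net()].
#' @param all_terms Include zero coefficients (default `FALSE`).
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @export
tidy.enet_fit <- function(x, all_terms = FALSE, ...) {
  b <- x$coefficients
  out <- tibble(term = c("(Intercept)", names(b)),
                estimate = c(x$intercept, unname(b)))
  if (!all_terms) out <- out[out$term == "(Intercept)" | out$estimate != 0, ]
  out
}

#' @rdname tidy.enet_fit
#' @export
glance.enet_fit <- function(x, ...) {
  tibble(lambda = x$lambda, alpha = x$alpha, n_nonzero = x$n_nonzero,
         objective = x$objective_value, niter = x$niter,
         converged = x$converged)
}

#' Tidy a cross-validation result
#'
#' @param x An `enet_cv` from [cross_validate()].
#' @param ... Unused.
#' @return One row per penalty: `lambda`, `estimate` (mean CV MSE),
#'   `std.error`, `n_nonzero`.
#' @export
tidy.enet_cv <- function(x, ...) {
  tibble(lambda = x$lambda_path, estimate = x$mean_cv_error,
         std.error = x$se, n_nonzero = x$n_nonzero)
}

#' @rdname tidy.enet_cv
#' @export
glance.enet_cv <- function(x, ...) {
  i <- match(x$chosen_lambda, x$lambda_path)
  tibble(chosen_lambda = x$chosen_lambda, rule = x$rule,
         cv_folds = x$config$cv_folds, cv_error = x$mean_cv_error[i],
         n_nonzero = x$n_nonzero[i])
}

#' Tidy a Cox fit
#'
#' @param x A `cox_fit` from [fit_cox()].
#' @param ... Unused.
#' @return One row per design term: `term`, `estimate` (log hazard ratio),
#'   `std.error`, `statistic` (Wald z), `p.value`, `hazard_ratio`,
#'   `conf.low`, `conf.high` (95%, on the hazard-ratio scale).
#' @export
tidy.cox_fit <- function(x, ...) {
  b <- x$coefficients; se <- x$se
  z <- b / se
  tibble(term = names(b), estimate = unname(b), std.error = unname(se),
         statistic = unname(z),
         p.value = 2 * pnorm(abs(unname(z)), lower.tail = FALSE),
         hazard_ratio = exp(unname(b)),
         conf.low = exp(unname(b) - qnorm(0.975) * unname(se)),
         conf.high = exp(unname(b) + qnorm(0.975) * unname(se)))
}

#' @rdname tidy.cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_cases = x$n_cases, n_controls = x$n_controls,
         loglik = x$loglik, null_loglik = x$null_loglik, ties = x$ties,
         iter = x$iter, frailty_variance = x$frailty_variance)
}
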