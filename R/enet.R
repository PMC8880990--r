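#' Elastic-net training configuration
#'
#' Bundles the tuning constants for penalised training. The objective
#' minimised at penalty level lambda is
#' \deqn{\frac{1}{2n}\|y - b_0 - Xb\|^2 +
#'   \lambda\left(\alpha\|b\|_1 + \frac{1-\alpha}{2}\|b\|_2^2\right)}
#'
#' @param alpha L1/L2 mixing parameter in `[0, 1]`; 0.5 (equal mix) is the
#'   default used throughout the pipeline.
#' @param n_lambda Length of the penalty path.
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty on
#'   the path. Default `NULL` resolves to 1e-3 when n > p and 1e-2 otherwise.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling fold assignment.
#' @param tol Convergence tolerance on the relative objective change per
#'   coordinate-descent sweep.
#' @param max_iter Maximum sweeps per penalty level.
#' @param rule Penalty selection rule: `"min"` (CV-error-minimising, default)
#'   or `"1se"` (largest penalty within one standard error of the minimum).
#' @param min_overlap Minimum number of shared samples required between the
#'   methylation and protein tables when training.
#' @return A list of class `enet_config`.
#' @export
enet_config <- function(alpha = 0.5, n_lambda = 100, lambda_min_ratio = NULL,
                        cv_folds = 10, seed = 1, tol = 1e-7, max_iter = 100000,
                        rule = c("min", "1se"), min_overlap = 100) {
  rule <- match.arg(rule)
  if (alpha < 0 || alpha > 1) abort("enet_config: alpha must be in [0, 1]")
  if (cv_folds < 2) abort("enet_config: cv_folds must be >= 2")
  if (tol <= 0) abort("enet_config: tol must be positive")
  structure(list(alpha = alpha, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio, cv_folds = cv_folds,
                 seed = as.integer(seed), tol = tol, max_iter = max_iter,
                 rule = rule, min_overlap = min_overlap),
            class = "enet_config")
}

as_xy <- function(X, y) {
  if (is.data.frame(X)) X <- as_sample_matrix(X, "predictor matrix")
  if (!is.matrix(X)) abort("X must be a matrix or wide data frame")
  y <- as.numeric(y)
  if (length(y) != nrow(X)) abort("length(y) must equal nrow(X)")
  check_finite(X, "X")
  check_finite(y, "y")
  list(X = X, y = y)
}

#' Penalty path for the elastic net
#'
#' Builds the decreasing log-linear lambda sequence starting at the smallest
#' penalty giving an all-zero solution,
#' `lambda_max = max_j |x_j' y| / (n * alpha)` (the KKT stationarity bound of
#' the null model), descending to `lambda_max * lambda_min_ratio`.
#'
#' @param X Predictor matrix (or wide data frame), columns standardized.
#' @param y Centred response vector.
#' @param config An [enet_config()].
#' @return Strictly decreasing numeric vector of length `config$n_lambda`.
#' @export
compute_lambda_path <- function(X, y, config = enet_config()) {
  d <- as_xy(X, y)
  if (config$alpha == 0) {
    abort("compute_lambda_path: lambda_max is undefined for alpha = 0 (pure ridge); supply an explicit lambda grid")
  }
  n <- nrow(d$X)
  lambda_max <- max(abs(crossprod(d$X, d$y))) / (n * config$alpha)
  if (lambda_max <= 1e-10 * max(1, sqrt(mean(d$y^2)))) {
    abort("compute_lambda_path: degenerate path; response is orthogonal to every predictor (lambda_max = 0)")
  }
  ratio <- config$lambda_min_ratio %||%
    (if (n > ncol(d$X)) 1e-3 else 1e-2)
  exp(seq(log(lambda_max), log(lambda_max * ratio),
          length.out = config$n_lambda))
}

#' Fit the elastic net at fixed penalty levels
#'
#' Cyclic coordinate descent with soft-thresholding, warm starts along the
#' path and active-set iteration. Convergence requires the relative objective
#' decrease over a full sweep to fall below `config$tol`; the returned
#' solution satisfies the subgradient stationarity conditions (see
#' [check_kkt()]).
#'
#' @param X Predictor matrix or wide data frame.
#' @param y Response vector.
#' @param lambda Single penalty or decreasing penalty vector.
#' @param config An [enet_config()].
#' @param warm_start Optional coefficient vector (length `ncol(X)`) to start
#'   from.
#' @param intercept Fit an unpenalised intercept (default `TRUE`).
#' @return For a single `lambda`, an object of class `enet_fit` with elements
#'   `lambda`, `alpha`, `coefficients` (named, dense), `intercept`,
#'   `n_nonzero`, `objective_value`, `niter`, `converged`. For a penalty
#'   vector, an `enet_path`: list with the coefficient matrix and per-lambda
#'   metadata.
#' @export
fit_elastic_net <- function(X, y, lambda, config = enet_config(),
                            warm_start = NULL, intercept = TRUE) {
  d <- as_xy(X, y)
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    abort("fit_elastic_net: lambda must be finite and non-negative")
  }
  if (length(lambda) > 1 && any(diff(lambda) > 0)) {
    abort("fit_elastic_net: a lambda path must be decreasing")
  }
  p <- ncol(d$X)
  b0 <- if (is.null(warm_start)) rep(0, p) else {
    if (length(warm_start) != p) abort("fit_elastic_net: warm_start has wrong length")
    as.numeric(warm_start)
  }
  # single-penalty fits are the returned solutions and get the strict
  # subgradient-stationarity guarantee; path fits (the CV workhorse) stop on
  # the relative-objective criterion plus screen-set KKT feasibility
  res <- .enet_cd_path(d$X, d$y, as.numeric(lambda), config$alpha,
                       config$tol, config$max_iter, b0,
                       if (intercept) mean(d$y) else 0, intercept,
                       length(lambda) == 1)
  if (!all(res$converged)) {
    bad <- which(!res$converged)
    abort(sprintf("fit_elastic_net: no convergence at lambda = %s after %d sweeps (tol = %g)",
                  paste(signif(lambda[bad], 4), collapse = ", "),
                  config$max_iter, config$tol))
  }
  rownames(res$beta) <- colnames(d$X)
  if (length(lambda) == 1) {
    enet_fit_at(res, 1, lambda, config, d)
  } else {
    structure(list(lambda = lambda, beta = res$beta, intercept = res$intercept,
                   alpha = config$alpha, niter = res$niter, config = config),
              class = "enet_path")
  }
}

enet_fit_at <- function(res, l, lambda, config, d) {
  b <- res$beta[, l]
  names(b) <- colnames(d$X)
  r <- d$y - res$intercept[l] - drop(d$X %*% b)
  n <- length(d$y)
  obj <- sum(r^2) / (2 * n) +
    lambda * (config$alpha * sum(abs(b)) +
                (1 - config$alpha) / 2 * sum(b^2))
  structure(list(lambda = lambda, alpha = config$alpha, coefficients = b,
                 intercept = res$intercept[l], n_nonzero = sum(b != 0),
                 objective_value = obj, niter = res$niter[l],
                 converged = res$converged[l]),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf("<enet_fit> lambda = %.4g, alpha = %.2f, %d nonzero of %d, objective = %.6g\n",
              x$lambda, x$alpha, x$n_nonzero, length(x$coefficients),
              x$objective_value))
  invisible(x)
}

#' Karush-Kuhn-Tucker residuals of an elastic-net solution
#'
#' For each nonzero coefficient the stationarity condition
#' `x_j'(y - b0 - Xb)/n - lambda (1 - alpha) b_j = lambda alpha sign(b_j)`
#' must hold; for zero coefficients the gradient magnitude must not exceed
#' `lambda alpha`. Returns the largest violation across coordinates — a
#' converged solution has a value near zero (< 1e-6 at default tolerance).
#'
#' @param fit An `enet_fit`.
#' @param X,y The data the fit was computed on.
#' @return Single non-negative number: the maximum KKT violation.
#' @export
check_kkt <- function(fit, X, y) {
  d <- as_xy(X, y)
  b <- fit$coefficients
  n <- nrow(d$X)
  r <- d$y - fit$intercept - drop(d$X %*% b)
  g <- drop(crossprod(d$X, r)) / n
  l1 <- fit$lambda * fit$alpha
  l2 <- fit$lambda * (1 - fit$alpha)
  nz <- b != 0
  v_nz <- if (any(nz)) abs(g[nz] - l2 * b[nz] - l1 * sign(b[nz])) else 0
  v_z <- if (any(!nz)) pmax(0, abs(g[!nz]) - l1) else 0
  max(v_nz, v_z)
}

# Run code with a temporary RNG state derived from `seed`, restoring the
# caller's stream afterwards so package internals never perturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cross-validated penalty selection
#'
#' K-fold cross-validation of the elastic net over the penalty path computed
#' on the full data. Folds are a uniform random permutation given
#' `config$seed` (sizes differ by at most one); the per-penalty criterion is
#' the mean squared prediction error across folds with its standard error
#' (standard deviation of the per-fold means / sqrt(K)).
#'
#' @inheritParams compute_lambda_path
#' @param lambda Optional explicit penalty path; computed from the data by
#'   default.
#' @return An object of class `enet_cv`: `lambda_path`, `mean_cv_error`,
#'   `se`, `n_nonzero`, `fold_assignment` (named integer vector),
#'   `chosen_lambda`, `rule`.
#' @export
cross_validate <- function(X, y, config = enet_config(), lambda = NULL) {
  d <- as_xy(X, y)
  n <- nrow(d$X)
  K <- config$cv_folds
  if (n < K) abort("cross_validate: fewer samples than folds")
  if (is.null(lambda)) lambda <- compute_lambda_path(d$X, d$y, config)

  folds <- with_seed(config$seed, sample(rep_len(seq_len(K), n)))
  names(folds) <- rownames(d$X) %||% as.character(seq_len(n))
  if (min(table(folds)) < 2) abort("cross_validate: a fold has fewer than 2 samples")

  nlam <- length(lambda)
  fold_mse <- matrix(NA_real_, K, nlam)
  for (k in seq_len(K)) {
    tr <- folds != k
    path <- fit_elastic_net(d$X[tr, , drop = FALSE], d$y[tr], lambda, config)
    pred <- d$X[!tr, , drop = FALSE] %*% path$beta
    pred <- sweep(pred, 2, path$intercept, "+")
    fold_mse[k, ] <- colMeans((d$y[!tr] - pred)^2)
  }
  mcv <- colMeans(fold_mse)
  se <- apply(fold_mse, 2, sd) / sqrt(K)

  i_min <- which.min(mcv)
  chosen <- if (config$rule == "min") lambda[i_min] else {
    lambda[min(which(mcv <= mcv[i_min] + se[i_min]))]
  }

  full_path <- fit_elastic_net(d$X, d$y, lambda, config)
  structure(list(lambda_path = lambda, mean_cv_error = mcv, se = se,
                 n_nonzero = colSums(full_path$beta != 0),
                 fold_assignment = folds, chosen_lambda = chosen,
                 rule = config$rule, config = config),
            class = "enet_cv")
}

#' @export
print.enet_cv <- function(x, ...) {
  i <- match(x$chosen_lambda, x$lambda_path)
  cat(sprintf("<enet_cv> %d-fold, %d penalties; chosen lambda = %.4g (rule '%s'), CV MSE = %.4g, %d nonzero\n",
              x$config$cv_folds, length(x$lambda_path), x$chosen_lambda,
              x$rule, x$mean_cv_error[i], x$n_nonzero[i]))
  invisible(x)
}
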