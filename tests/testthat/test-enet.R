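# Predictors built so that x'x/n = 1 exactly, matching the closed-form
# soft-threshold algebra.
unit_column <- function(n, seed) {
  set.seed(seed)
  x <- rnorm(n)
  x <- x - mean(x)
  x / sqrt(sum(x^2) / n)
}

test_that("lambda path starts at the null-model KKT bound", {
  n <- 100
  x <- unit_column(n, 1)
  y0 <- rnorm(n); y0 <- y0 - mean(y0)
  y <- y0 - x * sum(x * y0) / n + 0.5 * x        # force x'y/n = 0.5
  X <- matrix(x, ncol = 1, dimnames = list(sprintf("s%d", 1:n), "x1"))
  cfg <- enet_config(alpha = 0.5, n_lambda = 25)
  path <- compute_lambda_path(X, y, cfg)
  expect_equal(path[1], 0.5 / 0.5, tolerance = 1e-12)  # max|x'y|/(n*alpha)
  expect_length(path, 25)
  expect_true(all(diff(path) < 0))

  expect_error(compute_lambda_path(X, y, enet_config(alpha = 0)),
               "explicit lambda grid")
  y_orth <- y0 - x * sum(x * y0) / n
  expect_error(compute_lambda_path(X, y_orth, cfg), "degenerate|orthogonal")
})

test_that("univariate fit matches the soft-threshold closed form", {
  n <- 200
  x <- unit_column(n, 2)
  y0 <- rnorm(n); y0 <- y0 - mean(y0)
  y <- y0 - x * sum(x * y0) / n + 0.5 * x
  X <- matrix(x, ncol = 1, dimnames = list(sprintf("s%d", 1:n), "x1"))
  f <- fit_elastic_net(X, y, lambda = 0.2, enet_config(alpha = 0.5))
  # b = S(0.5, 0.2*0.5) / (1 + 0.2*0.5)
  expect_equal(unname(f$coefficients), (0.5 - 0.1) / 1.1, tolerance = 1e-9)
  expect_equal(f$n_nonzero, 1L)

  # at or above lambda_max everything is zero
  f0 <- fit_elastic_net(X, y, lambda = 1.0, enet_config(alpha = 0.5))
  expect_equal(unname(f0$coefficients), 0)
  expect_equal(f0$n_nonzero, 0L)
})

test_that("lambda = 0 with p < n reproduces ordinary least squares", {
  set.seed(3)
  n <- 80; p <- 5
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%d", 1:n), paste0("v", 1:p)))
  y <- drop(X %*% c(1, -0.5, 0.25, 0, 2)) + rnorm(n)
  f <- fit_elastic_net(X, y, lambda = 0, enet_config(tol = 1e-12))
  Xi <- cbind(1, X)
  ols <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_equal(unname(f$coefficients), as.numeric(ols[-1]), tolerance = 1e-6)
  expect_equal(f$intercept, ols[1], tolerance = 1e-6)
})

test_that("solutions satisfy the KKT conditions across random problems", {
  set.seed(4)
  for (rep in 1:8) {
    n <- 60; p <- sample(2:40, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%d", 1:n), paste0("v", 1:p)))
    y <- rnorm(n) + drop(X[, 1:2] %*% c(1, -1))
    alpha <- runif(1, 0.1, 1)
    cfg <- enet_config(alpha = alpha)
    lam <- compute_lambda_path(X, y, cfg)[sample(10:90, 1)]
    f <- fit_elastic_net(X, y, lam, cfg)
    expect_lt(check_kkt(f, X, y), 1e-6)
  }
})

test_that("p <= 2 solutions agree with brute-force grid minimization", {
  set.seed(5)
  for (p in 1:2) {
    n <- 50
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%d", 1:n), paste0("v", 1:p)))
    y <- drop(X %*% rep(0.8, p)) + rnorm(n)
    for (lam in c(0.05, 0.3)) {
      f <- fit_elastic_net(X, y, lam, enet_config(alpha = 0.5, tol = 1e-12))
      oracle <- enet_grid_minimize(X, y, lam, 0.5)
      expect_equal(unname(f$coefficients), oracle$beta, tolerance = 1e-4)
    }
  }
})

test_that("alpha = 1 on an orthonormal-in-1/n design is exact soft-thresholding", {
  n <- 64
  # Haar-like orthogonal columns scaled so x_j'x_j / n = 1
  X <- cbind(rep(c(1, -1), each = n / 2), rep(c(1, -1), times = n / 2))
  colnames(X) <- c("v1", "v2"); rownames(X) <- sprintf("s%d", 1:n)
  set.seed(6)
  y <- drop(X %*% c(0.9, -0.3)) + rnorm(n)
  z <- drop(crossprod(X, y - mean(y))) / n
  for (lam in c(0.1, 0.5)) {
    f <- fit_elastic_net(X, y, lam, enet_config(alpha = 1, tol = 1e-12))
    soft <- sign(z) * pmax(abs(z) - lam, 0)
    expect_equal(unname(f$coefficients), unname(soft), tolerance = 1e-8)
  }
})

test_that("elastic net matches glmnet up to its looser convergence", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  n <- 150; p <- 40
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%d", 1:n), paste0("v", 1:p)))
  X <- scale(X) * sqrt(n / (n - 1))
  y <- drop(X[, 1:3] %*% rep(0.5, 3)) + rnorm(n)
  lam <- 0.1
  f <- fit_elastic_net(X, y, lam, enet_config(alpha = 0.5, tol = 1e-10))
  g <- glmnet::glmnet(X, y, alpha = 0.5, lambda = lam, standardize = FALSE,
                      thresh = 1e-14)
  expect_lt(max(abs(f$coefficients - as.numeric(g$beta))), 0.02)
  # on the exact objective, our solution is at least as good
  ours <- enet_objective(f$coefficients, X, y, lam, 0.5)
  theirs <- enet_objective(as.numeric(g$beta), X, y, lam, 0.5)
  expect_lte(ours, theirs + 1e-10)
})

test_that("cross-validation is deterministic, balanced and finds signal", {
  set.seed(8)
  n <- 100; p <- 12
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%d", 1:n), paste0("v", 1:p)))
  y <- X[, 1]                                    # perfect noiseless signal
  cfg <- enet_config(cv_folds = 5, seed = 99)
  cv <- cross_validate(X, y, cfg)
  cv2 <- cross_validate(X, y, cfg)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_identical(cv$chosen_lambda, cv2$chosen_lambda)
  expect_lte(diff(range(table(cv$fold_assignment))), 1)

  f <- fit_elastic_net(X, y, cv$chosen_lambda, cfg)
  expect_gt(f$coefficients["v1"], 0.9)
  i <- match(cv$chosen_lambda, cv$lambda_path)
  expect_lt(cv$mean_cv_error[i], 0.01)

  expect_error(cross_validate(X[1:4, ], y[1:4], enet_config(cv_folds = 3)),
               "fewer than 2")
})

test_that("pure-noise responses select the empty model under the 1se rule", {
  set.seed(9)
  empty <- vapply(1:25, function(s) {
    n <- 60; p <- 15
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%d", 1:n), paste0("v", 1:p)))
    y <- rnorm(n)
    cfg <- enet_config(cv_folds = 5, seed = s, n_lambda = 50, rule = "1se")
    cv <- cross_validate(X, y, cfg)
    f <- fit_elastic_net(X, y, cv$chosen_lambda, cfg)
    f$n_nonzero == 0
  }, logical(1))
  expect_gt(mean(empty), 0.5)
  # the CV-minimising rule still keeps null models very small
  set.seed(10)
  sizes <- vapply(1:10, function(s) {
    n <- 60; p <- 15
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("s%d", 1:n), paste0("v", 1:p)))
    y <- rnorm(n)
    cfg <- enet_config(cv_folds = 5, seed = s, n_lambda = 50)
    cv <- cross_validate(X, y, cfg)
    fit_elastic_net(X, y, cv$chosen_lambda, cfg)$n_nonzero
  }, integer(1))
  expect_lt(median(sizes), 5)
})

test_that("non-finite inputs and increasing paths are rejected", {
  X <- matrix(c(1, NA, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("v1", "v2")))
  expect_error(fit_elastic_net(X, c(1, 2), 0.1), "non-finite")
  X2 <- matrix(rnorm(20), 10, 2,
               dimnames = list(sprintf("s%d", 1:10), c("v1", "v2")))
  expect_error(fit_elastic_net(X2, rnorm(10), c(0.1, 0.2)), "decreasing")
})
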