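# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the elastic-net oracle minimises the objective by
# nested grid refinement, the Cox oracle evaluates the Efron partial
# likelihood written out directly from its definition, and the BH oracle is
# the step-up formula applied literally.

# Elastic-net objective with the (unpenalised) intercept profiled out:
# for fixed b the optimal intercept is mean(y - Xb).
enet_objective <- function(b, X, y, lambda, alpha) {
  n <- nrow(X)
  r <- y - X %*% b
  r <- r - mean(r)
  sum(r^2) / (2 * n) +
    lambda * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
}

# Brute-force minimiser for p <= 2: coarse grid refined around the incumbent
# until the grid step falls below `step_target`. Independent of coordinate
# descent.
enet_grid_minimize <- function(X, y, lambda, alpha, lim = 3, step_target = 1e-5) {
  p <- ncol(X)
  centre <- rep(0, p)
  half <- lim
  repeat {
    gr <- seq(-half, half, length.out = 41)
    if (p == 1) {
      cand <- matrix(centre[1] + gr, ncol = 1)
    } else {
      cand <- as.matrix(expand.grid(centre[1] + gr, centre[2] + gr))
    }
    vals <- apply(cand, 1, function(b) enet_objective(b, X, y, lambda, alpha))
    centre <- as.numeric(cand[which.min(vals), ])
    step <- gr[2] - gr[1]
    if (step < step_target) break
    half <- 2 * step
  }
  list(beta = centre, objective = min(vals))
}

# Efron-corrected Cox log partial likelihood written from the definition,
# scalar covariate, vectorised over a grid of beta values.
efron_loglik_hand <- function(beta_grid, time, event, x) {
  vapply(beta_grid, function(beta) {
    eta <- beta * x
    w <- exp(eta)
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      D <- which(event == 1 & time == t)
      R <- which(time >= t)
      d <- length(D)
      s0 <- sum(w[R]); s0d <- sum(w[D])
      ll <- ll + sum(eta[D])
      for (l in seq_len(d) - 1) ll <- ll - log(s0 - (l / d) * s0d)
    }
    ll
  }, numeric(1))
}

# Benjamini-Hochberg step-up applied literally: sort, p * m / i, enforce
# monotonicity from the largest down.
bh_stepup_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Small deterministic wide methylation tibble for unit tests.
toy_beta <- function(n = 6, probes = c("cg01", "cg02", "cg03"), seed = 42) {
  set.seed(seed)
  m <- matrix(runif(n * length(probes), 0.1, 0.9), n,
              dimnames = list(sprintf("s%02d", seq_len(n)), probes))
  episcore:::matrix_to_tibble(m)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
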