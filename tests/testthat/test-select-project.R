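make_weights <- function(...) {
  episcore_weights(tibble::tibble(...))
}

test_that("projection is the weighted sum over present CpGs", {
  w <- make_weights(episcore_id = "P1", protein_id = "P1", panel = "somascan",
                    cpg = c("cgA", "cgB"), weight = c(0.5, -0.2))
  Z <- matrix(c(1, -1), 1, 2, dimnames = list("s1", c("cgA", "cgB")))
  zt <- episcore:::matrix_to_tibble(Z)
  attr(zt, "standardized") <- TRUE
  sc <- project_episcores(zt, w, standardize = FALSE)
  expect_equal(sc$P1, 0.5 * 1 + (-0.2) * (-1))   # = 0.7
  expect_equal(attr(sc, "coverage")$probe_coverage, 1)
})

test_that("absent CpGs contribute zero and zero overlap warns with NA scores", {
  w <- make_weights(episcore_id = c("P1", "P1", "P2"),
                    protein_id = c("P1", "P1", "P2"),
                    panel = "somascan",
                    cpg = c("cgA", "cgMissing", "cgGone"),
                    weight = c(0.5, 1.0, 2.0))
  Z <- matrix(c(2, -2), 2, 1, dimnames = list(c("s1", "s2"), "cgA"))
  zt <- episcore:::matrix_to_tibble(Z)
  expect_warning(sc <- project_episcores(zt, w, standardize = FALSE),
                 "no weight CpGs.*P2")
  expect_equal(sc$P1, c(1, -1))                  # missing probe dropped
  expect_true(all(is.na(sc$P2)))
  cov <- attr(sc, "coverage")
  expect_equal(cov$probe_coverage[cov$episcore_id == "P1"], 0.5)
  expect_equal(cov$probe_coverage[cov$episcore_id == "P2"], 0)
})

test_that("projection onto the training matrix reproduces the fit's linear predictor", {
  set.seed(21)
  n <- 120; p <- 60
  cg <- sprintf("cg%05d", 1:p)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(sprintf("s%03d", 1:n), cg))
  X <- scale(X)
  y <- drop(X[, 1:4] %*% c(1, -1, 0.5, 0.5)) + rnorm(n, 0, 0.5)
  cfg <- enet_config(alpha = 0.5)
  lam <- compute_lambda_path(X, y, cfg)[30]
  f <- fit_elastic_net(X, y, lam, cfg)
  nz <- f$coefficients[f$coefficients != 0]
  w <- make_weights(episcore_id = "P1", protein_id = "P1", panel = "test",
                    cpg = names(nz), weight = unname(nz))
  zt <- episcore:::matrix_to_tibble(X)
  sc <- project_episcores(zt, w, standardize = FALSE)
  expect_equal(sc$P1, unname(drop(X %*% f$coefficients)), tolerance = 1e-8)
})

test_that("projection is linear in the matrix", {
  set.seed(22)
  Z <- matrix(rnorm(30), 10, 3,
              dimnames = list(sprintf("s%d", 1:10), c("cgA", "cgB", "cgC")))
  w <- make_weights(episcore_id = "P1", protein_id = "P1", panel = "t",
                    cpg = c("cgA", "cgC"), weight = c(1.5, -2))
  s1 <- project_episcores(episcore:::matrix_to_tibble(Z), w, standardize = FALSE)
  s2 <- project_episcores(episcore:::matrix_to_tibble(3 * Z), w, standardize = FALSE)
  expect_equal(s2$P1, 3 * s1$P1, tolerance = 1e-12)
})

test_that("validation statistics match the closed-form t and Fisher z", {
  # hand-computed oracle: r = 0.8, t = r sqrt(n-2)/sqrt(1-r^2) = 2.309, 3 df
  v <- evaluate_episcore(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(v$pearson_r, 0.8, tolerance = 1e-12)
  tstat <- 0.8 * sqrt(3) / sqrt(1 - 0.64)
  expect_equal(tstat, 2.309, tolerance = 1e-3)
  expect_equal(v$p_value, 2 * pt(tstat, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
  hw <- qnorm(0.975) / sqrt(5 - 3)
  expect_equal(c(v$ci_lo, v$ci_hi), tanh(atanh(0.8) + c(-hw, hw)),
               tolerance = 1e-12)
  expect_true(v$ci_lo <= v$pearson_r && v$pearson_r <= v$ci_hi)

  # perfect and anti-perfect correlation
  expect_equal(evaluate_episcore(1:5, 1:5)$pearson_r, 1)
  expect_equal(evaluate_episcore(1:5, -(1:5))$pearson_r, -1)

  expect_error(evaluate_episcore(1:3, 3:1), ">= 4")
  expect_error(evaluate_episcore(rep(1, 5), 1:5), "degenerate correlation")
})

test_that("the selection rule applies strict thresholds and any-test logic", {
  res <- tibble::tibble(
    episcore_id = c("A", "B", "C", "C"),
    cohort = c("test1", "test1", "testA", "testB"),
    n_test = 100,
    pearson_r = c(0.1, 0.25, 0.4, 0.02),
    p_value = c(0.001, 0.03, 1e-6, 0.9),
    ci_lo = NA_real_, ci_hi = NA_real_, probe_coverage = 1, selected = NA)
  sel <- select_episcores(res)
  # r = 0.1 exactly fails the strict inequality even at tiny p
  expect_false(sel$selected[sel$episcore_id == "A"])
  expect_true(sel$selected[sel$episcore_id == "B"])
  # one passing external test set suffices, provenance recorded
  expect_true(sel$selected[sel$episcore_id == "C"])
  expect_equal(sel$passing_cohort[sel$episcore_id == "C"], "testA")
  # requiring all test sets flips C
  sel_all <- select_episcores(res, require_any_test = FALSE)
  expect_false(sel_all$selected[sel_all$episcore_id == "C"])
})

test_that("selection count is monotone in the thresholds", {
  set.seed(23)
  res <- tibble::tibble(
    episcore_id = sprintf("S%02d", 1:40), cohort = "test", n_test = 200,
    pearson_r = runif(40, -0.2, 0.6), p_value = runif(40),
    ci_lo = NA_real_, ci_hi = NA_real_, probe_coverage = 1, selected = NA)
  counts_r <- vapply(c(0, 0.1, 0.2, 0.4),
                     function(r) sum(select_episcores(res, r_threshold = r)$selected),
                     numeric(1))
  expect_true(all(diff(counts_r) <= 0))
  counts_p <- vapply(c(0.2, 0.05, 0.01),
                     function(p) sum(select_episcores(res, p_threshold = p)$selected),
                     numeric(1))
  expect_true(all(diff(counts_p) <= 0))
})

test_that("scores without external results need a holdout fallback", {
  res <- tibble::tibble(episcore_id = "A", cohort = "test", n_test = 100,
                        pearson_r = 0.3, p_value = 1e-4, ci_lo = NA_real_,
                        ci_hi = NA_real_, probe_coverage = 1, selected = NA)
  w <- make_weights(episcore_id = c("A", "B"), protein_id = c("A", "B"),
                    panel = "t", cpg = c("cg1", "cg2"), weight = c(1, 1))
  expect_error(select_episcores(res, weights = w), "no validation results")
  hold <- tibble::tibble(episcore_id = "B", cohort = "holdout", n_test = 150,
                         pearson_r = 0.2, p_value = 0.01, ci_lo = NA_real_,
                         ci_hi = NA_real_, probe_coverage = 1, selected = NA)
  sel <- select_episcores(res, weights = w, holdout_results = hold)
  expect_true(sel$selected[sel$episcore_id == "B"])
  expect_equal(sel$via[sel$episcore_id == "B"], "holdout")
})

test_that("weight files round-trip bit-exactly and reject malformed input", {
  set.seed(24)
  w <- make_weights(
    episcore_id = rep(c("P1", "P2"), c(3, 2)),
    protein_id = rep(c("P1", "P2"), c(3, 2)),
    panel = c(rep("somascan", 3), rep("olink", 2)),
    cpg = sprintf("cg%08d", 1:5),
    weight = rnorm(5) * 10^runif(5, -8, 2))
  attr(w, "training_meta") <- tibble::tibble(episcore_id = c("P1", "P2"),
                                             n_train = c(900, 700))
  path <- withr::local_tempfile(fileext = ".csv")
  write_episcore_weights(w, path)
  w2 <- read_episcore_weights(path)
  expect_identical(w2$weight, w$weight)        # bit-exact
  expect_equal(w2$cpg, w$cpg)
  expect_equal(attr(w2, "training_meta")$n_train, c(900, 700))

  # duplicate (episcore, cpg) pair names the line
  lines <- readLines(path)
  writeLines(c(lines, lines[length(lines)]), path)
  expect_error(read_episcore_weights(path),
               sprintf("line %d", length(lines) + 1))

  # non-numeric weight
  writeLines(c(lines[-length(lines)],
               "P9,P9,olink,cg00000099,notanumber"), path)
  expect_error(read_episcore_weights(path), "non-numeric weight")

  # unknown extra column accepted with a warning
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("episcore_id,protein_id,panel,cpg,weight,gene",
               "P1,P1,somascan,cg1,0.5,ABC"), path2)
  expect_warning(w3 <- read_episcore_weights(path2), "unknown columns gene")
  expect_equal(w3$weight, 0.5)
})

test_that("training recovers planted CpGs and returns empty sets for null proteins", {
  set.seed(25)
  n <- 500; p <- 1000
  cg <- sprintf("cg%05d", 1:p)
  ids <- sprintf("s%04d", 1:n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(ids, cg))
  causal <- c(3, 97, 405, 512, 800)
  signal <- drop(X[, causal] %*% c(1, -1, 0.8, -0.8, 1.2))
  signal <- signal / sd(signal) * sqrt(0.5)
  y_sig <- signal + rnorm(n, 0, sqrt(0.5))     # methylation R^2 = 0.5
  y_null <- rnorm(n)
  prot <- protein_matrix(
    tibble::tibble(sample_id = ids,
                   sig = as.numeric(scale(y_sig)),
                   nul = as.numeric(scale(y_null))),
    "residualized")
  meth <- episcore:::matrix_to_tibble(X)
  attr(meth, "standardized") <- TRUE

  cfg <- enet_config(seed = 42, min_overlap = 100)
  fit_sig <- train_episcore(meth, prot, "sig", cfg)
  hits <- sum(cg[causal] %in% fit_sig$weights$cpg)
  expect_gte(hits, 4)                           # >= 4 of the 5 true CpGs
  expect_lt(nrow(fit_sig$weights), p / 2)       # sparse, never ~p

  fit_null <- train_episcore(meth, prot, "nul", cfg)
  expect_lte(nrow(fit_null$weights), 10)        # empty or near-empty
  meta <- attr(fit_null$weights, "training_meta")
  if (nrow(fit_null$weights) == 0) {
    expect_equal(meta$note, "no features selected")
  }
})

test_that("holdout training excludes the holdout and evaluates on it", {
  set.seed(26)
  n <- 260; p <- 80
  cg <- sprintf("cg%05d", 1:p)
  ids <- sprintf("s%04d", 1:n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(ids, cg))
  y <- drop(X[, 1:3] %*% c(1, 1, -1)) + rnorm(n)
  prot <- protein_matrix(tibble::tibble(sample_id = ids, p1 = y), "residualized")
  meth <- episcore:::matrix_to_tibble(X)
  attr(meth, "standardized") <- TRUE
  out <- train_episcore(meth, prot, "p1",
                        enet_config(seed = 7, min_overlap = 100),
                        holdout = 0.2)
  expect_equal(attr(out$weights, "training_meta")$n_train, 208)
  expect_false(is.null(out$holdout_validation))
  expect_equal(out$holdout_validation$cohort, "holdout")
  expect_gt(out$holdout_validation$pearson_r, 0.5)
})
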