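#' Configuration for synthetic methylation-cohort simulation
#'
#' Defines the generative model used to build matched train/test/target
#' cohorts with planted ground truth: blocks of correlated CpGs on a latent
#' Gaussian scale squashed to beta values, proteins as a variance-budgeted
#' sum of covariate, pQTL-dosage, causal-CpG and noise components, and
#' incident-disease times from an exponential proportional-hazards model
#' driven by the true (noise-free) methylation score, with administrative
#' censoring at 14 years.
#'
#' @param n_train,n_test,n_target Sample counts of the three cohorts.
#' @param n_cpg Number of CpG probes.
#' @param block_size CpGs per correlated block; a `block_size` not dividing
#'   `n_cpg` truncates the last block.
#' @param rho Within-block latent correlation in `[0, 1)`.
#' @param n_proteins Number of proteins.
#' @param r2 Optional explicit per-protein methylation-explained variance
#'   fractions (length `n_proteins`); by default drawn uniformly from
#'   `r2_range`.
#' @param r2_range Range the per-protein methylation R-squared is drawn
#'   from; the default 0.01-0.58 spans weakly to strongly methylation-
#'   determined proteins.
#' @param n_causal_cpgs Causal CpGs per protein.
#' @param pqtl_frac Protein-variance fraction explained by pQTL dosages.
#' @param n_pqtl pQTL variants per protein.
#' @param age_frac,sex_frac Protein-variance fractions for the age and sex
#'   covariate effects.
#' @param diseases Tibble with columns `disease`, `protein` (index of the
#'   protein whose true score drives the hazard) and `log_hr` (per 1-SD of
#'   true score). Default: one planted effect of 0.3 and one null disease.
#' @param baseline_hazard Exponential baseline event rate per year.
#' @param censor_years Administrative censoring horizon (14 years).
#' @param early_censor_prob Probability a subject is additionally censored
#'   uniformly before the horizon (drop-out).
#' @param binary_outcome_logor Log odds ratio per SD of true score for the
#'   auxiliary binary outcome.
#' @param seed Integer seed for the shared generative parameters.
#' @return List of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_train = 500, n_test = 300, n_target = 1000,
                              n_cpg = 2000, block_size = 20, rho = 0.5,
                              n_proteins = 20, r2 = NULL,
                              r2_range = c(0.01, 0.58), n_causal_cpgs = 5,
                              pqtl_frac = 0.1, n_pqtl = 2,
                              age_frac = 0.05, sex_frac = 0.02,
                              diseases = NULL, baseline_hazard = 0.02,
                              censor_years = 14, early_censor_prob = 0.2,
                              binary_outcome_logor = 0.3, seed = 1) {
  if (rho < 0 || rho >= 1) abort("sim_cohort_config: rho must be in [0, 1)")
  if (any(c(n_train, n_test, n_target, n_cpg, n_proteins) <= 0)) {
    abort("sim_cohort_config: counts must be positive")
  }
  if (baseline_hazard <= 0) abort("sim_cohort_config: baseline hazard must be positive")
  if (!is.null(r2) && length(r2) != n_proteins) {
    abort("sim_cohort_config: r2 must have one value per protein")
  }
  budget_max <- max(r2 %||% r2_range[2]) + pqtl_frac + age_frac + sex_frac
  if (budget_max > 1) {
    abort(sprintf("sim_cohort_config: infeasible variance budget (max %.2f > 1)", budget_max))
  }
  diseases <- diseases %||% tibble(disease = c("planted", "null"),
                                   protein = c(1L, 1L), log_hr = c(0.3, 0))
  structure(list(n_train = n_train, n_test = n_test, n_target = n_target,
                 n_cpg = n_cpg, block_size = block_size, rho = rho,
                 n_proteins = n_proteins, r2 = r2, r2_range = r2_range,
                 n_causal_cpgs = n_causal_cpgs, pqtl_frac = pqtl_frac,
                 n_pqtl = n_pqtl, age_frac = age_frac, sex_frac = sex_frac,
                 diseases = diseases, baseline_hazard = baseline_hazard,
                 censor_years = censor_years,
                 early_censor_prob = early_censor_prob,
                 binary_outcome_logor = binary_outcome_logor,
                 seed = as.integer(seed)),
            class = "sim_cohort_config")
}

cpg_ids <- function(n) sprintf("cg%08d", seq_len(n))
block_of <- function(config) {
  (seq_len(config$n_cpg) - 1) %/% config$block_size + 1
}

# Shared generative parameters (probe means, causal sets and weights, pQTL
# architecture, true disease effects) drawn once per config seed so that all
# cohorts of a run share them.
draw_truth_params <- function(config) {
  with_seed(config$seed, {
    n_p <- config$n_proteins
    probe_means <- rnorm(config$n_cpg, 0, 1)
    r2 <- config$r2 %||% runif(n_p, config$r2_range[1], config$r2_range[2])
    blocks <- block_of(config)
    causal <- purrr::map(seq_len(n_p), function(k) {
      if (r2[k] <= 0) {
        return(tibble(protein_id = protein_name(k), cpg = character(),
                      weight = numeric()))
      }
      idx <- sample.int(config$n_cpg, config$n_causal_cpgs)
      w <- rnorm(config$n_causal_cpgs)
      # latent covariance: 1 on diagonal, rho within a block
      same <- outer(blocks[idx], blocks[idx], "==")
      Sig <- ifelse(same, config$rho, 0); diag(Sig) <- 1
      v <- drop(t(w) %*% Sig %*% w)
      w <- w * sqrt(r2[k] / v)
      tibble(protein_id = protein_name(k), cpg = cpg_ids(config$n_cpg)[idx],
             cpg_index = idx, weight = w)
    })
    n_var <- n_p * config$n_pqtl
    maf <- runif(n_var, 0.1, 0.5)
    variant_ids <- sprintf("rs%06d", seq_len(n_var))
    pqtl <- tibble(
      protein_id = rep(protein_name(seq_len(n_p)), each = config$n_pqtl),
      variant_id = variant_ids, maf = maf,
      beta = {
        b <- rnorm(n_var)
        b # scaled per protein below
      })
    # scale pQTL effects so each protein's dosage component has variance pqtl_frac
    for (k in seq_len(n_p)) {
      rows <- which(pqtl$protein_id == protein_name(k))
      v <- sum(pqtl$beta[rows]^2 * 2 * pqtl$maf[rows] * (1 - pqtl$maf[rows]))
      pqtl$beta[rows] <- pqtl$beta[rows] *
        sqrt(config$pqtl_frac / max(v, .Machine$double.eps))
    }
    list(probe_means = probe_means, r2 = r2,
         causal = dplyr::bind_rows(causal), pqtl = pqtl,
         diseases = config$diseases)
  })
}

protein_name <- function(k) sprintf("prot_%02d", k)

#' Simulate a block-correlated methylation matrix
#'
#' Latent Gaussians with equicorrelated blocks (correlation `rho`) are
#' squashed through the inverse logit around per-probe means, yielding beta
#' values in (0, 1). Planted protein effects act on the latent scale, so
#' they stay exactly linear in the latents while the observables remain
#' array-like.
#'
#' @param config A [sim_cohort_config()].
#' @param n Number of samples.
#' @param seed Seed for this cohort's draws.
#' @param id_prefix Sample-ID prefix.
#' @param probe_means Per-probe latent means; drawn from the config seed by
#'   default so cohorts match.
#' @return List: `latent` (n x n_cpg matrix), `beta` (wide tibble of beta
#'   values), `probe_means`.
#' @export
simulate_methylation <- function(config, n = config$n_train,
                                 seed = config$seed, id_prefix = "s",
                                 probe_means = NULL) {
  probe_means <- probe_means %||% draw_truth_params(config)$probe_means
  blocks <- block_of(config)
  Z <- with_seed(seed, {
    Z <- matrix(rnorm(n * config$n_cpg), n, config$n_cpg)
    if (config$rho > 0) {
      for (b in unique(blocks)) {
        j <- which(blocks == b)
        f <- rnorm(n)
        Z[, j] <- sqrt(config$rho) * f + sqrt(1 - config$rho) * Z[, j]
      }
    }
    Z
  })
  ids <- sprintf("%s%05d", id_prefix, seq_len(n))
  dimnames(Z) <- list(ids, cpg_ids(config$n_cpg))
  beta <- plogis(sweep(Z, 2, probe_means, "+"))
  list(latent = Z, beta = matrix_to_tibble(beta), probe_means = probe_means)
}

#' Simulate protein levels over a latent methylation matrix
#'
#' Each protein is `beta_age * age + beta_sex * sex + pQTL dosage effects +
#' causal-CpG effects (latent scale) + Gaussian noise`, with the variance
#' components fixed by the config (an infeasible budget errors). The true
#' methylation component per sample is returned as the planted "true score".
#'
#' @param latent Latent matrix from [simulate_methylation()].
#' @param genotypes Dosage matrix/tibble (samples x variants in `[0, 2]`).
#' @param covariates Tibble with `sample_id`, `age`, `sex`.
#' @param config A [sim_cohort_config()].
#' @param seed Seed for the noise draws.
#' @param params Shared truth parameters from the internal draw; recomputed
#'   from the config by default.
#' @return List: `proteins` (raw-stage [protein_matrix()]), `truth` (list
#'   with per-protein causal weights, target and realized R-squared, true
#'   scores).
#' @export
simulate_proteins <- function(latent, genotypes, covariates, config,
                              seed = config$seed + 1, params = NULL) {
  params <- params %||% draw_truth_params(config)
  G <- as_sample_matrix(genotypes, "genotype table")
  n <- nrow(latent)
  ids <- rownames(latent)
  age <- covariates$age[match(ids, covariates$sample_id)]
  sex <- covariates$sex[match(ids, covariates$sample_id)]
  b_age <- sqrt(config$age_frac) / 10      # age ~ N(50, 10^2)
  b_sex <- sqrt(config$sex_frac) / 0.5     # sex ~ Bernoulli(0.5)

  n_p <- config$n_proteins
  Y <- matrix(0, n, n_p, dimnames = list(ids, protein_name(seq_len(n_p))))
  true_scores <- Y
  realized_r2 <- numeric(n_p)
  noise <- with_seed(seed, matrix(rnorm(n * n_p), n, n_p))
  for (k in seq_len(n_p)) {
    pid <- protein_name(k)
    cw <- params$causal[params$causal$protein_id == pid, ]
    meth_part <- if (nrow(cw)) {
      drop(latent[, cw$cpg_index, drop = FALSE] %*% cw$weight)
    } else rep(0, n)
    pq <- params$pqtl[params$pqtl$protein_id == pid, ]
    geno_part <- drop(G[ids, pq$variant_id, drop = FALSE] %*% pq$beta)
    noise_var <- 1 - params$r2[k] - config$pqtl_frac -
      config$age_frac - config$sex_frac
    if (noise_var < 0) abort("simulate_proteins: infeasible variance budget")
    Y[, k] <- b_age * (age - 50) + b_sex * (sex - 0.5) + geno_part +
      meth_part + sqrt(noise_var) * noise[, k]
    true_scores[, k] <- meth_part
    realized_r2[k] <- if (sd(meth_part) > 0) var(meth_part) / var(Y[, k]) else 0
  }
  list(proteins = protein_matrix(Y, stage = "raw", panel = "synthetic"),
       truth = list(causal = params$causal,
                    r2_target = params$r2, r2_realized = realized_r2,
                    true_scores = matrix_to_tibble(true_scores),
                    pqtl = params$pqtl))
}

#' Simulate incident-disease survival records under proportional hazards
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(log_hr * score)` per disease, where `score` is the
#' standardized true score of the disease's driver protein; censoring is
#' administrative at `censor_years` plus optional uniform early drop-out.
#'
#' @param true_scores Tibble `sample_id` + per-protein true-score columns
#'   (standardized internally).
#' @param config A [sim_cohort_config()].
#' @param seed Seed for the event/censoring draws.
#' @return Long survival tibble: `sample_id`, `disease`, `time_years`,
#'   `event`.
#' @export
simulate_survival <- function(true_scores, config, seed = config$seed + 2) {
  S <- as_sample_matrix(true_scores, "true score table")
  n <- nrow(S)
  with_seed(seed, {
    purrr::pmap(config$diseases, function(disease, protein, log_hr) {
      s <- S[, protein]
      s <- if (sd(s) > 0) (s - mean(s)) / sd(s) else s * 0
      rate <- config$baseline_hazard * exp(log_hr * s)
      T_ev <- rexp(n, rate)
      C <- rep(config$censor_years, n)
      early <- runif(n) < config$early_censor_prob
      C[early] <- runif(sum(early), 0, config$censor_years)
      tibble(sample_id = rownames(S), disease = disease,
             time_years = pmax(pmin(T_ev, C), 1e-6),
             event = as.integer(T_ev <= C))
    }) |> dplyr::bind_rows()
  })
}

simulate_covariates <- function(config, ids, seed) {
  with_seed(seed, tibble(sample_id = ids,
                         age = rnorm(length(ids), 50, 10),
                         sex = rbinom(length(ids), 1, 0.5)))
}

simulate_genotypes <- function(params, ids, seed) {
  v <- dplyr::distinct(params$pqtl, .data$variant_id, .data$maf)
  G <- with_seed(seed, vapply(v$maf, function(m) rbinom(length(ids), 2, m),
                              numeric(length(ids))))
  dimnames(G) <- list(ids, v$variant_id)
  G
}

#' Generate matched synthetic train/test/target cohorts
#'
#' Composes the methylation, protein and survival simulators into three
#' cohorts sharing all generative parameters (probe means, causal CpG sets
#' and weights, pQTL architecture, disease effects) but with independent,
#' disjoint samples, so the full train-select-project-associate pipeline can
#' be exercised against known truth.
#'
#' @param config A [sim_cohort_config()].
#' @return List of class `synthetic_cohort` with elements `train`, `test`,
#'   `target` (each: `beta`, `latent`, `genotypes`, `covariates`,
#'   `proteins`; the target also has `survival` and `binary_outcome`),
#'   `pqtl_map` ([pqtl_map()] of the true architecture) and `truth` (planted
#'   parameters, realized R-squared and true scores per cohort).
#' @export
generate_cohort <- function(config = sim_cohort_config()) {
  params <- draw_truth_params(config)
  sizes <- c(train = config$n_train, test = config$n_test,
             target = config$n_target)
  cohorts <- purrr::imap(sizes, function(n, nm) {
    off <- match(nm, names(sizes))
    meth <- simulate_methylation(config, n = n, seed = config$seed + 10 * off,
                                 id_prefix = paste0(nm, "_"),
                                 probe_means = params$probe_means)
    ids <- rownames(meth$latent)
    cov <- simulate_covariates(config, ids, seed = config$seed + 10 * off + 1)
    G <- simulate_genotypes(params, ids, seed = config$seed + 10 * off + 2)
    pr <- simulate_proteins(meth$latent, G, cov, config,
                            seed = config$seed + 10 * off + 3, params = params)
    list(beta = meth$beta, latent = meth$latent, genotypes = matrix_to_tibble(G),
         covariates = cov, proteins = pr$proteins, truth = pr$truth)
  })
  target <- cohorts$target
  target$survival <- simulate_survival(target$truth$true_scores, config,
                                       seed = config$seed + 41)
  target$binary_outcome <- with_seed(config$seed + 42, {
    s <- as_sample_matrix(target$truth$true_scores, "true scores")[, config$diseases$protein[1]]
    s <- if (sd(s) > 0) (s - mean(s)) / sd(s) else s * 0
    p <- plogis(-2 + config$binary_outcome_logor * s)
    tibble(sample_id = rownames(target$latent),
           outcome = rbinom(length(p), 1, p))
  })
  cohorts$target <- target
  structure(list(train = cohorts$train, test = cohorts$test,
                 target = cohorts$target,
                 pqtl_map = pqtl_map(params$pqtl),
                 truth = list(params = params,
                              r2_target = params$r2,
                              per_cohort = purrr::map(cohorts, "truth")),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> train %d / test %d / target %d samples, %d CpGs, %d proteins, %d diseases\n",
              x$config$n_train, x$config$n_test, x$config$n_target,
              x$config$n_cpg, x$config$n_proteins, nrow(x$config$diseases)))
  invisible(x)
}
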