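# Cox proportional-hazards fitting by Newton-Raphson on the partial
# likelihood with Efron (default) or Breslow handling of tied event times.

# Precompute the sorting / tie-group structure of a survival dataset.
# Rows are sorted by decreasing time so risk-set sums are cumulative sums.
cox_structure <- function(time, event, X) {
  ord <- order(-time)
  time <- time[ord]; event <- event[ord] == 1
  X <- X[ord, , drop = FALSE]
  ev_idx <- which(event)
  d_total <- length(ev_idx)
  # tie group per event = its event time; risk set boundary = last sorted row
  # sharing that time (all rows with time >= t precede it in the ordering)
  grp <- match(time[ev_idx], unique(time[ev_idx]))
  riskend <- vapply(unique(time[ev_idx]),
                    function(t) max(which(time == t)), integer(1))
  d_g <- tabulate(grp)
  # expansion: each group contributes terms l = 0 .. d_g - 1
  exp_g <- rep(seq_along(d_g), d_g)
  exp_l <- unlist(lapply(d_g, function(d) seq_len(d) - 1), use.names = FALSE)
  list(time = time, event = event, X = X, ev_idx = ev_idx, grp = grp,
       riskend = riskend, d_g = d_g, exp_g = exp_g, exp_l = exp_l,
       d_total = d_total, n = length(time))
}

# Efron/Breslow log partial likelihood, score vector and observed
# information at coefficient vector beta. `frac` of the tied-death sums is
# subtracted per expansion term: l/d for Efron, 0 for Breslow.
cox_ll <- function(st, beta, ties = "efron", want_resid = FALSE) {
  X <- st$X; p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)                       # guard exp overflow; cancels in ratios
  w <- exp(eta)
  wX <- w * X
  cum0 <- cumsum(w)
  cum1 <- apply(wX, 2, cumsum)
  if (p == 1) cum1 <- matrix(cum1, ncol = 1)
  # upper-triangle cross products for the information matrix
  ut <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  XX <- X[, ut[, 1], drop = FALSE] * X[, ut[, 2], drop = FALSE]
  cum2 <- apply(w * XX, 2, cumsum)
  if (nrow(ut) == 1) cum2 <- matrix(cum2, ncol = 1)

  ev <- st$ev_idx
  S0d <- rowsum(w[ev], st$grp)[, 1]
  S1d <- rowsum(wX[ev, , drop = FALSE], st$grp)
  S2d <- rowsum((w * XX)[ev, , drop = FALSE], st$grp)

  g <- st$exp_g
  frac <- if (ties == "efron") st$exp_l / st$d_g[g] else rep(0, length(g))
  re <- st$riskend[g]
  M0 <- cum0[re] - frac * S0d[g]
  M1 <- cum1[re, , drop = FALSE] - frac * S1d[g, , drop = FALSE]
  M2 <- cum2[re, , drop = FALSE] - frac * S2d[g, , drop = FALSE]

  mean1 <- M1 / M0
  ll <- sum(eta[ev]) - sum(log(M0))
  U <- colSums(X[ev, , drop = FALSE]) - colSums(mean1)

  I <- matrix(0, p, p)
  v <- colSums(M2 / M0) - colSums(mean1[, ut[, 1], drop = FALSE] *
                                    mean1[, ut[, 2], drop = FALSE])
  I[cbind(ut[, 1], ut[, 2])] <- v
  I[cbind(ut[, 2], ut[, 1])] <- v

  out <- list(ll = ll, U = U, I = I)
  if (want_resid) {
    # Schoenfeld residuals, one per death; within a tie group the l-th death
    # uses the Efron-downweighted risk-set mean
    out$schoenfeld <- X[ev, , drop = FALSE] - mean1
    out$event_time <- st$time[ev]
    # per-event risk-set covariance V_k (upper-triangle layout), needed for
    # the exact correlation-with-time score test
    out$vk <- M2 / M0 - mean1[, ut[, 1], drop = FALSE] *
      mean1[, ut[, 2], drop = FALSE]
    out$ut <- ut
  }
  out
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the tie-corrected Cox partial likelihood by Newton-Raphson with
#' step halving. Efron's correction for tied event times is the default
#' (Breslow available); with no ties the two coincide. An optional shared
#' gamma frailty per family cluster approximates kinship-based relatedness
#' modelling and is fitted through [survival::coxph()] with a `frailty()`
#' term.
#'
#' @param data Data frame holding the time, event and term columns, one row
#'   per subject.
#' @param terms Character vector of design columns (the score of interest
#'   plus covariates); character/logical/factor columns are expanded to
#'   full-rank indicator contrasts.
#' @param time,event Column names (defaults `"time_years"`, `"event"`).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param frailty_by Optional column name with family/cluster labels for a
#'   shared gamma frailty.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `cox_fit`: coefficients (log hazard ratios), SEs,
#'   variance matrix, log-likelihoods, case/control counts and the Schoenfeld
#'   residual material used by [schoenfeld_ph_test()]. Use [tidy()] for
#'   per-term hazard ratios with 95% CIs.
#' @export
fit_cox <- function(data, terms, time = "time_years", event = "event",
                    ties = c("efron", "breslow"), frailty_by = NULL,
                    tol = 1e-9, max_iter = 30) {
  ties <- match.arg(ties)
  miss <- setdiff(c(time, event, terms, frailty_by), names(data))
  if (length(miss)) {
    abort(sprintf("fit_cox: columns not in data: %s", paste(miss, collapse = ", ")))
  }
  keep <- complete.cases(data[c(time, event, terms)])
  data <- data[keep, , drop = FALSE]
  tt <- as.numeric(data[[time]])
  ev <- as.numeric(data[[event]])
  if (any(!ev %in% c(0, 1))) abort("fit_cox: event must be 0/1")
  if (any(!is.finite(tt)) || any(tt <= 0)) abort("fit_cox: times must be finite and positive")
  if (sum(ev) < 1) abort("fit_cox: no events")

  df <- as.data.frame(lapply(data[terms], function(col) {
    if (is.character(col) || is.logical(col)) factor(col) else col
  }), check.names = FALSE)
  X <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  const <- apply(X, 2, function(z) sd(z) == 0)
  if (any(const)) {
    abort(sprintf("fit_cox: constant design column(s): %s",
                  paste(colnames(X)[const], collapse = ", ")))
  }
  check_design_rank(X, "Cox design")

  if (!is.null(frailty_by)) {
    return(fit_cox_frailty(data, X, tt, ev, frailty_by, ties))
  }

  st <- cox_structure(tt, ev, X)
  p <- ncol(X)
  beta <- rep(0, p)
  cur <- cox_ll(st, beta, ties)
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) NULL)
    if (is.null(step)) {
      abort("fit_cox: singular information matrix (design not full rank on the risk sets)")
    }
    # step halving if the likelihood does not improve
    lam <- 1
    repeat {
      cand <- beta + lam * step
      new <- cox_ll(st, cand, ties)
      if (is.finite(new$ll) && new$ll >= cur$ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) abort("fit_cox: step halving failed; likelihood not improvable")
    }
    done <- abs(new$ll - cur$ll) < tol
    beta <- cand; cur <- new
    if (done) break
    if (it == max_iter || max(abs(beta)) > 15) {
      abort("fit_cox: nonconvergent: monotone partial likelihood")
    }
  }

  final <- cox_ll(st, beta, ties, want_resid = TRUE)
  V <- solve(final$I)
  names(beta) <- colnames(X)
  se <- sqrt(diag(V))
  structure(list(
    coefficients = beta, se = setNames(se, colnames(X)), vcov = V,
    loglik = final$ll, null_loglik = cox_ll(st, rep(0, p), ties)$ll,
    n = st$n, n_cases = sum(ev), n_controls = sum(ev == 0),
    ties = ties, iter = it, terms = terms, design_names = colnames(X),
    schoenfeld = final$schoenfeld, event_time = final$event_time,
    schoenfeld_vk = final$vk, vk_ut = final$ut,
    frailty_variance = NA_real_, engine = "episcore"),
    class = "cox_fit")
}

fit_cox_frailty <- function(data, X, tt, ev, frailty_by, ties) {
  fd <- data.frame(.time = tt, .event = ev, X, check.names = FALSE)
  fd$.cluster <- as.character(data[[frailty_by]])
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + "),
    "+ survival::frailty(.cluster, distribution = 'gamma')"))
  f <- survival::coxph(fml, data = fd, ties = ties)
  idx <- seq_len(ncol(X))
  beta <- coef(f)[idx]
  names(beta) <- colnames(X)
  V <- f$var[idx, idx, drop = FALSE]
  structure(list(
    coefficients = beta, se = setNames(sqrt(diag(V)), colnames(X)), vcov = V,
    loglik = f$loglik[2], null_loglik = f$loglik[1],
    n = length(tt), n_cases = sum(ev), n_controls = sum(ev == 0),
    ties = ties, iter = f$iter[1], terms = colnames(X),
    design_names = colnames(X), schoenfeld = NULL, event_time = NULL,
    frailty_variance = f$history[[1]]$theta %||% NA_real_,
    coxph_fit = f, engine = "coxph-frailty"),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %s ties, %d cases / %d controls, loglik %.3f\n",
              x$ties, x$n_cases, x$n_controls, x$loglik))
  print(tidy(x))
  invisible(x)
}

#' Schoenfeld test of the proportional-hazards assumption
#'
#' Correlation-with-time score test on the Schoenfeld residuals
#' (Grambsch-Therneau), per design term and globally, with the identity time
#' transform. The score for a time-varying coefficient `beta + theta * t` at
#' `theta = 0` is `U = sum_k g_k s_k` over events `k` (with `g` the centred
#' event time and `s_k` the Schoenfeld residual); its variance is computed
#' from the per-event risk-set covariances, so the statistic agrees with
#' modern [survival::cox.zph()]. A small p-value indicates the term's effect
#' drifts with follow-up time, violating proportional hazards.
#'
#' @param fit A `cox_fit` from [fit_cox()].
#' @return Tibble with one row per design term plus a `GLOBAL` row: `term`,
#'   `chisq`, `df`, `p_value`.
#' @export
schoenfeld_ph_test <- function(fit) {
  if (!inherits(fit, "cox_fit")) abort("schoenfeld_ph_test: need a cox_fit")
  if (fit$engine == "coxph-frailty") {
    z <- survival::cox.zph(fit$coxph_fit, transform = "identity")$table
    return(tibble(term = rownames(z), chisq = z[, "chisq"],
                  df = z[, "df"], p_value = z[, "p"]))
  }
  s <- fit$schoenfeld
  d <- nrow(s)
  if (is.null(s) || d < 2) abort("schoenfeld_ph_test: need at least 2 events")
  p <- ncol(s)
  g <- fit$event_time
  g <- g - mean(g)
  if (all(g == 0)) abort("schoenfeld_ph_test: all events at one time")

  # reconstruct per-event V_k from the upper-triangle layout and accumulate
  # A = sum V_k, B = sum g_k V_k, C = sum g_k^2 V_k
  ut <- fit$vk_ut
  vk <- fit$schoenfeld_vk
  fold <- function(w) {
    M <- matrix(0, p, p)
    v <- colSums(w * vk)
    M[cbind(ut[, 1], ut[, 2])] <- v
    M[cbind(ut[, 2], ut[, 1])] <- v
    M
  }
  A <- fold(rep(1, d)); B <- fold(g); C <- fold(g^2)
  U <- drop(crossprod(g, s))
  Vgg <- C - B %*% solve(A, B)

  per_chisq <- unname(U^2 / diag(Vgg))
  global_chisq <- drop(t(U) %*% solve(Vgg, U))
  tibble(term = c(fit$design_names, "GLOBAL"),
         chisq = c(per_chisq, global_chisq),
         df = c(rep(1, p), p),
         p_value = pchisq(c(per_chisq, global_chisq),
                          df = c(rep(1, p), p), lower.tail = FALSE))
}
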