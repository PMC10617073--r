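# Shared fixtures and independent oracles for the test suite.

FIXTURE_Q0 <- c(0.10, 0.001, 0.24, 0.09)  # per month: 1->2, 1->3, 2->1, 2->3

fixture_model <- function() {
  intensity_model(transition_structure(), log_q0 = log(FIXTURE_Q0))
}

# single-covariate generating model: hazard ratio `hr` on one transition
effect_model <- function(hr, pair, covariate) {
  s <- transition_structure()
  beta <- matrix(0, 4, 1, dimnames = list(NULL, covariate))
  k <- which(s$allowed[, 1] == pair[1] & s$allowed[, 2] == pair[2])
  beta[k, 1] <- log(hr)
  intensity_model(s, log_q0 = log(FIXTURE_Q0), beta = beta,
                  covariates = covariate)
}

# random valid 3-state generator with death absorbing
random_Q <- function() {
  m <- intensity_model(transition_structure(),
                       log_q0 = log(stats::runif(4, 0.005, 0.5)))
  build_Q(m)
}

# independent oracle: numerically integrate the Kolmogorov forward
# equations dP/dt = P Q from P(0) = I
ode_transition_probability <- function(Q, t) {
  n <- nrow(Q)
  deriv <- function(time, y, parms) {
    P <- matrix(y, n, n)
    list(as.vector(P %*% Q))
  }
  out <- deSolve::ode(y = as.vector(diag(n)), times = c(0, t), func = deriv,
                      rtol = 1e-12, atol = 1e-14)
  matrix(out[2, -1], n, n)
}

# small hand-built panel: one subject per row-list of (time, state)
panel_from_visits <- function(visits, min_visits = 2L, covariates = NULL) {
  rows <- do.call(rbind, lapply(seq_along(visits), function(i) {
    v <- visits[[i]]
    df <- data.frame(subject = sprintf("P%03d", i), time = v$time,
                     state = v$state)
    if (!is.null(covariates))
      for (cv in names(covariates)) df[[cv]] <- covariates[[cv]][i]
    df
  }))
  panel_data(rows, covariates = names(covariates) %||% character(),
             min_visits = min_visits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# panel realising exact per-pair transition counts: one 2-visit subject per
# observed pair (used to reproduce printed transition tables)
panel_from_pair_counts <- function(counts) {
  visits <- list()
  for (r in 1:3) for (s in 1:3) {
    k <- counts[r, s]
    if (k > 0)
      visits <- c(visits, replicate(k, list(time = c(0, 3), state = c(r, s)),
                                    simplify = FALSE))
  }
  panel_from_visits(visits)
}

# simulate one scenario replicate and fit the single-covariate model;
# returns the fitted HR (and Wald interval pieces) for the focal pair
sim_fit_hr <- function(hr_true, pair, covariate, prevalence, n, seed,
                       hessian = TRUE) {
  marg <- c(0.5, 0.5, 0.47, 0.322, 0.258, 0.319)
  names(marg) <- c("female", "age60", "hypertension", "diabetes",
                   "hemorrhage", "af")
  marg[covariate] <- prevalence
  spec <- cohort_spec(n_subjects = n, covariate_marginals = marg,
                      true_model = effect_model(hr_true, pair, covariate),
                      seed = seed)
  coh <- generate_cohort(spec)
  f <- suppressWarnings(suppressMessages(
    fit_panel_msm(coh$data, covariates = covariate, hessian = hessian)))
  k <- which(f$model$structure$allowed[, 1] == pair[1] &
               f$model$structure$allowed[, 2] == pair[2])
  b <- f$model$beta[k, 1]
  se <- NA_real_
  if (!is.null(f$covariance)) {
    idx <- 4L + k
    se <- sqrt(max(f$covariance[idx, idx], 0))
  }
  list(hr = exp(b), beta = b, se = se, fit = f)
}
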