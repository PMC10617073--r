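## Panel-data likelihood and maximum-likelihood fitting.
##
## The likelihood of panel-observed Markov data is a product over consecutive
## visit pairs of transition probabilities P(dt) = exp(Q(z) dt). Pairs sharing
## a covariate pattern and interval length share the same P, so pairs are
## aggregated into (z, dt) groups once and each likelihood evaluation costs
## one matrix exponential per group.

# consecutive visit pairs of a panel: from, to, dt, exact flag, z columns
panel_pairs <- function(d, covariates = d$covariates) {
  df <- d$data
  n <- nrow(df)
  same <- df$subject[-1] == df$subject[-n]
  idx2 <- which(same) + 1L
  idx1 <- idx2 - 1L
  out <- data.frame(subject = df$subject[idx1],
                    from = df$state[idx1], to = df$state[idx2],
                    dt = df$time[idx2] - df$time[idx1])
  out$exact <- if ("exact" %in% names(df)) as.logical(df$exact[idx2])
               else rep(FALSE, length(idx2))
  out$exact[is.na(out$exact)] <- FALSE
  for (cv in covariates) out[[cv]] <- df[[cv]][idx1]
  if (any(out$dt <= 0)) stop("non-positive interval between visits")
  out
}

# group pairs by (covariate pattern, dt, exact): each group holds a count
# table so the log-likelihood is sum(counts * log P) per group
aggregate_pairs <- function(d, covariates = d$covariates,
                            n_states = 3L, absorbing = 3L,
                            death_exact = FALSE) {
  pr <- panel_pairs(d, covariates)
  if (!death_exact) pr$exact <- FALSE
  zmat <- as.matrix(pr[, covariates, drop = FALSE])
  key <- do.call(paste, c(list(format(pr$dt, digits = 15), pr$exact),
                          lapply(covariates, function(cv) pr[[cv]]),
                          sep = "\r"))
  groups <- lapply(split(seq_len(nrow(pr)), key), function(rows) {
    g <- list(z = as.numeric(zmat[rows[1], ]), dt = pr$dt[rows[1]],
              exact = pr$exact[rows[1]])
    if (g$exact) {
      g$from_counts <- tabulate(pr$from[rows], n_states)
      g$abs_state <- absorbing[1]
    } else {
      g$counts <- unclass(table(factor(pr$from[rows], seq_len(n_states)),
                                factor(pr$to[rows], seq_len(n_states))))
    }
    g
  })
  names(groups) <- NULL
  groups
}

LOGLIK_FLOOR <- 1e-300

group_loglik <- function(m, g) {
  Q <- build_Q(m, g$z)
  P <- transition_probability(Q, g$dt)
  if (g$exact) {
    tr <- transient_states(m$structure)
    dens <- as.numeric(P[, tr, drop = FALSE] %*% Q[tr, g$abs_state])
    sum(g$from_counts * log(pmax(dens, LOGLIK_FLOOR)))
  } else {
    sum(g$counts * log(pmax(P, LOGLIK_FLOOR)))
  }
}

#' Log-likelihood contribution of one observed visit pair
#'
#' For an ordinary panel observation the contribution is
#' `log P(dt)[from, to]`. With `death_exact = TRUE` and an absorbing
#' destination, the exact-time density is used instead: the chain is in some
#' transient state k just before the recorded death time, so the contribution
#' is `log( sum_k P(dt)[from, k] q_{k,death} )`.
#'
#' @param m an [intensity_model()].
#' @param z covariate vector for the subject.
#' @param from_state,to_state observed states at the two visits.
#' @param dt positive interval between the visits, months.
#' @param death_exact treat an absorbing destination as observed at its
#'   exact time.
#' @return The log-likelihood contribution (probabilities are floored at
#'   1e-300 before taking logs).
#' @export
pair_loglik <- function(m, z, from_state, to_state, dt,
                        death_exact = FALSE) {
  if (dt <= 0) stop("dt must be positive")
  Q <- build_Q(m, z)
  P <- transition_probability(Q, dt)
  if (death_exact && to_state %in% m$structure$absorbing) {
    tr <- transient_states(m$structure)
    dens <- sum(P[from_state, tr] * Q[tr, to_state])
    return(log(max(dens, LOGLIK_FLOOR)))
  }
  log(max(P[from_state, to_state], LOGLIK_FLOOR))
}

#' Total panel log-likelihood of a dataset
#'
#' Sums [pair_loglik()] over every consecutive observation pair of every
#' subject, each evaluated at the subject's baseline covariate profile.
#'
#' @param m an [intensity_model()].
#' @param d a `panel_data` whose covariate columns include `m$covariates`.
#' @param death_exact apply the exact-death density to visit rows flagged
#'   `exact` (see [panel_observe()]); rows without the flag are ordinary
#'   panel observations either way.
#' @return The total log-likelihood.
#' @export
total_loglik <- function(m, d, death_exact = FALSE) {
  groups <- aggregate_pairs(d, m$covariates,
                            n_states = m$structure$n_states,
                            absorbing = m$structure$absorbing,
                            death_exact = death_exact)
  sum(vapply(groups, function(g) group_loglik(m, g), numeric(1)))
}

#' Crude-rate starting values for maximum likelihood
#'
#' For each allowed transition r->s the crude rate is the number of observed
#' r->s visit pairs divided by the total time spent in intervals whose
#' origin state was r — a method-of-moments style initial value. Pairs with
#' no observed transitions fall back to 0.01/month (with a message).
#' Covariate coefficients start at zero.
#'
#' @param d a `panel_data`.
#' @param structure a [transition_structure()].
#' @param covariates covariate names for the returned model (coefficients 0).
#' @param constraint_mode passed to [intensity_model()].
#' @return An [intensity_model()] usable as `init` in [fit_panel_msm()].
#' @export
initialize_from_crude_rates <- function(d, structure = transition_structure(),
                                        covariates = character(),
                                        constraint_mode = "unrestricted") {
  pr <- panel_pairs(d, character())
  q0 <- numeric(nrow(structure$allowed))
  for (k in seq_len(nrow(structure$allowed))) {
    r <- structure$allowed[k, 1]; s <- structure$allowed[k, 2]
    n_rs <- sum(pr$from == r & pr$to == s)
    t_r <- sum(pr$dt[pr$from == r])
    if (n_rs == 0 || t_r == 0) {
      message("no observed ", r, "->", s,
              " transitions; starting rate set to 0.01/month")
      q0[k] <- 0.01
    } else q0[k] <- n_rs / t_r
  }
  intensity_model(structure, log_q0 = log(q0),
                  beta = matrix(0, nrow(structure$allowed),
                                length(covariates)),
                  covariates = covariates, constraint_mode = constraint_mode)
}

## ---- working-scale parameter packing -------------------------------------

n_free_beta <- function(structure, p, mode) {
  if (p == 0L) return(0L)
  switch(mode,
         unrestricted = nrow(structure$allowed) * p,
         progressive_regressive = {
           prog <- structure$allowed[, 2] > structure$allowed[, 1]
           (1L + any(!prog)) * p
         },
         symmetric = p)
}

expand_beta <- function(b_free, structure, p, mode) {
  n_pairs <- nrow(structure$allowed)
  if (p == 0L) return(matrix(0, n_pairs, 0))
  prog <- structure$allowed[, 2] > structure$allowed[, 1]
  switch(mode,
         unrestricted = matrix(b_free, n_pairs, p),
         progressive_regressive = {
           b_p <- b_free[seq_len(p)]
           b_r <- if (any(!prog)) b_free[p + seq_len(p)] else NULL
           t(vapply(seq_len(n_pairs),
                    function(r) if (prog[r]) b_p else b_r, numeric(p)))
         },
         symmetric = t(vapply(seq_len(n_pairs),
                              function(r) if (prog[r]) b_free else -b_free,
                              numeric(p))))
}

pack_theta <- function(m) {
  p <- length(m$covariates)
  b_free <- switch(m$constraint_mode,
    unrestricted = as.numeric(m$beta),
    progressive_regressive = {
      prog <- m$structure$allowed[, 2] > m$structure$allowed[, 1]
      c(m$beta[which(prog)[1], ],
        if (any(!prog)) m$beta[which(!prog)[1], ])
    },
    symmetric = {
      prog <- m$structure$allowed[, 2] > m$structure$allowed[, 1]
      m$beta[which(prog)[1], ]
    })
  if (p == 0L) b_free <- numeric(0)
  c(unname(m$log_q0), b_free)
}

theta_names <- function(structure, covariates, mode) {
  labs <- sprintf("%d->%d", structure$allowed[, 1], structure$allowed[, 2])
  nm <- paste0("logq0(", labs, ")")
  p <- length(covariates)
  if (p == 0L) return(nm)
  bn <- switch(mode,
    unrestricted = as.character(outer(labs, covariates,
                                      function(a, b) paste0("beta(", a, ",", b, ")"))),
    progressive_regressive = {
      prog <- structure$allowed[, 2] > structure$allowed[, 1]
      c(paste0("beta_prog(", covariates, ")"),
        if (any(!prog)) paste0("beta_regr(", covariates, ")"))
    },
    symmetric = paste0("beta_sym(", covariates, ")"))
  c(nm, bn)
}

model_from_theta <- function(theta, structure, covariates, mode) {
  n_pairs <- nrow(structure$allowed)
  p <- length(covariates)
  intensity_model(structure,
                  log_q0 = theta[seq_len(n_pairs)],
                  beta = expand_beta(theta[-seq_len(n_pairs)], structure, p,
                                     mode),
                  covariates = covariates, constraint_mode = mode)
}

## ---- numerical derivatives ------------------------------------------------

# central-difference Hessian, step on the working (log/linear) scale
numerical_hessian <- function(fn, x, step = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  pert <- function(i, h) { y <- x; y[i] <- y[i] + h; y }
  for (i in seq_len(p)) {
    H[i, i] <- (fn(pert(i, step)) - 2 * f0 + fn(pert(i, -step))) / step^2
    for (j in seq_len(p)) {
      if (j >= i) next
      ypp <- pert(i, step); ypp[j] <- ypp[j] + step
      ypm <- pert(i, step); ypm[j] <- ypm[j] - step
      ymp <- pert(i, -step); ymp[j] <- ymp[j] + step
      ymm <- pert(i, -step); ymm[j] <- ymm[j] - step
      H[i, j] <- H[j, i] <-
        (fn(ypp) - fn(ypm) - fn(ymp) + fn(ymm)) / (4 * step^2)
    }
  }
  H
}

## ---- fitting ---------------------------------------------------------------

#' Fit the multistate Markov model to panel data by maximum likelihood
#'
#' Maximises the panel log-likelihood over the unconstrained working
#' parameters (log baseline intensities and covariate coefficients) with a
#' quasi-Newton optimiser. Positivity of the intensities is guaranteed by the
#' log parameterisation. Uncertainty comes from the inverse observed
#' information (central finite-difference Hessian of the negative
#' log-likelihood, step 1e-4 on the working scale); hazard-ratio and
#' intensity intervals are Wald intervals on the working scale, then
#' exponentiated.
#'
#' The fit is deterministic given the data, the starting values (crude rates
#' by default, see [initialize_from_crude_rates()]) and the optimiser
#' options.
#'
#' @param d a `panel_data`.
#' @param structure a [transition_structure()].
#' @param covariates character vector of covariate columns of `d` to include
#'   (default: all of them); use `character()` for the no-covariate model.
#' @param constraint_mode coefficient constraint, see [intensity_model()].
#' @param death_exact use the exact-death density for visit rows flagged
#'   `exact`.
#' @param init optional [intensity_model()] of starting values.
#' @param hessian compute the observed-information covariance (set `FALSE`
#'   to skip, e.g. in large simulation loops that only need point estimates).
#' @param control list: `maxit` (default 500), `reltol` on the
#'   log-likelihood (default 1e-9), `gradtol` gradient-norm report threshold
#'   (default 1e-5).
#' @return Object of class `fitted_msm`: `model` (at the MLE), `loglik`,
#'   `n_params`, `covariance` (or `NULL` if the Hessian was skipped or not
#'   invertible, then flagged in `convergence`), `aic`, `convergence`
#'   (status, iterations, gradient norm), `param_names`, and a data
#'   fingerprint used by [likelihood_ratio_test()].
#' @examples
#' spec <- cohort_spec(n_subjects = 150, seed = 1)
#' coh <- generate_cohort(spec)
#' f <- fit_panel_msm(coh$data, covariates = character(), hessian = FALSE)
#' f$aic
#' @export
fit_panel_msm <- function(d, structure = transition_structure(),
                          covariates = d$covariates,
                          constraint_mode = "unrestricted",
                          death_exact = FALSE, init = NULL, hessian = TRUE,
                          control = list()) {
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-9, gradtol = 1e-5),
                           control)
  groups <- aggregate_pairs(d, covariates, n_states = structure$n_states,
                            absorbing = structure$absorbing,
                            death_exact = death_exact)

  # identifiability screen: warn on allowed pairs never observed
  obs <- matrix(0, structure$n_states, structure$n_states)
  for (g in groups) if (!g$exact) obs <- obs + g$counts
  never <- structure$allowed[obs[structure$allowed] == 0, , drop = FALSE]
  if (nrow(never))
    warning("no observed transitions for allowed pair(s): ",
            paste(sprintf("%d->%d", never[, 1], never[, 2]), collapse = ", "),
            "; the corresponding intensities are weakly identified")

  if (is.null(init))
    init <- initialize_from_crude_rates(d, structure, covariates,
                                        constraint_mode)
  theta0 <- pack_theta(init)
  nms <- theta_names(structure, covariates, constraint_mode)
  n_pairs <- nrow(structure$allowed)

  negll <- function(theta) {
    m <- model_from_theta(theta, structure, covariates, constraint_mode)
    -sum(vapply(groups, function(g) group_loglik(m, g), numeric(1)))
  }
  lower <- c(rep(-20, n_pairs), rep(-10, length(theta0) - n_pairs))
  upper <- c(rep(5, n_pairs), rep(10, length(theta0) - n_pairs))
  opt <- stats::optim(pmin(pmax(theta0, lower), upper), negll,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = ctl$maxit,
                                     factr = ctl$reltol / .Machine$double.eps))
  theta_hat <- opt$par
  # numerical gradient at the optimum for the convergence record
  gr <- vapply(seq_along(theta_hat), function(i) {
    h <- 1e-6
    e <- numeric(length(theta_hat)); e[i] <- h
    (negll(theta_hat + e) - negll(theta_hat - e)) / (2 * h)
  }, numeric(1))

  covariance <- NULL
  cov_flag <- if (hessian) "ok" else "skipped"
  if (hessian) {
    H <- numerical_hessian(negll, theta_hat, step = 1e-4)
    covariance <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(covariance)) {
      cov_flag <- "hessian not invertible"
    } else {
      covariance <- (covariance + t(covariance)) / 2
      dimnames(covariance) <- list(nms, nms)
      if (any(diag(covariance) < 0)) cov_flag <- "negative variance estimate"
    }
  }

  m_hat <- model_from_theta(theta_hat, structure, covariates, constraint_mode)
  ll <- -opt$value
  p <- length(theta_hat)
  base::structure(
    list(model = m_hat, loglik = ll, n_params = p, covariance = covariance,
         aic = -2 * ll + 2 * p,
         convergence = list(status = opt$convergence,
                            message = opt$message %||% "",
                            iterations = opt$counts[["function"]],
                            gradient_norm = sqrt(sum(gr^2)),
                            gradtol = ctl$gradtol,
                            covariance = cov_flag,
                            converged = opt$convergence == 0),
         param_names = nms, theta = stats::setNames(theta_hat, nms),
         covariates = covariates, constraint_mode = constraint_mode,
         death_exact = death_exact,
         data_fingerprint = data_fingerprint(d)),
    class = "fitted_msm"
  )
}

data_fingerprint <- function(d) {
  list(n_subjects = n_subjects(d), n_obs = nrow(d$data),
       state_sum = sum(d$data$state), time_sum = sum(d$data$time),
       covariate_sum = if (length(d$covariates))
         sum(as.matrix(d$data[, d$covariates, drop = FALSE])) else 0)
}

#' @export
print.fitted_msm <- function(x, ...) {
  cat("Fitted panel multistate Markov model\n")
  cat(sprintf("  log-likelihood %.4f, %d parameters, AIC %.2f\n",
              x$loglik, x$n_params, x$aic))
  cat("  convergence:", if (x$convergence$converged) "yes" else
      paste("NO -", x$convergence$message),
      sprintf("(|grad| = %.2g)\n", x$convergence$gradient_norm))
  cat("\nBaseline intensities (per month):\n")
  q0 <- exp(x$model$log_q0)
  se_q <- if (!is.null(x$covariance))
    sqrt(pmax(diag(x$covariance)[seq_along(q0)], 0)) else rep(NA_real_,
                                                              length(q0))
  tab <- data.frame(transition = names(q0), estimate = q0,
                    lower = exp(x$model$log_q0 - 1.96 * se_q),
                    upper = exp(x$model$log_q0 + 1.96 * se_q))
  print(tab, row.names = FALSE, digits = 4)
  if (length(x$covariates)) {
    cat("\nHazard ratios:\n")
    print(hr_table(x), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
logLik.fitted_msm <- function(object, ...) {
  base::structure(object$loglik, df = object$n_params, class = "logLik")
}

#' Akaike information criterion of a fitted model
#'
#' `AIC = -2 log L + 2 p` with `p` the number of estimated parameters.
#'
#' @param f a `fitted_msm`.
#' @export
aic <- function(f) -2 * f$loglik + 2 * f$n_params

#' Hazard-ratio table of a fitted covariate model
#'
#' One row per (transition, covariate component): the estimated hazard ratio
#' `exp(beta)` with its 95% Wald interval from the observed-information
#' covariance.
#'
#' @param f a `fitted_msm` with covariates.
#' @param conf_level confidence level.
#' @return Data frame with `transition`, `covariate`, `hr`, `lower`, `upper`,
#'   `beta`, `se`.
#' @export
hr_table <- function(f, conf_level = 0.95) {
  m <- f$model
  if (!length(m$covariates)) stop("model has no covariates")
  labs <- pair_labels(m$structure)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- list()
  for (cv in m$covariates) {
    for (k in seq_along(labs)) {
      pair <- m$structure$allowed[k, ]
      b <- m$beta[k, cv]
      se <- NA_real_
      if (!is.null(f$covariance) && f$constraint_mode == "unrestricted") {
        idx <- beta_param_index(m, pair, cv)
        v <- f$covariance[idx, idx]
        if (is.finite(v) && v >= 0) se <- sqrt(v)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transition = labs[k], covariate = cv, hr = exp(b),
        lower = exp(b - zq * se), upper = exp(b + zq * se),
        beta = b, se = se)
    }
  }
  do.call(rbind, rows)
}

#' Likelihood-ratio test between two nested fitted models
#'
#' The statistic is twice the log-likelihood difference, referred to a
#' chi-squared distribution with degrees of freedom equal to the difference
#' in parameter count. The two fits must be on identical data (checked via a
#' stored fingerprint) and the null's covariate set must nest in the full's.
#'
#' @param null,full `fitted_msm` objects, `null` nested in `full`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(null, full) {
  if (!isTRUE(all.equal(null$data_fingerprint, full$data_fingerprint)))
    stop("models were fitted to different datasets")
  if (!all(null$covariates %in% full$covariates))
    stop("models are not nested (null covariates not a subset)")
  if (full$n_params < null$n_params)
    stop("models are not nested (full model has fewer parameters)")
  stat <- max(0, 2 * (full$loglik - null$loglik))
  df <- full$n_params - null$n_params
  p <- if (df == 0) as.numeric(stat <= 0) else
    stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Serialize a fitted model to JSON
#'
#' Stores estimates, standard errors, hazard ratios with intervals,
#' log-likelihood, AIC, convergence record and the data fingerprint.
#'
#' @param f a `fitted_msm`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @export
fitted_to_json <- function(f, path = NULL) {
  obj <- list(
    model = jsonlite::fromJSON(intensity_model_to_json(f$model)),
    loglik = f$loglik, n_params = f$n_params, aic = f$aic,
    theta = as.list(f$theta),
    se = if (!is.null(f$covariance))
      as.list(stats::setNames(sqrt(pmax(diag(f$covariance), 0)),
                              f$param_names)) else NULL,
    hr_table = if (length(f$covariates)) hr_table(f) else NULL,
    convergence = f$convergence,
    data_fingerprint = f$data_fingerprint
  )
  if (is.null(path))
    return(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
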