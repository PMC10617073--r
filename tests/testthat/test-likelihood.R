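test_that("pair log-likelihoods match two-state closed forms", {
  s2 <- transition_structure(2L, cbind(1L, 2L), 2L)
  a <- 0.17
  m2 <- intensity_model(s2, log_q0 = log(a))
  t <- 4.5
  # survival in state 1: P_11(t) = exp(-a t)
  expect_equal(pair_loglik(m2, NULL, 1, 1, t), -a * t, tolerance = 1e-10)
  # exact death time: exponential density a exp(-a t)
  expect_equal(pair_loglik(m2, NULL, 1, 2, t, death_exact = TRUE),
               log(a) - a * t, tolerance = 1e-10)
  # panel-observed death: distribution function, not the density
  expect_equal(pair_loglik(m2, NULL, 1, 2, t), log(1 - exp(-a * t)),
               tolerance = 1e-10)
  expect_error(pair_loglik(m2, NULL, 1, 1, 0), "positive")
  # dt -> 0+ from = to: P -> I so the contribution vanishes
  expect_equal(pair_loglik(m2, NULL, 1, 1, 1e-9), 0, tolerance = 1e-8)
})

test_that("total log-likelihood is the sum over observed pairs", {
  skip_if_not_installed("Matrix")
  coh <- generate_cohort(cohort_spec(n_subjects = 50, seed = 21))
  m <- effect_model(1.8, c(1, 2), "hypertension")
  ll <- total_loglik(m, coh$data)
  # independent oracle: loop over raw rows, Matrix::expm for each pair
  df <- coh$data$data
  brute <- 0
  for (id in unique(df$subject)) {
    rows <- which(df$subject == id)
    z <- df$hypertension[rows[1]]
    Q <- build_Q(m, c(hypertension = z))
    for (j in rows[-1]) {
      dt <- df$time[j] - df$time[j - 1]
      P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * dt)))
      brute <- brute + log(P[df$state[j - 1], df$state[j]])
    }
  }
  expect_equal(ll, brute, tolerance = 1e-8)

  # duplicating every subject doubles the log-likelihood
  df2 <- df
  df2$subject <- paste0(df2$subject, "_copy")
  both <- panel_data(rbind(df, df2), covariates = coh$data$covariates,
                     min_visits = 2)
  expect_equal(total_loglik(m, both), 2 * ll, tolerance = 1e-9)
})

test_that("crude-rate initial values are occurrence/exposure ratios", {
  # 10 observed 1->2 pairs over 300 months spent in intervals starting good
  visits <- c(replicate(10, list(time = c(0, 6), state = c(1, 2)),
                        simplify = FALSE),
              replicate(20, list(time = c(0, 12), state = c(1, 1)),
                        simplify = FALSE))
  d <- panel_from_visits(visits)
  init <- suppressMessages(initialize_from_crude_rates(d))
  expect_equal(unname(exp(init$log_q0[1])), 10 / 300)
  # unobserved transitions fall back to 0.01 with a message
  expect_message(initialize_from_crude_rates(d), "0.01")
  expect_equal(unname(exp(suppressMessages(
    initialize_from_crude_rates(d))$log_q0[2])), 0.01)

  # crude rates land within a factor of 2 of truth on simulated data
  coh <- generate_cohort(cohort_spec(n_subjects = 1000, seed = 31))
  init2 <- suppressMessages(initialize_from_crude_rates(coh$data))
  ratio <- exp(init2$log_q0) / FIXTURE_Q0
  expect_true(all(ratio[c(1, 3, 4)] > 0.5 & ratio[c(1, 3, 4)] < 2))
})

test_that("maximum likelihood recovers generating intensities and effects", {
  coh <- generate_cohort(cohort_spec(n_subjects = 1000, seed = 41))
  f <- suppressWarnings(fit_panel_msm(coh$data, covariates = character()))
  expect_true(f$convergence$converged)
  se <- sqrt(pmax(diag(f$covariance), 0))[1:4]
  expect_true(all(abs(f$model$log_q0 - log(FIXTURE_Q0)) <= 3 * se))

  # binary covariate with true hazard ratio 2 on good -> poor
  r <- sim_fit_hr(2.0, c(1, 2), "hypertension", 0.5, n = 2000, seed = 42)
  expect_true(abs(r$beta - log(2)) <= 3 * r$se)

  # refitting from the maximum is a fixed point
  f2 <- suppressWarnings(fit_panel_msm(coh$data, covariates = character(),
                                       init = f$model, hessian = FALSE))
  expect_lt(abs(f2$loglik - f$loglik), 1e-6)
})

test_that("likelihood and estimates are invariant to subject relabeling", {
  coh <- generate_cohort(cohort_spec(n_subjects = 120, seed = 51))
  df <- coh$data$data
  m <- fixture_model()
  ll <- total_loglik(m, coh$data)

  perm <- rev(unique(df$subject))
  df_perm <- df[order(match(df$subject, perm), df$time), ]
  relabel <- stats::setNames(sprintf("Z%04d", seq_along(perm)), perm)
  df_perm$subject <- relabel[df_perm$subject]
  d_perm <- panel_data(df_perm, covariates = coh$data$covariates,
                       min_visits = 2)
  expect_equal(total_loglik(m, d_perm), ll, tolerance = 1e-12)

  f1 <- suppressWarnings(fit_panel_msm(coh$data, covariates = character(),
                                       hessian = FALSE))
  f2 <- suppressWarnings(fit_panel_msm(d_perm, covariates = character(),
                                       hessian = FALSE))
  expect_equal(f1$model$log_q0, f2$model$log_q0, tolerance = 1e-7)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
})

test_that("AIC identity and model nesting behave as expected", {
  coh <- generate_cohort(cohort_spec(n_subjects = 200, seed = 61))
  f0 <- suppressWarnings(fit_panel_msm(coh$data, covariates = character(),
                                       hessian = FALSE))
  expect_identical(f0$aic, -2 * f0$loglik + 2 * f0$n_params)
  expect_identical(aic(f0), f0$aic)
  expect_equal(AIC(f0), f0$aic)

  f1 <- suppressWarnings(fit_panel_msm(coh$data, covariates = "diabetes",
                                       hessian = FALSE))
  # the richer model can never fit worse on the same data
  expect_gte(f1$loglik, f0$loglik - 1e-6)

  # strong true effect: the covariate model wins on AIC
  strong <- generate_cohort(cohort_spec(
    n_subjects = 800, seed = 62,
    true_model = effect_model(3.0, c(1, 2), "hypertension")))
  g0 <- suppressWarnings(fit_panel_msm(strong$data, covariates = character(),
                                       hessian = FALSE))
  g1 <- suppressWarnings(fit_panel_msm(strong$data,
                                       covariates = "hypertension",
                                       hessian = FALSE))
  expect_lt(g1$aic, g0$aic)
  lrt <- likelihood_ratio_test(g0, g1)
  expect_lt(lrt$p_value, 0.05)
})

test_that("likelihood ratio test computes the chi-squared tail and guards nesting", {
  coh <- generate_cohort(cohort_spec(n_subjects = 150, seed = 71))
  f0 <- suppressWarnings(fit_panel_msm(coh$data, covariates = character(),
                                       hessian = FALSE))
  same <- likelihood_ratio_test(f0, f0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # the textbook 1-df critical value 10.83 corresponds to p about 0.001
  expect_equal(pchisq(10.83, 1, lower.tail = FALSE), 0.001, tolerance = 0.005)

  other <- generate_cohort(cohort_spec(n_subjects = 150, seed = 72))
  g <- suppressWarnings(fit_panel_msm(other$data, covariates = character(),
                                      hessian = FALSE))
  expect_error(likelihood_ratio_test(f0, g), "different datasets")
})

test_that("fit results serialize to JSON with estimates and provenance", {
  coh <- generate_cohort(cohort_spec(n_subjects = 150, seed = 81))
  f <- suppressWarnings(fit_panel_msm(coh$data, covariates = "af"))
  path <- withr::local_tempfile(fileext = ".json")
  fitted_to_json(f, path)
  obj <- jsonlite::fromJSON(path)
  expect_equal(obj$loglik, f$loglik)
  expect_equal(obj$aic, f$aic)
  expect_equal(nrow(obj$hr_table), 4)
  expect_true(obj$convergence$converged)
})
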