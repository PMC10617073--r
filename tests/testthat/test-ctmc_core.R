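test_that("build_Q applies proportional covariate effects to the right cells", {
  m0 <- fixture_model()
  Q0 <- build_Q(m0)
  expect_equal(Q0[cbind(c(1, 1, 2, 2), c(2, 3, 1, 3))], FIXTURE_Q0)
  expect_lt(max(abs(rowSums(Q0))), 1e-12)
  expect_equal(Q0[3, ], c("1" = 0, "2" = 0, "3" = 0))

  # null covariate effect leaves the baseline untouched
  m <- intensity_model(transition_structure(), log_q0 = log(FIXTURE_Q0),
                       beta = matrix(0, 4, 2), covariates = c("a", "b"))
  expect_equal(build_Q(m, c(a = 1, b = 1)), Q0)

  # a hazard ratio of 2.34 multiplies the focal intensity only
  m_htn <- effect_model(2.34, c(1, 2), "hypertension")
  Q1 <- build_Q(m_htn, c(hypertension = 1))
  expect_equal(Q1[1, 2], 0.234)
  expect_equal(Q1[cbind(c(1, 2, 2), c(3, 1, 3))],
               Q0[cbind(c(1, 2, 2), c(3, 1, 3))])

  # increasing a coefficient increases only its own intensity
  m_big <- effect_model(3.0, c(1, 2), "hypertension")
  Q2 <- build_Q(m_big, c(hypertension = 1))
  expect_gt(Q2[1, 2], Q1[1, 2])
  expect_equal(Q2[cbind(c(1, 2, 2), c(3, 1, 3))],
               Q1[cbind(c(1, 2, 2), c(3, 1, 3))])

  expect_error(build_Q(m_htn, c(1, 2)), "length")
})

test_that("symmetric constraint negates the recovery coefficient", {
  b <- 0.4
  m <- intensity_model(transition_structure(), log_q0 = log(FIXTURE_Q0),
                       beta = matrix(b, 4, 1), covariates = "x",
                       constraint_mode = "symmetric")
  Q <- build_Q(m, c(x = 1))
  expect_equal(Q[1, 2], 0.10 * exp(b))
  expect_equal(Q[2, 3], 0.09 * exp(b))
  expect_equal(Q[2, 1], 0.24 * exp(-b))
})

test_that("transition probabilities agree with the forward-equation oracle", {
  Q <- build_Q(fixture_model())
  expect_equal(transition_probability(Q, 0), diag(3), ignore_attr = TRUE)
  expect_error(transition_probability(Q, -1), "non-negative")

  # two-state closed form: P_11(t) = exp(-a t)
  s2 <- transition_structure(2L, cbind(1L, 2L), 2L)
  Q2 <- build_Q(intensity_model(s2, log_q0 = log(0.1)))
  expect_equal(transition_probability(Q2, 3)[1, 1], exp(-0.3),
               tolerance = 1e-12)

  skip_if_not_installed("deSolve")
  set.seed(42)
  for (i in 1:10) {
    Q <- random_Q()
    t <- runif(1, 0.05, 60)
    expect_lt(max(abs(transition_probability(Q, t) -
                        ode_transition_probability(Q, t))), 1e-8)
  }
})

test_that("transition matrices satisfy the semigroup and stochasticity laws", {
  set.seed(7)
  for (i in 1:25) {
    Q <- random_Q()
    s <- runif(1, 0.01, 30); t <- runif(1, 0.01, 30)
    Ps <- transition_probability(Q, s)
    Pt <- transition_probability(Q, t)
    Pst <- transition_probability(Q, s + t)
    expect_lt(max(abs(Ps %*% Pt - Pst)), 1e-9)
    expect_lt(max(abs(rowSums(Pst) - 1)), 1e-10)
    expect_true(all(Pst >= 0 & Pst <= 1))
    expect_equal(Pst[3, ], c("1" = 0, "2" = 0, "3" = 1))
    # small-time expansion P(t) = I + Q t + O(t^2)
    h <- 1e-3
    expect_lt(max(abs(transition_probability(Q, h) - diag(3) - Q * h)),
              10 * max(abs(Q))^2 * h^2)
  }
})

test_that("mean sojourn times invert the diagonal exit rates", {
  Q <- build_Q(fixture_model())
  soj <- mean_sojourn_times(Q)
  expect_equal(unname(soj), c(-1 / Q[1, 1], -1 / Q[2, 2]))
  expect_equal(unname(soj[1]), 1 / 0.101)
  Qd <- diag(c(-0.25, -0.101, 0))
  Qd[1, 2] <- 0.25; Qd[2, 1] <- 0.101
  expect_equal(unname(mean_sojourn_times(Qd)), c(4.0, 9.90099, Inf)[1:2],
               tolerance = 1e-6)

  # Monte-Carlo oracle: holding times in state 1 are Exponential(-q_11);
  # a long horizon keeps censoring negligible
  spec <- cohort_spec(n_subjects = 1, visit_schedule = c(0, 600), seed = 1)
  set.seed(123)
  Qf <- build_Q(spec$true_model)
  hold <- replicate(4000, {
    tr <- simulate_trajectory(spec, NULL, 1)
    if (length(tr$jump_times) > 1) tr$jump_times[2] else NA
  })
  hold <- hold[!is.na(hold)]
  se <- sd(hold) / sqrt(length(hold))
  expect_lt(abs(mean(hold) - (-1 / Qf[1, 1])), 3 * se)

  Qz <- matrix(c(0, 0, 0.3, -0.3), 2, 2)
  expect_warning(mean_sojourn_times(Qz), "infinite")
})

test_that("hazard ratios exponentiate coefficients with Wald intervals", {
  m <- effect_model(2.34, c(1, 2), "hypertension")
  expect_equal(hazard_ratio(m, c(1, 2), "hypertension")$hr, 2.34)
  expect_equal(hazard_ratio(m, c(2, 3), "hypertension")$hr, 1.0)
  hr <- hazard_ratio(effect_model(2, c(1, 2), "x"), c(1, 2), "x", se = 0.1)
  expect_equal(hr$lower, exp(log(2) - qnorm(0.975) * 0.1))
  expect_equal(hr$upper, exp(log(2) + qnorm(0.975) * 0.1))
  expect_error(hazard_ratio(m, c(3, 1), "hypertension"), "not an allowed")
})

test_that("intensity models survive a JSON round trip", {
  m <- effect_model(0.54, c(2, 1), "diabetes")
  path <- withr::local_tempfile(fileext = ".json")
  intensity_model_to_json(m, path)
  back <- intensity_model_from_json(path)
  expect_equal(back$log_q0, m$log_q0)
  expect_equal(back$beta, m$beta)
  expect_identical(back$covariates, m$covariates)
  expect_identical(back$structure$allowed, m$structure$allowed)
  z <- c(diabetes = 1)
  expect_equal(build_Q(back, z), build_Q(m, z))
})
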