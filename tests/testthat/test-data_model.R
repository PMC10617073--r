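test_that("MRS maps onto the three states with cuts at 3 and 6", {
  expect_identical(state_from_mrs(0:6), c(1L, 1L, 1L, 2L, 2L, 2L, 3L))
  # total and monotone with exactly two cut points
  states <- state_from_mrs(0:6)
  expect_true(all(diff(states) >= 0))
  expect_identical(sum(diff(states) > 0), 2L)
  expect_error(state_from_mrs(7), "0..6")
  expect_error(state_from_mrs(-1), "0..6")
  expect_error(state_from_mrs(2.5), "0..6")
})

test_that("panel validation enforces ordering, absorbing death and visit minima", {
  ok <- data.frame(subject = "a", time = c(0, 3), state = c(1, 1))
  d <- panel_data(ok, min_visits = 2)
  expect_s3_class(d, "panel_data")
  expect_identical(nrow(d$data), 2L)
  expect_identical(n_subjects(d), 1L)

  out_of_death <- data.frame(subject = "a", time = c(0, 6, 9),
                             state = c(2, 3, 2))
  expect_error(panel_data(out_of_death), "absorbing")
  coerced <- panel_data(out_of_death, coerce = TRUE)
  expect_identical(nrow(coerced$data), 0L)
  expect_match(coerced$dropped$reason, "absorbing")

  dup <- data.frame(subject = "a", time = c(0, 0, 3), state = c(1, 1, 2))
  expect_error(panel_data(dup), "duplicate")

  # default minimum of three visits drops shorter series with a report
  mixed <- data.frame(subject = rep(c("a", "b"), c(2, 3)),
                      time = c(0, 3, 0, 3, 6), state = 1)
  d3 <- panel_data(mixed)
  expect_identical(n_subjects(d3), 1L)
  expect_identical(d3$dropped$subject, "a")
  expect_identical(n_subjects(panel_data(mixed, min_visits = 2)), 2L)

  # a lone visit carries no information even when min_visits = 1 is asked
  lone <- data.frame(subject = "a", time = 0, state = 1)
  expect_identical(n_subjects(panel_data(lone, min_visits = 1)), 0L)
})

test_that("mrs column is mapped and missing scores widen the interval", {
  df <- data.frame(subject = "a", time = c(0, 3, 6, 9), mrs = c(2, NA, 4, 6))
  d <- panel_data(df, min_visits = 2)
  expect_identical(d$data$state, c(1L, 2L, 3L))
  expect_identical(d$data$time, c(0, 6, 9))
})

test_that("a synthetic cohort round-trips through CSV identically", {
  coh <- generate_cohort(cohort_spec(n_subjects = 40, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_panel(path, min_visits = 2)
  expect_equal(back$data$state, coh$data$data$state)
  expect_equal(back$data$time, coh$data$data$time)
  expect_identical(back$covariates, coh$data$covariates)
  expect_equal(back$data[back$covariates], coh$data$data[coh$data$covariates])
  expect_true(file.exists(paste0(path, ".truth.json")))
})

test_that("schema mapping renames columns and errors name the offender", {
  df <- data.frame(id = "a", months = c(0, 3), score = c(1, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  d <- read_panel(path, schema = list(subject = "id", time = "months",
                                      mrs = "score"), min_visits = 2)
  expect_identical(d$data$state, c(1L, 2L))
  expect_error(read_panel(path, schema = list(subject = "nope")), "nope")
})

test_that("transition counts match a brute-force pair scan", {
  d <- panel_from_visits(list(list(time = c(0, 3, 6, 9, 12),
                                   state = c(1, 1, 2, 2, 3))))
  tc <- transition_count_matrix(d)
  expect_identical(as.integer(tc$counts), as.integer(
    matrix(c(1, 0, 0, 1, 1, 0, 0, 1, 0), 3, 3)))

  coh <- generate_cohort(cohort_spec(n_subjects = 20, seed = 2))
  tc2 <- transition_count_matrix(coh$data)
  brute <- matrix(0L, 3, 3)
  df <- coh$data$data
  for (id in unique(df$subject)) {
    s <- df$state[df$subject == id]
    if (length(s) < 2) next
    for (j in 2:length(s)) brute[s[j - 1], s[j]] <- brute[s[j - 1], s[j]] + 1L
  }
  expect_identical(as.integer(tc2$counts), as.integer(brute))
  expect_identical(sum(tc2$counts),
                   sum(table(df$subject) - 1L))
  rs <- rowSums(tc2$counts)
  expect_lt(max(abs(rowSums(tc2$proportions)[rs > 0] - 1)), 1e-12)
  # death row has no exits
  expect_identical(tc2$counts[3, 1] + tc2$counts[3, 2], 0L)
})

test_that("published per-interval transition proportions are recovered from counts", {
  printed <- matrix(c(1505, 256, 0, 167, 730, 0, 2, 102, 104), 3, 3)
  tc <- transition_count_matrix(panel_from_pair_counts(printed))
  expect_identical(as.integer(tc$counts), as.integer(printed))
  expect_equal(round(tc$proportions[1, ], 3),
               c(good = 0.899, poor = 0.100, death = 0.001))
  expect_equal(round(tc$proportions[2, ], 2),
               c(good = 0.24, poor = 0.67, death = 0.09))
  expect_equal(tc$proportions[3, ], c(good = 0, poor = 0, death = 1))
})

test_that("occupancy counts subjects observed at each grid time", {
  d <- panel_from_visits(list(list(time = c(0, 3), state = c(1, 1)),
                              list(time = c(0, 3), state = c(2, 3))))
  occ <- occupancy_table(d, grid = c(0, 3))
  expect_equal(unlist(occ[1, c("good", "poor", "death")], use.names = FALSE),
               c(1, 1, 0))
  expect_equal(occ["Total", "n"], nrow(d$data))

  coh <- generate_cohort(cohort_spec(n_subjects = 50, seed = 9))
  occ2 <- occupancy_table(coh$data)
  expect_true(all(occ2$n[-nrow(occ2)] <= 50))
  expect_equal(occ2["Total", "n"], nrow(coh$data$data))
  # baseline occupancy covers every subject with a baseline visit
  expect_equal(occ2$n[occ2$time == 0 & !is.na(occ2$time)],
               sum(coh$data$data$time == 0))
})
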