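## Observed-vs-expected prevalence and survival diagnostics.
##
## The observed prevalence follows the usual panel convention: a subject's
## state at time t is their last observed state at or before t (LOCF), with
## death persisting; the expected prevalence averages each subject's row of
## P(t) from their observed baseline state under their own covariates.

as_intensity_model <- function(x) {
  if (inherits(x, "fitted_msm")) x$model
  else if (inherits(x, "intensity_model")) x
  else stop("expected a fitted_msm or intensity_model")
}

#' Observed state prevalence on a time grid
#'
#' Assigns each subject a state at every grid time by carrying their last
#' observation forward (death, once observed, persists), then counts. With
#' `mode = "censor"` a subject whose follow-up ended before t (last visit
#' before t, not dead) leaves the denominator at t instead of carrying their
#' last state. Subjects with no observation at or before t are excluded at t
#' in both modes.
#'
#' @param d a `panel_data`.
#' @param grid times in months.
#' @param mode `"locf"` (default) or `"censor"`.
#' @return List with `grid`, `counts` (time x state matrix), `props`
#'   (row-normalised), `n` (denominator per time).
#' @export
observed_prevalence <- function(d, grid, mode = c("locf", "censor")) {
  mode <- match.arg(mode)
  df <- d$data
  counts <- matrix(0L, length(grid), 3,
                   dimnames = list(format(grid), c("good", "poor", "death")))
  rows_by_subject <- split(seq_len(nrow(df)),
                           factor(df$subject, levels = unique(df$subject)))
  for (rows in rows_by_subject) {
    tt <- df$time[rows]
    st <- df$state[rows]
    idx <- findInterval(grid, tt)
    for (k in seq_along(grid)) {
      if (idx[k] == 0L) next
      s <- st[idx[k]]
      if (mode == "censor" && s != 3L && tt[length(tt)] < grid[k]) next
      counts[k, s] <- counts[k, s] + 1L
    }
  }
  n <- rowSums(counts)
  props <- counts / ifelse(n == 0, 1, n)
  list(grid = grid, counts = counts, props = props, n = n)
}

#' Expected state prevalence under a fitted model
#'
#' For each subject the model predicts a distribution over states at time t:
#' the row of the transition probability matrix P(t), built from the
#' subject's covariate profile, starting from their observed baseline state
#' (the process is taken to start for everyone at time 0). The expected
#' prevalence at t is the average of these rows over subjects.
#'
#' @param f a `fitted_msm` or [intensity_model()].
#' @param d the `panel_data` supplying baseline states and covariates.
#' @param grid times in months.
#' @return List with `grid`, `props` (time x state matrix of expected
#'   proportions).
#' @export
expected_prevalence <- function(f, d, grid) {
  m <- as_intensity_model(f)
  df <- d$data
  rows_by_subject <- split(seq_len(nrow(df)),
                           factor(df$subject, levels = unique(df$subject)))
  first <- vapply(rows_by_subject, `[`, integer(1), 1L)
  s0 <- df$state[first]
  zmat <- if (length(m$covariates))
    as.matrix(df[first, m$covariates, drop = FALSE])
  else matrix(0, length(first), 0)
  key <- paste(s0, apply(zmat, 1, paste, collapse = "\r"))
  agg <- matrix(0, length(grid), m$structure$n_states)
  for (rows in split(seq_along(first), key)) {
    z <- zmat[rows[1], ]
    Q <- build_Q(m, z)
    for (k in seq_along(grid)) {
      P <- transition_probability(Q, grid[k])
      agg[k, ] <- agg[k, ] + length(rows) * P[s0[rows[1]], ]
    }
  }
  props <- agg / length(first)
  dimnames(props) <- list(format(grid), c("good", "poor", "death"))
  list(grid = grid, props = props)
}

#' Observed and expected prevalence series
#'
#' Combines [observed_prevalence()] and [expected_prevalence()] on one grid
#' — the standard graphical goodness-of-fit check for panel multistate
#' models. Expected counts are the expected proportions scaled by the
#' observed denominator at each time.
#'
#' @param f a `fitted_msm` or [intensity_model()].
#' @param d a `panel_data`.
#' @param grid times in months; defaults to the distinct observed times.
#' @param mode observed-prevalence denominator convention, see
#'   [observed_prevalence()].
#' @return Object of class `prevalence_series` with elements `grid`,
#'   `observed_counts`, `observed_props`, `expected_counts`,
#'   `expected_props`, `n`.
#' @export
prevalence_series <- function(f, d, grid = sort(unique(d$data$time)),
                              mode = "locf") {
  obs <- observed_prevalence(d, grid, mode)
  exp_ <- expected_prevalence(f, d, grid)
  base::structure(
    list(grid = grid,
         observed_counts = obs$counts, observed_props = obs$props,
         expected_props = exp_$props,
         expected_counts = exp_$props * obs$n,
         n = obs$n),
    class = "prevalence_series"
  )
}

#' @export
print.prevalence_series <- function(x, ...) {
  cat("Observed vs expected prevalence at", length(x$grid), "times\n")
  gap <- abs(x$observed_props - x$expected_props)
  cat(sprintf("  max |observed - expected| proportion: %.4f\n", max(gap)))
  invisible(x)
}

#' Convert a prevalence series to a long data frame
#'
#' @param x a `prevalence_series`.
#' @return Data frame with `time`, `state`, `observed_count`,
#'   `observed_prop`, `expected_count`, `expected_prop`.
#' @export
as.data.frame.prevalence_series <- function(x, ...) {
  states <- colnames(x$observed_counts)
  data.frame(
    time = rep(x$grid, times = length(states)),
    state = rep(states, each = length(x$grid)),
    observed_count = as.vector(x$observed_counts),
    observed_prop = as.vector(x$observed_props),
    expected_count = as.vector(x$expected_counts),
    expected_prop = as.vector(x$expected_props)
  )
}

#' Expected survival curve from a transient state
#'
#' The model-implied probability of being alive at time t for a subject in
#' `from_state` at time 0 with covariate profile `z`:
#' `S(t) = 1 - P(t)[from_state, death]`. Non-increasing with `S(0) = 1`.
#'
#' @param f a `fitted_msm` or [intensity_model()].
#' @param from_state starting transient state.
#' @param z covariate profile (default: reference level, all zero).
#' @param grid times in months.
#' @return Data frame with `time` and `survival`.
#' @export
survival_curve <- function(f, from_state, z = NULL, grid = seq(0, 36, by = 3)) {
  m <- as_intensity_model(f)
  if (from_state %in% m$structure$absorbing)
    stop("from_state must be transient")
  Q <- build_Q(m, z)
  death <- m$structure$absorbing[1]
  surv <- vapply(grid, function(tt)
    1 - transition_probability(Q, tt)[from_state, death], numeric(1))
  data.frame(time = grid, survival = surv)
}
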