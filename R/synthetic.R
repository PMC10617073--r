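#' Specification of a synthetic stroke cohort
#'
#' Describes a cohort to simulate: size, quarterly visit schedule, baseline
#' covariate prevalences, baseline state distribution, the true
#' intensity model generating trajectories, how death is recorded, and
#' optional uninformative dropout. Defaults emulate the observational stroke
#' cohort the model was designed for: 298 subjects followed quarterly to 36
#' months, 45.6% female, 47% hypertensive, 32.2% diabetic, 25.8%
#' hemorrhagic stroke, 31.9% atrial fibrillation, Glasgow coma scale
#' mild/moderate/severe 191/35/72, and 93 good / 205 poor at baseline.
#' The default generator intensities (0.10, 0.001, 0.24, 0.09 per month for
#' good->poor, good->death, poor->good, poor->death) are a fixture chosen so
#' the synthetic per-interval transition proportions resemble the published
#' empirical table; they are not a claim about fitted intensities.
#'
#' Binary covariates are drawn independently at their marginal prevalences
#' (only marginals are known for the real cohort); the two Glasgow indicator
#' columns are drawn jointly from the three-category split so they are never
#' both 1. Baseline state is drawn independently of covariates.
#'
#' @param n_subjects cohort size.
#' @param visit_schedule scheduled visit times in months, starting at 0.
#' @param covariate_marginals named prevalences for the binary covariates.
#' @param gcs_probs probabilities of mild/moderate/severe Glasgow category.
#' @param baseline_state_probs probabilities of starting in each state.
#' @param true_model [intensity_model()] generating the trajectories; its
#'   covariates must be a subset of the generated covariate columns.
#' @param death_recording `"at_next_visit"` records death at the first
#'   scheduled visit after it happens (the panel convention); `"exact_time"`
#'   adds a visit row at the actual death time flagged `exact`.
#' @param dropout_rate per-month hazard of uninformative dropout (0 = none).
#' @param seed integer seed; per-subject substreams are derived from it so
#'   the cohort is reproducible subject by subject.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 298L,
                        visit_schedule = seq(0, 36, by = 3),
                        covariate_marginals = c(female = 0.456,
                                                age60 = 0.5,
                                                hypertension = 0.47,
                                                diabetes = 0.322,
                                                hemorrhage = 0.258,
                                                af = 0.319),
                        gcs_probs = c(mild = 191, moderate = 35,
                                      severe = 72) / 298,
                        baseline_state_probs = c(93, 205, 0) / 298,
                        true_model = intensity_model(
                          transition_structure(),
                          log_q0 = log(c(0.10, 0.001, 0.24, 0.09))),
                        death_recording = c("at_next_visit", "exact_time"),
                        dropout_rate = 0,
                        seed = 1L) {
  death_recording <- match.arg(death_recording)
  if (any(covariate_marginals < 0 | covariate_marginals > 1))
    stop("covariate marginals must be probabilities")
  if (is.null(names(covariate_marginals)))
    stop("covariate_marginals must be named")
  if (abs(sum(gcs_probs) - 1) > 1e-8 || abs(sum(baseline_state_probs) - 1) > 1e-8)
    stop("gcs_probs and baseline_state_probs must each sum to 1")
  visit_schedule <- as.numeric(visit_schedule)
  if (visit_schedule[1] != 0 || any(diff(visit_schedule) <= 0))
    stop("visit_schedule must be strictly increasing and start at 0")
  covs <- c(names(covariate_marginals), "gcs_moderate", "gcs_severe")
  if (!all(true_model$covariates %in% covs))
    stop("true_model covariates must be among: ", paste(covs, collapse = ", "))
  base::structure(
    list(n_subjects = as.integer(n_subjects),
         visit_schedule = visit_schedule,
         covariate_marginals = covariate_marginals,
         gcs_probs = gcs_probs,
         baseline_state_probs = baseline_state_probs,
         true_model = true_model,
         death_recording = death_recording,
         dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Draw one baseline covariate profile
#'
#' Independent Bernoulli draws at the spec's marginal prevalences, plus one
#' categorical draw for the Glasgow coma scale (returned as the two
#' indicator columns `gcs_moderate`, `gcs_severe` against the mild
#' reference). Uses the current RNG state.
#'
#' @param spec a [cohort_spec()].
#' @return Named numeric vector of covariate values in \{0, 1\}.
#' @export
sample_covariates <- function(spec) {
  z <- stats::rbinom(length(spec$covariate_marginals), 1,
                     spec$covariate_marginals)
  names(z) <- names(spec$covariate_marginals)
  gcs <- sample.int(3L, 1L, prob = spec$gcs_probs)
  c(z, gcs_moderate = as.numeric(gcs == 2L),
    gcs_severe = as.numeric(gcs == 3L))
}

#' Simulate one exact continuous-time trajectory
#'
#' Gillespie-style simulation of the continuous-time Markov chain implied by
#' the spec's true model at a covariate profile: holding times are
#' exponential with rate `-q_ii`, the next state is drawn with probabilities
#' `q_ij / (-q_ii)`. Simulation stops at absorption or once the path covers
#' the follow-up horizon. Uses the current RNG state.
#'
#' @param spec a [cohort_spec()].
#' @param z covariate profile (named, matching the true model's covariates).
#' @param start_state baseline state.
#' @return List with `jump_times` (entry times, starting at 0) and `states`
#'   (state entered at each time).
#' @export
simulate_trajectory <- function(spec, z, start_state) {
  Q <- build_Q(spec$true_model, z)
  horizon <- max(spec$visit_schedule)
  times <- 0
  states <- as.integer(start_state)
  t_now <- 0
  s_now <- as.integer(start_state)
  while (t_now <= horizon) {
    rate <- -Q[s_now, s_now]
    if (rate <= 0) break  # absorbed
    t_now <- t_now + stats::rexp(1, rate)
    if (t_now > horizon) break
    probs <- Q[s_now, ]
    probs[s_now] <- 0
    s_now <- sample.int(ncol(Q), 1L, prob = probs)
    times <- c(times, t_now)
    states <- c(states, s_now)
  }
  list(jump_times = times, states = states)
}

#' Read a trajectory off at scheduled visit times
#'
#' Converts an exact path into panel visit records. The state at a scheduled
#' time is the state of the path at that instant. Under
#' `"at_next_visit"` death recording, the subject contributes one death
#' record at the first scheduled visit on or after the death time and no
#' visits after it. Under `"exact_time"`, visits stop at death and a single
#' record at the exact death time is appended, flagged `exact`.
#'
#' @param traj a trajectory from [simulate_trajectory()].
#' @param schedule scheduled visit times.
#' @param death_recording `"at_next_visit"` or `"exact_time"`.
#' @return Data frame with `time`, `state`, `exact`.
#' @export
panel_observe <- function(traj, schedule,
                          death_recording = c("at_next_visit", "exact_time")) {
  death_recording <- match.arg(death_recording)
  st <- traj$states[findInterval(schedule, traj$jump_times)]
  dead <- traj$states[length(traj$states)] == 3L
  death_time <- if (dead) traj$jump_times[length(traj$jump_times)] else Inf
  if (death_recording == "at_next_visit") {
    first_dead <- match(TRUE, st == 3L)
    keep <- if (is.na(first_dead)) seq_along(schedule) else seq_len(first_dead)
    data.frame(time = schedule[keep], state = st[keep],
               exact = rep(FALSE, length(keep)))
  } else {
    keep <- which(schedule < death_time)
    out <- data.frame(time = schedule[keep], state = st[keep],
                      exact = rep(FALSE, length(keep)))
    if (is.finite(death_time) && death_time <= max(schedule))
      out <- rbind(out, data.frame(time = death_time, state = 3L,
                                   exact = TRUE))
    out
  }
}

subject_seed <- function(seed, i) {
  (as.double(seed) * 48271 + as.double(i) * 10007) %% 2147483629 + 1
}

#' Generate a synthetic panel cohort
#'
#' Draws a full cohort from a [cohort_spec()]: covariates, baseline states,
#' exact trajectories, and their panel observation, returning both the
#' validated dataset and the ground truth for recovery studies. Each subject
#' uses a deterministic RNG substream derived from the cohort seed, so the
#' cohort is byte-reproducible and per-subject draws do not depend on
#' ordering.
#'
#' @param spec a [cohort_spec()].
#' @return List of class `synthetic_cohort`: `data` (a `panel_data` with all
#'   covariate columns; subjects reduced to one visit by early death plus
#'   dropout are dropped with a report), `truth` (spec echo, true model,
#'   seed), `trajectories` (per-subject exact paths).
#' @export
generate_cohort <- function(spec) {
  n <- spec$n_subjects
  covs <- c(names(spec$covariate_marginals), "gcs_moderate", "gcs_severe")
  visit_list <- vector("list", n)
  trajs <- vector("list", n)
  zmat <- matrix(NA_real_, n, length(covs), dimnames = list(NULL, covs))
  ids <- sprintf("S%05d", seq_len(n))
  for (i in seq_len(n)) {
    set.seed(subject_seed(spec$seed, i))
    z <- sample_covariates(spec)
    s0 <- sample.int(3L, 1L, prob = spec$baseline_state_probs)
    traj <- simulate_trajectory(spec, z, s0)
    visits <- panel_observe(traj, spec$visit_schedule, spec$death_recording)
    if (spec$dropout_rate > 0) {
      t_drop <- stats::rexp(1, spec$dropout_rate)
      visits <- visits[visits$time <= t_drop | visits$time == 0, ,
                       drop = FALSE]
    }
    zmat[i, ] <- z[covs]
    visit_list[[i]] <- visits
    trajs[[i]] <- c(list(subject = ids[i], start_state = s0,
                         covariates = as.list(z)), traj)
  }
  nv <- vapply(visit_list, nrow, integer(1))
  df <- data.frame(subject = rep(ids, nv),
                   time = unlist(lapply(visit_list, `[[`, "time")),
                   state = unlist(lapply(visit_list, `[[`, "state")),
                   exact = unlist(lapply(visit_list, `[[`, "exact")))
  df <- cbind(df, as.data.frame(zmat[rep(seq_len(n), nv), , drop = FALSE]))
  d <- panel_data(df, covariates = covs, min_visits = 2L)
  base::structure(
    list(data = d,
         truth = list(seed = spec$seed, spec = spec,
                      model = spec$true_model),
         trajectories = trajs),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort (seed ", x$truth$seed, ")\n", sep = "")
  print(x$data)
  invisible(x)
}

#' Write a synthetic cohort to CSV plus a ground-truth sidecar
#'
#' The CSV is the long-format panel consumed by [read_panel()]; the sidecar
#' JSON records the seed, the generating spec, the true model, and the exact
#' trajectories.
#'
#' @param cohort a `synthetic_cohort`.
#' @param path CSV output path.
#' @param sidecar sidecar JSON path (default `<path>.truth.json`).
#' @export
write_cohort <- function(cohort, path,
                         sidecar = paste0(path, ".truth.json")) {
  write_panel(cohort$data, path)
  spec <- cohort$truth$spec
  obj <- list(
    seed = cohort$truth$seed,
    true_model = jsonlite::fromJSON(intensity_model_to_json(spec$true_model)),
    spec = list(n_subjects = spec$n_subjects,
                visit_schedule = spec$visit_schedule,
                covariate_marginals = as.list(spec$covariate_marginals),
                gcs_probs = as.list(spec$gcs_probs),
                baseline_state_probs = spec$baseline_state_probs,
                death_recording = spec$death_recording,
                dropout_rate = spec$dropout_rate),
    trajectories = cohort$trajectories
  )
  jsonlite::write_json(obj, sidecar, digits = NA, auto_unbox = TRUE)
  invisible(c(path, sidecar))
}
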