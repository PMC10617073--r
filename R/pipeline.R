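## Full study pipeline: descriptives -> null fit -> covariate fit ->
## LRT/AIC -> hazard-ratio and sojourn tables -> prevalence and survival
## series, mirroring how a panel multistate analysis is reported.

cheap_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Mean sojourn times per covariate level
#'
#' Reproduces the "average time spent in each transient state by group"
#' presentation: for every covariate component and level, the generator is
#' built at that level and the sojourn times -1/q_ii are read off. With
#' `mode = "reference"` all other covariates sit at their reference (zero)
#' level; with `mode = "marginal"` the sojourn time is averaged over the
#' empirical covariate distribution of the data with the focal component
#' forced to each level.
#'
#' @param f a `fitted_msm` (or [intensity_model()]).
#' @param d the `panel_data` (required for `mode = "marginal"`).
#' @param mode `"reference"` or `"marginal"`.
#' @return Data frame with `covariate`, `level`, and one column of months
#'   per transient state.
#' @export
sojourn_table <- function(f, d = NULL, mode = c("reference", "marginal")) {
  mode <- match.arg(mode)
  m <- as_intensity_model(f)
  covs <- m$covariates
  if (!length(covs)) stop("model has no covariates")
  tr <- transient_states(m$structure)
  state_names <- c("good", "poor", "death")[tr]
  zmat <- NULL
  if (mode == "marginal") {
    if (is.null(d)) stop("marginal mode needs the dataset")
    df <- d$data
    first <- vapply(split(seq_len(nrow(df)),
                          factor(df$subject, levels = unique(df$subject))),
                    `[`, integer(1), 1L)
    zmat <- as.matrix(df[first, covs, drop = FALSE])
  }
  rows <- list()
  for (cv in covs) {
    for (lev in 0:1) {
      if (mode == "reference") {
        z <- stats::setNames(numeric(length(covs)), covs)
        z[cv] <- lev
        soj <- mean_sojourn_times(build_Q(m, z))[as.character(tr)]
      } else {
        zz <- zmat
        zz[, cv] <- lev
        soj <- colMeans(t(apply(zz, 1, function(z)
          mean_sojourn_times(build_Q(m, z))[as.character(tr)])))
      }
      row <- data.frame(covariate = cv, level = lev)
      row[state_names] <- as.list(unname(soj))
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Run the full study pipeline
#'
#' Executes, in order: data loading (or synthetic generation), descriptive
#' tables, the no-covariate fit, the covariate fit, AIC and likelihood-ratio
#' comparison, the hazard-ratio table, the sojourn-time table, the
#' observed-vs-expected prevalence series, and expected survival curves from
#' each transient state. Deterministic given the configuration and seed.
#'
#' @param config named list or YAML/JSON file path with entries:
#'   `input` (CSV path) plus optional `schema`, or `synthetic` (arguments to
#'   [cohort_spec()]); `covariates` (character vector; default: all covariate
#'   columns); `min_visits`, `coerce`; `good_death_allowed` (keep the direct
#'   good-to-death intensity free, default `TRUE`); `constraint_mode`;
#'   `death_exact`; `grid` (prevalence times); `prevalence_mode`;
#'   `sojourn_mode`; `seed`.
#' @param out_dir optional directory; when given, the report JSON and the
#'   CSV tables are written there.
#' @return Object of class `study_report`.
#' @export
run_study <- function(config = list(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::fromJSON(config)
              else yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(input = NULL, schema = NULL, synthetic = NULL,
         covariates = NULL, min_visits = 3L, coerce = FALSE,
         good_death_allowed = TRUE, constraint_mode = "unrestricted",
         death_exact = FALSE, grid = NULL,
         prevalence_mode = "locf", sojourn_mode = "reference",
         seed = 1L),
    config)

  if (!is.null(cfg$input)) {
    d <- read_panel(cfg$input, cfg$schema, min_visits = cfg$min_visits,
                    coerce = cfg$coerce)
  } else if (!is.null(cfg$synthetic)) {
    spec <- do.call(cohort_spec, utils::modifyList(list(seed = cfg$seed),
                                                   cfg$synthetic))
    d <- generate_cohort(spec)$data
  } else stop("config needs either 'input' or 'synthetic'")

  covs <- cfg$covariates %||% d$covariates
  allowed <- cbind(c(1L, 1L, 2L, 2L), c(2L, 3L, 1L, 3L))
  if (!cfg$good_death_allowed) allowed <- allowed[-2, , drop = FALSE]
  structure <- transition_structure(3L, allowed, 3L)
  grid <- cfg$grid %||% sort(unique(d$data$time))

  stage <- "descriptives"
  report <- list()
  result <- tryCatch({
    report$descriptives <- list(
      occupancy = occupancy_table(d, grid[grid %in% d$data$time]),
      transitions = transition_count_matrix(d))
    stage <- "null_fit"
    null_fit <- fit_panel_msm(d, structure, covariates = character(),
                              death_exact = cfg$death_exact)
    stage <- "covariate_fit"
    cov_fit <- fit_panel_msm(d, structure, covariates = covs,
                             constraint_mode = cfg$constraint_mode,
                             death_exact = cfg$death_exact)
    stage <- "model_comparison"
    report$null_fit <- null_fit
    report$covariate_fit <- cov_fit
    report$lrt <- likelihood_ratio_test(null_fit, cov_fit)
    report$aic <- c(null = null_fit$aic, covariate = cov_fit$aic)
    stage <- "hr_table"
    report$hr_table <- hr_table(cov_fit)
    stage <- "sojourn_table"
    report$sojourn_table <- sojourn_table(cov_fit, d, mode = cfg$sojourn_mode)
    stage <- "prevalence"
    report$prevalence <- prevalence_series(cov_fit, d, grid,
                                           mode = cfg$prevalence_mode)
    stage <- "survival"
    report$survival <- lapply(transient_states(structure), function(s)
      survival_curve(cov_fit, s, z = NULL, grid = grid))
    names(report$survival) <- c("good", "poor",
                                "death")[transient_states(structure)]
    report
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result$provenance <- list(
    config = cfg[setdiff(names(cfg), c("schema", "synthetic"))],
    config_hash = cheap_hash(cfg),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("strokemsm")),
    r_version = R.version.string)
  out <- base::structure(result, class = "study_report")
  if (!is.null(out_dir)) write_study_report(out, out_dir)
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n============\n")
  cat(sprintf("AIC: null %.2f, covariate %.2f; LRT stat %.2f (df %d), p = %.4g\n",
              x$aic["null"], x$aic["covariate"], x$lrt$statistic, x$lrt$df,
              x$lrt$p_value))
  cat("\nHazard ratios (2 dp):\n")
  tab <- x$hr_table
  tab$hr <- round(tab$hr, 2); tab$lower <- round(tab$lower, 2)
  tab$upper <- round(tab$upper, 2)
  print(tab[, c("transition", "covariate", "hr", "lower", "upper")],
        row.names = FALSE)
  cat("\nMean sojourn times (whole months):\n")
  st <- x$sojourn_table
  for (cl in setdiff(names(st), c("covariate", "level")))
    st[[cl]] <- round(st[[cl]])
  print(st, row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `report.json` (full precision) plus CSV tables (occupancy,
#' transition counts, hazard ratios, sojourn times, prevalence series,
#' survival curves) into `out_dir`.
#'
#' @param report a `study_report`.
#' @param out_dir output directory (created if needed).
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(report$descriptives$occupancy, p("occupancy.csv"))
  utils::write.csv(report$descriptives$transitions$counts,
                   p("transition_counts.csv"))
  utils::write.csv(report$hr_table, p("hr_table.csv"), row.names = FALSE)
  utils::write.csv(report$sojourn_table, p("sojourn_table.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$prevalence), p("prevalence.csv"),
                   row.names = FALSE)
  for (nm in names(report$survival))
    utils::write.csv(report$survival[[nm]],
                     p(sprintf("survival_from_%s.csv", nm)),
                     row.names = FALSE)
  obj <- list(
    aic = as.list(report$aic),
    lrt = report$lrt,
    null_fit = jsonlite::fromJSON(fitted_to_json(report$null_fit)),
    covariate_fit = jsonlite::fromJSON(fitted_to_json(report$covariate_fit)),
    hr_table = report$hr_table,
    sojourn_table = report$sojourn_table,
    prevalence = as.data.frame(report$prevalence),
    provenance = report$provenance)
  jsonlite::write_json(obj, p("report.json"), digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}
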