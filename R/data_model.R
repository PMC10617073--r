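#' Map a modified Rankin Scale score to the three-state outcome space
#'
#' Collapses the 7-level MRS disability scale to the model's state space:
#' MRS 0-2 (no to slight disability) is the good outcome (state 1), MRS 3-5
#' (moderate to severe disability) the poor outcome (state 2), and MRS 6
#' death (state 3).
#'
#' @param mrs integer vector of MRS scores, each in 0..6.
#' @return Integer vector of states in \{1, 2, 3\}.
#' @examples
#' state_from_mrs(c(0, 2, 3, 5, 6))
#' @export
state_from_mrs <- function(mrs) {
  bad <- which(!is.finite(mrs) | mrs < 0 | mrs > 6 | mrs != round(mrs))
  if (length(bad))
    stop("MRS score(s) outside 0..6 at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": ", paste(utils::head(mrs[bad], 5), collapse = ", "))
  ifelse(mrs < 3, 1L, ifelse(mrs < 6, 2L, 3L))
}

#' Construct and validate a panel dataset
#'
#' Builds the long-format panel object the likelihood works on: one row per
#' subject per visit, with an integer state, a visit time in months, and
#' baseline (time-constant) covariate columns. Validation enforces strictly
#' increasing times within subject, states in 1..3, no exit from the
#' absorbing death state, and a minimum number of visits per subject
#' (default 3, the usual inclusion criterion for panel follow-up; subjects
#' below the minimum are dropped and reported). Subjects with a single visit
#' carry no likelihood information and are always dropped.
#'
#' @param df data frame with columns `subject`, `time`, and `state` (or
#'   `mrs`, mapped via [state_from_mrs()]), plus covariate columns.
#' @param covariates character vector of covariate column names (numeric,
#'   baseline-fixed; 3-level factors must already be indicator-coded).
#' @param min_visits minimum visits per retained subject (>= 2).
#' @param coerce if `TRUE`, rows violating monotone time are re-sorted,
#'   duplicate times and post-death inconsistencies drop the subject with a
#'   diagnostic instead of failing.
#' @return An object of class `panel_data`: list with `data` (validated
#'   data frame), `covariates`, and `dropped` (subject, reason).
#' @export
panel_data <- function(df, covariates = character(), min_visits = 3L,
                       coerce = FALSE) {
  df <- as.data.frame(df)
  need <- c("subject", "time")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"state" %in% names(df)) {
    if (!"mrs" %in% names(df)) stop("need a 'state' or 'mrs' column")
    keep <- !is.na(df$mrs)
    df <- df[keep, , drop = FALSE]  # missing MRS: visit omitted, gap widens
    df$state <- state_from_mrs(df$mrs)
  }
  miss_cov <- setdiff(covariates, names(df))
  if (length(miss_cov))
    stop("missing covariate column(s): ", paste(miss_cov, collapse = ", "))
  if (any(!is.finite(df$time)) || any(df$time < 0))
    stop("visit times must be non-negative finite months")
  if (any(!df$state %in% 1:3))
    stop("states must be in 1..3; offending rows: ",
         paste(utils::head(which(!df$state %in% 1:3), 5), collapse = ", "))
  df$state <- as.integer(df$state)

  df <- df[order(match(df$subject, unique(df$subject)), df$time), ,
           drop = FALSE]
  rownames(df) <- NULL

  dropped <- data.frame(subject = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop_subject <- function(id, reason) {
    dropped[nrow(dropped) + 1L, ] <<- list(as.character(id), reason)
  }
  keep_rows <- rep(TRUE, nrow(df))
  rows_by_subject <- split(seq_len(nrow(df)),
                           factor(df$subject, levels = unique(df$subject)))
  for (id in names(rows_by_subject)) {
    rows <- rows_by_subject[[id]]
    tt <- df$time[rows]
    st <- df$state[rows]
    if (anyDuplicated(tt)) {
      if (!coerce) stop("duplicate visit times for subject ", id)
      drop_subject(id, "duplicate visit times")
      keep_rows[rows] <- FALSE
      next
    }
    after_death <- which(cummax(st == 3L) == 1L & st != 3L)
    if (length(after_death)) {
      if (!coerce) stop("transition out of absorbing state for subject ", id)
      drop_subject(id, "transition out of absorbing state")
      keep_rows[rows] <- FALSE
      next
    }
    for (cv in covariates) {
      v <- df[[cv]][rows]
      if (length(unique(v)) > 1L) {
        if (!coerce) stop("covariate '", cv, "' varies over time for subject ",
                          id, " (baseline covariates must be constant)")
        drop_subject(id, paste0("time-varying covariate ", cv))
        keep_rows[rows] <- FALSE
        break
      }
    }
    if (!all(keep_rows[rows])) next
    n_vis <- length(rows)
    if (n_vis < max(2L, min_visits)) {
      drop_subject(id, sprintf("fewer than %d visits (%d)",
                               max(2L, min_visits), n_vis))
      keep_rows[rows] <- FALSE
    }
  }
  df <- df[keep_rows, , drop = FALSE]
  rownames(df) <- NULL
  base::structure(
    list(data = df, covariates = as.character(covariates), dropped = dropped,
         min_visits = as.integer(min_visits)),
    class = "panel_data"
  )
}

#' @export
print.panel_data <- function(x, ...) {
  ns <- length(unique(x$data$subject))
  cat("Panel dataset:", ns, "subjects,", nrow(x$data), "observations\n")
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (nrow(x$dropped))
    cat("  dropped", nrow(x$dropped), "subject(s); see $dropped\n")
  invisible(x)
}

#' Number of subjects in a panel dataset
#' @param d a `panel_data`.
#' @export
n_subjects <- function(d) length(unique(d$data$subject))

#' Read a panel dataset from delimited text
#'
#' Reads a long-format CSV/TSV of visit records and validates it via
#' [panel_data()]. Column names are mapped through a schema, given either as
#' a named list or as a path to a YAML/JSON file with entries `subject`,
#' `time`, one of `state`/`mrs`, and optionally `covariates` (vector of
#' column names).
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, otherwise
#'   comma-separated.
#' @param schema named list or YAML/JSON file path; `NULL` uses the column
#'   names as-is with no covariates.
#' @param min_visits,coerce passed to [panel_data()].
#' @return A validated `panel_data`.
#' @export
read_panel <- function(path, schema = NULL, min_visits = 3L, coerce = FALSE) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (is.character(schema) && length(schema) == 1L) {
    schema <- if (grepl("\\.json$", schema)) jsonlite::fromJSON(schema)
              else yaml::read_yaml(schema)
  }
  covs <- character()
  if (!is.null(schema)) {
    for (field in c("subject", "time", "state", "mrs")) {
      src <- schema[[field]]
      if (!is.null(src)) {
        if (!src %in% names(df)) stop("schema column not in file: ", src)
        names(df)[names(df) == src] <- field
      }
    }
    covs <- as.character(schema$covariates %||% character())
  } else {
    covs <- setdiff(names(df), c("subject", "time", "state", "mrs", "exact"))
  }
  panel_data(df, covariates = covs, min_visits = min_visits, coerce = coerce)
}

#' Write a panel dataset as CSV
#' @param d a `panel_data`.
#' @param path output file path.
#' @export
write_panel <- function(d, path) {
  utils::write.csv(d$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Transition count matrix of consecutive visit pairs
#'
#' Tabulates every consecutive pair of observed states within subject into a
#' from-by-to count matrix, with row-normalised proportions — the empirical
#' per-interval transition table. Rows with zero total have all-zero
#' proportions by convention.
#'
#' @param d a `panel_data`.
#' @return Object of class `transition_counts`: list with integer matrix
#'   `counts` and numeric matrix `proportions`, both 3x3 with rows = origin
#'   state.
#' @export
transition_count_matrix <- function(d) {
  df <- d$data
  same <- df$subject[-1] == df$subject[-nrow(df)]
  from <- df$state[-nrow(df)][same]
  to <- df$state[-1][same]
  counts <- matrix(0L, 3, 3,
                   dimnames = list(from = c("good", "poor", "death"),
                                   to = c("good", "poor", "death")))
  tab <- table(factor(from, 1:3), factor(to, 1:3))
  counts[] <- as.integer(tab)
  rs <- rowSums(counts)
  proportions <- counts / ifelse(rs == 0, 1, rs)
  base::structure(list(counts = counts, proportions = proportions),
                  class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, digits = 3, ...) {
  cat("Observed transitions between consecutive visits\n")
  m <- matrix(sprintf("%d (%.*f)", x$counts, digits, x$proportions),
              3, 3, dimnames = dimnames(x$counts))
  print(m, quote = FALSE)
  invisible(x)
}

#' State occupancy at scheduled visit times
#'
#' Counts the subjects observed in each state at each grid time (no
#' carrying-forward: a subject not observed exactly at a grid time is not
#' counted there; the last-observation-carried-forward view lives in
#' [observed_prevalence()]).
#'
#' @param d a `panel_data`.
#' @param grid visit times in months; defaults to all distinct observed
#'   times.
#' @return Data frame with `time`, one count column per state, and `n`
#'   (row total); a final `"Total"` row sums each state column over the grid.
#' @export
occupancy_table <- function(d, grid = sort(unique(d$data$time))) {
  df <- d$data
  rows <- lapply(grid, function(tt) {
    st <- df$state[df$time == tt]
    tab <- tabulate(st, 3L)
    data.frame(time = tt, good = tab[1], poor = tab[2], death = tab[3],
               n = length(st))
  })
  out <- do.call(rbind, rows)
  total <- data.frame(time = NA, good = sum(out$good), poor = sum(out$poor),
                      death = sum(out$death), n = sum(out$n))
  rownames(total) <- "Total"
  rbind(out, total)
}
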