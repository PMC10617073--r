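#' Covariate-dependent transition intensity model
#'
#' Holds the baseline log-intensities and covariate coefficients of a
#' proportional-intensity model: for an allowed transition i->j and a
#' baseline covariate vector z, the intensity is
#' \deqn{q_{ij}(z) = q_{ij}(0) \exp(\beta_{ij}' z)}
#' so each `exp(beta)` is a hazard ratio on that transition. Intensities are
#' per month.
#'
#' Three constraint modes are supported. `"unrestricted"` gives every allowed
#' transition its own coefficient vector (the default; covariate effects are
#' typically reported per transition). `"progressive_regressive"` shares one
#' coefficient vector across all forward transitions (to a higher-numbered
#' state) and one across all backward transitions. `"symmetric"` further
#' restricts the backward coefficients to the negated forward ones.
#'
#' @param structure a [transition_structure()].
#' @param log_q0 numeric vector of log baseline intensities, one per allowed
#'   pair, in the row order of `structure$allowed` (units log(1/month)).
#' @param beta numeric matrix of covariate coefficients, rows = allowed pairs,
#'   columns = covariate components; may have zero columns. In the restricted
#'   modes the stored matrix is the expanded per-pair form.
#' @param covariates character vector naming the covariate components
#'   (columns of `beta`).
#' @param constraint_mode one of `"unrestricted"`, `"progressive_regressive"`,
#'   `"symmetric"`.
#' @return An object of class `intensity_model`.
#' @examples
#' s <- transition_structure()
#' m <- intensity_model(s, log_q0 = log(c(0.10, 0.001, 0.24, 0.09)))
#' build_Q(m)
#' @export
intensity_model <- function(structure = transition_structure(),
                            log_q0,
                            beta = NULL,
                            covariates = character(),
                            constraint_mode = c("unrestricted",
                                                "progressive_regressive",
                                                "symmetric")) {
  constraint_mode <- match.arg(constraint_mode)
  n_pairs <- nrow(structure$allowed)
  log_q0 <- as.numeric(log_q0)
  if (length(log_q0) != n_pairs)
    stop("log_q0 must have one entry per allowed pair (", n_pairs, ")")
  names(log_q0) <- pair_labels(structure)
  if (is.null(beta)) {
    beta <- matrix(0, n_pairs, length(covariates))
  }
  beta <- as.matrix(beta)
  if (nrow(beta) != n_pairs || ncol(beta) != length(covariates))
    stop("beta must be ", n_pairs, " x ", length(covariates))
  dimnames(beta) <- list(pair_labels(structure), covariates)
  if (constraint_mode != "unrestricted" && ncol(beta) > 0) {
    prog <- structure$allowed[, "to"] > structure$allowed[, "from"]
    b_p <- beta[which(prog)[1], , drop = TRUE]
    for (r in which(prog)) beta[r, ] <- b_p
    if (any(!prog)) {
      b_r <- if (constraint_mode == "symmetric") -b_p
             else beta[which(!prog)[1], , drop = TRUE]
      for (r in which(!prog)) beta[r, ] <- b_r
    }
  }
  base::structure(
    list(structure = structure, log_q0 = log_q0, beta = beta,
         covariates = as.character(covariates),
         constraint_mode = constraint_mode),
    class = "intensity_model"
  )
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("Intensity model (", x$constraint_mode, "), intensities per month\n",
      sep = "")
  tab <- data.frame(transition = pair_labels(x$structure),
                    q0 = exp(x$log_q0))
  if (ncol(x$beta) > 0) tab <- cbind(tab, HR = exp(x$beta))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Build the generator matrix for a covariate profile
#'
#' Evaluates the intensity model at a covariate vector, producing the
#' generator (Q) matrix: off-diagonal entries are the transition intensities,
#' each row sums to zero, and absorbing rows are identically zero.
#'
#' @param m an [intensity_model()].
#' @param z numeric covariate vector matching `m$covariates` (or `NULL` /
#'   length 0 for a model without covariates). A named vector is matched by
#'   name.
#' @return A `n_states x n_states` numeric matrix, units 1/month.
#' @examples
#' m <- intensity_model(transition_structure(),
#'                      log_q0 = log(c(0.10, 0.001, 0.24, 0.09)),
#'                      beta = matrix(c(log(2.34), 0, 0, 0), 4, 1),
#'                      covariates = "hypertension")
#' build_Q(m, z = c(hypertension = 1))["1", "2"]  # 0.234
#' @export
build_Q <- function(m, z = NULL) {
  p <- length(m$covariates)
  if (p == 0L) {
    eta <- m$log_q0
  } else {
    if (is.null(z)) z <- numeric(p)
    if (!is.null(names(z)) && all(m$covariates %in% names(z)))
      z <- z[m$covariates]
    z <- as.numeric(z)
    if (length(z) != p)
      stop("covariate vector has length ", length(z), ", expected ", p)
    eta <- m$log_q0 + as.numeric(m$beta %*% z)
  }
  n <- m$structure$n_states
  Q <- matrix(0, n, n, dimnames = list(seq_len(n), seq_len(n)))
  Q[m$structure$allowed] <- exp(eta)
  diag(Q) <- -rowSums(Q)
  Q
}

#' Hazard ratio for a covariate effect on one transition
#'
#' Returns `exp(beta)` for the requested (transition, covariate) cell, with a
#' 95% Wald interval when a standard error for the coefficient is supplied
#' (or available from a fitted model; see [fit_panel_msm()]).
#'
#' @param m an [intensity_model()] or a `fitted_msm`.
#' @param pair length-2 integer vector `c(from, to)` naming an allowed pair.
#' @param component covariate name or column index.
#' @param se optional standard error of the coefficient on the log scale;
#'   taken from the fitted covariance when `m` is a fitted model.
#' @param conf_level confidence level for the Wald interval.
#' @return A list with `hr`, `beta`, and (when an SE is available) `se`,
#'   `lower`, `upper`.
#' @export
hazard_ratio <- function(m, pair, component, se = NULL, conf_level = 0.95) {
  if (inherits(m, "fitted_msm")) {
    f <- m
    m <- f$model
    if (is.null(se)) {
      idx <- beta_param_index(m, pair, component)
      if (!is.null(f$covariance) && !is.null(idx) &&
          idx <= nrow(f$covariance)) {
        v <- f$covariance[idx, idx]
        if (is.finite(v) && v >= 0) se <- sqrt(v)
      }
    }
  }
  lab <- sprintf("%d->%d", pair[1], pair[2])
  row <- match(lab, pair_labels(m$structure))
  if (is.na(row)) stop("transition ", lab, " is not an allowed pair")
  if (is.character(component)) {
    col <- match(component, m$covariates)
    if (is.na(col)) stop("unknown covariate component: ", component)
  } else col <- as.integer(component)
  b <- m$beta[row, col]
  out <- list(transition = lab, component = m$covariates[col],
              beta = b, hr = exp(b))
  if (!is.null(se)) {
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    out$se <- se
    out$lower <- exp(b - zq * se)
    out$upper <- exp(b + zq * se)
  }
  out
}

# index of a beta cell in the packed parameter vector c(log_q0, vec(beta))
beta_param_index <- function(m, pair, component) {
  lab <- sprintf("%d->%d", pair[1], pair[2])
  row <- match(lab, pair_labels(m$structure))
  col <- if (is.character(component)) match(component, m$covariates)
         else as.integer(component)
  if (is.na(row) || is.na(col)) return(NULL)
  length(m$log_q0) + (col - 1L) * nrow(m$beta) + row
}

#' Serialize an intensity model to JSON
#'
#' Writes (or returns) a JSON representation carrying the transition
#' structure, baseline log-intensities, coefficients and constraint mode, so
#' a fitted or fixture model can be reloaded reproducibly with
#' [intensity_model_from_json()].
#'
#' @param m an [intensity_model()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
intensity_model_to_json <- function(m, path = NULL) {
  obj <- list(
    n_states = m$structure$n_states,
    allowed = m$structure$allowed,
    absorbing = m$structure$absorbing,
    log_q0 = unname(m$log_q0),
    beta = unname(m$beta),
    covariates = m$covariates,
    constraint_mode = m$constraint_mode
  )
  if (is.null(path))
    return(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname intensity_model_to_json
#' @param json a JSON string or file path produced by
#'   [intensity_model_to_json()].
#' @export
intensity_model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  s <- transition_structure(obj$n_states, as.matrix(obj$allowed),
                            obj$absorbing)
  intensity_model(s, log_q0 = obj$log_q0,
                  beta = matrix(unlist(obj$beta), nrow(s$allowed),
                                length(obj$covariates)),
                  covariates = obj$covariates,
                  constraint_mode = obj$constraint_mode)
}
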