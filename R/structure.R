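#' Transition structure of a multistate model
#'
#' Declares which instantaneous transitions are allowed and which states are
#' absorbing. The default is the three-state illness-death structure with
#' recovery used for stroke functional outcomes: state 1 = good outcome,
#' state 2 = poor outcome, state 3 = death, with transitions
#' 1->2, 1->3, 2->1, 2->3 and death absorbing.
#'
#' @param n_states number of states.
#' @param allowed two-column integer matrix of allowed (from, to) pairs,
#'   `from != to`. Order of rows fixes the parameter order everywhere else.
#' @param absorbing integer vector of absorbing states (no outgoing pairs).
#' @return An object of class `transition_structure`.
#' @examples
#' transition_structure()  # the default stroke structure
#' @export
transition_structure <- function(n_states = 3L,
                                 allowed = cbind(from = c(1L, 1L, 2L, 2L),
                                                 to   = c(2L, 3L, 1L, 3L)),
                                 absorbing = 3L) {
  allowed <- matrix(as.integer(allowed), ncol = 2,
                    dimnames = list(NULL, c("from", "to")))
  n_states <- as.integer(n_states)
  if (any(allowed < 1L) || any(allowed > n_states))
    stop("allowed pairs must reference states 1..", n_states)
  if (any(allowed[, 1] == allowed[, 2]))
    stop("allowed pairs must have from != to")
  absorbing <- as.integer(absorbing)
  if (any(allowed[, 1] %in% absorbing))
    stop("absorbing states cannot have outgoing transitions: state ",
         paste(intersect(allowed[, 1], absorbing), collapse = ", "))
  if (anyDuplicated(allowed))
    stop("duplicated (from,to) pair in allowed")
  structure(
    list(n_states = n_states, allowed = allowed, absorbing = absorbing),
    class = "transition_structure"
  )
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Transition structure:", x$n_states, "states;",
      nrow(x$allowed), "allowed transitions\n")
  cat("  allowed:",
      paste(sprintf("%d->%d", x$allowed[, 1], x$allowed[, 2]), collapse = ", "),
      "\n")
  cat("  absorbing:", paste(x$absorbing, collapse = ", "), "\n")
  invisible(x)
}

pair_labels <- function(structure) {
  sprintf("%d->%d", structure$allowed[, 1], structure$allowed[, 2])
}

transient_states <- function(structure) {
  setdiff(seq_len(structure$n_states), structure$absorbing)
}
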