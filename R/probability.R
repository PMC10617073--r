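## Matrix exponential by scaling-and-squaring with a degree-13 Pade
## approximant (Higham 2005) — the standard algorithm, implemented directly
## because it sits in the innermost likelihood loop where the generic
## S4 path is needlessly slow for 3x3 generators. Eigendecomposition is
## avoided: generators with repeated eigenvalues can be defective.
expm_pade <- function(A) {
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  n1 <- max(colSums(abs(A)))  # 1-norm
  theta13 <- 5.371920351148152
  s <- if (n1 > theta13) ceiling(log2(n1 / theta13)) else 0
  if (s > 0) A <- A / 2^s
  I <- diag(nrow(A))
  A2 <- A %*% A
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
                b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  P <- solve(V - U, V + U)
  for (k in seq_len(s)) P <- P %*% P
  P
}

#' Transition probability matrix over an interval
#'
#' Solves the Kolmogorov forward equations dP/dt = P Q for a time-homogeneous
#' generator by the matrix exponential, P(t) = exp(Q t), computed by
#' scaling-and-squaring with a degree-13 Pade approximant.
#' Rows of the result sum to one; tiny negative entries from floating point
#' are clipped to zero and rows of absorbing states are set exactly.
#'
#' @param Q generator matrix (off-diagonals >= 0, zero row sums), units
#'   1/month.
#' @param dt interval length in months, `dt >= 0`.
#' @return A stochastic matrix of the same dimension as `Q`.
#' @examples
#' Q <- build_Q(intensity_model(log_q0 = log(c(0.10, 0.001, 0.24, 0.09))))
#' transition_probability(Q, 3)
#' @export
transition_probability <- function(Q, dt) {
  if (length(dt) != 1 || !is.finite(dt) || dt < 0)
    stop("dt must be a single non-negative number of months")
  n <- nrow(Q)
  if (dt == 0) {
    P <- diag(n)
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- expm_pade(Q * dt)
  P[P < 0] <- 0
  P[P > 1] <- 1
  absorbing <- which(rowSums(abs(Q)) == 0)
  for (a in absorbing) {
    P[a, ] <- 0
    P[a, a] <- 1
  }
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Mean sojourn times of the transient states
#'
#' The expected length of a single stay in transient state i is -1/q_ii,
#' the mean of the exponential holding time implied by the generator.
#'
#' @param Q generator matrix, units 1/month.
#' @return Named numeric vector of mean sojourn times in months, one per
#'   transient state (states with an all-zero row are absorbing and omitted).
#'   A transient state with `q_ii == 0` is reported as `Inf` with a warning.
#' @examples
#' Q <- build_Q(intensity_model(log_q0 = log(c(0.10, 0.001, 0.24, 0.09))))
#' mean_sojourn_times(Q)  # about 9.9 and 3.0 months
#' @export
mean_sojourn_times <- function(Q) {
  transient <- which(rowSums(abs(Q)) > 0)
  zero_rate <- transient[diag(Q)[transient] == 0]
  if (length(zero_rate))
    warning("transient state(s) with zero exit rate: sojourn time infinite")
  out <- -1 / diag(Q)[transient]
  names(out) <- rownames(Q)[transient] %||% as.character(transient)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
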