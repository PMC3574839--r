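#' Scaled AR(1) covariance matrix
#'
#' Constructs the m x m matrix `A(rho)` with entries
#' `rho^|i-j| / (1 - rho^2)`, the covariance (up to the innovation variance
#' `theta^2`) of a stationary first-order autoregressive process observed at
#' `m` consecutive, equally spaced time points. The scaling by
#' `1/(1 - rho^2)` makes `theta^2 * A(rho)` the stationary covariance of an
#' AR(1) process with innovation variance `theta^2`.
#'
#' @param rho Autocorrelation, strictly inside (-1, 1).
#' @param m Number of time points (integer, at least 2).
#' @return A symmetric positive-definite `m x m` matrix.
#' @seealso [ar1_inverse()], [ar1_logdet()], [ar1_score_identity()]
#' @examples
#' ar1_matrix(0.5, 3)
#' @export
ar1_matrix <- function(rho, m) {
  check_rho(rho)
  check_m(m)
  idx <- seq_len(m)
  outer(idx, idx, function(i, j) rho^abs(i - j)) / (1 - rho^2)
}

#' Analytic inverse of the scaled AR(1) matrix
#'
#' The precision matrix of the stationary AR(1) process is tridiagonal:
#' `A(rho)^{-1} = (1 + rho^2) I - rho J - rho^2 K`, where `J` has ones on the
#' first sub- and super-diagonals and `K` is 1 at the (1,1) and (m,m)
#' positions. The symmetric form of `J` (both off-diagonals) is required for
#' the inverse of a symmetric matrix to be symmetric; it agrees with the
#' dense inverse of [ar1_matrix()] to machine precision.
#'
#' @inheritParams ar1_matrix
#' @return A symmetric tridiagonal `m x m` matrix equal to `solve(ar1_matrix(rho, m))`.
#' @export
ar1_inverse <- function(rho, m) {
  check_rho(rho)
  check_m(m)
  out <- diag(1 + rho^2, m)
  sub <- cbind(2:m, 1:(m - 1))
  out[sub] <- -rho
  out[sub[, 2:1, drop = FALSE]] <- -rho
  out[1, 1] <- out[m, m] <- 1
  out
}

#' Log-determinant of the scaled AR(1) matrix
#'
#' Under the `1/(1 - rho^2)` scaling the determinant of `A(rho)` is
#' `1/(1 - rho^2)` for every `m`, so the log-determinant is
#' `-log(1 - rho^2)`, independent of the number of time points. This closed
#' form is what makes the profile update of the autocorrelation cheap.
#'
#' @inheritParams ar1_matrix
#' @param m Number of time points; accepted for interface symmetry, the
#'   result does not depend on it.
#' @return `-log(1 - rho^2)` as a scalar.
#' @export
ar1_logdet <- function(rho, m = NULL) {
  check_rho(rho)
  -log(1 - rho^2)
}

#' Score identity for the AR(1) autocorrelation
#'
#' Returns `trace( d A(rho)^{-1} / d rho %*% A(rho) ) = -2 rho / (1 - rho^2)`,
#' the term entering the score equation for the autocorrelation parameter.
#'
#' @inheritParams ar1_logdet
#' @return A scalar.
#' @export
ar1_score_identity <- function(rho, m = NULL) {
  check_rho(rho)
  -2 * rho / (1 - rho^2)
}

# Admissible range for rho in optimizations; kept strictly inside (-1, 1)
# to avoid the boundary singularity of A(rho).
RHO_BOUND <- 1 - 1e-6

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1) {
    stop("`rho` must be a single finite value strictly inside (-1, 1), got ",
         deparse(rho), call. = FALSE)
  }
  invisible(rho)
}

check_m <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 2 || m != round(m)) {
    stop("`m` must be a single integer >= 2, got ", deparse(m), call. = FALSE)
  }
  invisible(as.integer(m))
}
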