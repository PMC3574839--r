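#' Fourier design matrix for periodic mean profiles
#'
#' Builds the fixed-effects design matrix of a k-th order Fourier expansion
#' of the mean profile: the row for time `t` is
#' `c(1, cos(2*pi*t/omega), sin(2*pi*t/omega), ..., cos(2*pi*k*t/omega),
#' sin(2*pi*k*t/omega))`, so a coefficient vector is ordered
#' `(a0, a1, b1, ..., ak, bk)`: intercept, then cosine/sine amplitude pairs.
#' First order (`order_k = 1`) is the usual choice for cell-cycle
#' expression profiles.
#'
#' @param times Numeric vector of m time coordinates.
#' @param order_k Order of the expansion (positive integer).
#' @param period_omega Period of the signal, in the units of `times`
#'   (positive).
#' @return An `m x (2 * order_k + 1)` matrix.
#' @export
fourier_design <- function(times, order_k = 1L, period_omega) {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times)) {
    stop("`times` must be a numeric vector without missing values", call. = FALSE)
  }
  if (!is.numeric(order_k) || length(order_k) != 1L || order_k < 1 ||
      order_k != round(order_k)) {
    stop("`order_k` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(period_omega) || length(period_omega) != 1L ||
      !is.finite(period_omega) || period_omega <= 0) {
    stop("`period_omega` must be a positive number", call. = FALSE)
  }
  ang <- outer(times, seq_len(order_k)) * (2 * pi / period_omega)
  X <- matrix(1, nrow = length(times), ncol = 2L * order_k + 1L)
  X[, 2L * seq_len(order_k)] <- cos(ang)
  X[, 2L * seq_len(order_k) + 1L] <- sin(ang)
  colnames(X) <- c("a0", paste0(rep(c("a", "b"), order_k),
                                rep(seq_len(order_k), each = 2L)))
  X
}

#' Cubic B-spline design matrix for non-periodic mean profiles
#'
#' Full cubic B-spline basis (intercept absorbed) with interior knots at
#' equally spaced quantiles of `times`. The basis is a partition of unity:
#' every row sums to 1 and all entries lie in [0, 1]. This is the design
#' used in place of the Fourier expansion when profiles show no clear
#' periodicity.
#'
#' @param times Numeric vector of m time coordinates (more than `spline_df`
#'   distinct values).
#' @param spline_df Basis dimension (integer, at least 4 for a cubic basis).
#' @return An `m x spline_df` matrix.
#' @export
bspline_design <- function(times, spline_df) {
  if (!is.numeric(spline_df) || length(spline_df) != 1L || spline_df < 4 ||
      spline_df != round(spline_df)) {
    stop("`spline_df` must be an integer >= 4 for a cubic basis", call. = FALSE)
  }
  if (length(times) <= spline_df) {
    stop("need more time points than basis columns (m = ", length(times),
         ", spline_df = ", spline_df, ")", call. = FALSE)
  }
  X <- splines::bs(times, df = spline_df, degree = 3L, intercept = TRUE,
                   Boundary.knots = range(times))
  X <- unclass(X)
  attributes(X)[setdiff(names(attributes(X)), "dim")] <- NULL
  colnames(X) <- paste0("s", seq_len(ncol(X)))
  X
}

#' Design specification for a mixture model
#'
#' Bundles the design kind and its parameters. For a Fourier design each
#' component may carry its own period, so `periods` is recycled to one value
#' per component when the model is assembled.
#'
#' @param kind `"fourier"` or `"bspline"`.
#' @param times Numeric vector of time coordinates.
#' @param order_k Fourier order (ignored for B-splines).
#' @param periods Period(s), one per component or a single shared value
#'   (Fourier only).
#' @param spline_df Basis dimension (B-spline only).
#' @return An object of class `tc_design`.
#' @export
design_spec <- function(kind = c("fourier", "bspline"), times, order_k = 1L,
                        periods = NULL, spline_df = NULL) {
  kind <- match.arg(kind)
  if (kind == "fourier") {
    if (is.null(periods)) stop("a Fourier design needs `periods`", call. = FALSE)
    if (any(periods <= 0)) stop("periods must be positive", call. = FALSE)
  } else if (is.null(spline_df)) {
    stop("a B-spline design needs `spline_df`", call. = FALSE)
  }
  structure(list(kind = kind, times = as.numeric(times), order_k = as.integer(order_k),
                 periods = periods, spline_df = spline_df),
            class = "tc_design")
}

#' Design matrix of one mixture component
#'
#' @param design A [design_spec()] object.
#' @param component Component index (used to pick the period when the design
#'   is Fourier and periods differ by component).
#' @return The component's design matrix.
#' @export
design_matrix <- function(design, component = 1L) {
  stopifnot(inherits(design, "tc_design"))
  if (design$kind == "fourier") {
    omega <- design$periods[[min(component, length(design$periods))]]
    fourier_design(design$times, design$order_k, omega)
  } else {
    bspline_design(design$times, design$spline_df)
  }
}

n_design_cols <- function(design) {
  if (design$kind == "fourier") 2L * design$order_k + 1L else as.integer(design$spline_df)
}
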