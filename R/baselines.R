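# Comparison baselines: the AR(1)-residual mixture (component covariance
# theta2 * A(rho) only, no gene- or cluster-level variance components) and a
# plain k-means adapter.

# One EM iteration of the AR(1)-residual mixture: responsibilities from the
# current model, beta by generalized least squares with weight A(rho)^-1,
# then (theta2, rho) by the same profile scheme as the full model with the
# accumulated moment matrix replaced by the tau-weighted residual
# outer-product matrix.
kim_step <- function(model, data) {
  tau <- posterior_probs(model, data)
  Y <- data$values
  n <- nrow(Y)
  m <- ncol(Y)
  comps <- vector("list", model$g)
  for (h in seq_len(model$g)) {
    cp <- model$components[[h]]
    tau_h <- tau[, h]
    t_sum <- sum(tau_h)
    if (t_sum < 1e-8) {
      stop("component ", h, " has vanishing responsibility mass (sum tau = ",
           format(t_sum), ")", call. = FALSE)
    }
    X <- design_matrix(model$design, h)
    Ainv <- ar1_inverse(cp$rho, m)
    ybar <- drop(crossprod(Y, tau_h)) / t_sum
    XtAinv <- crossprod(X, Ainv)
    beta_hat <- solve(XtAinv %*% X, XtAinv %*% ybar)
    Rc <- t(Y) - drop(X %*% beta_hat)
    S <- Rc %*% (t(Rc) * tau_h)
    S <- (S + t(S)) / 2
    ar1 <- profile_ar1_update(S, t_sum)
    comps[[h]] <- new_component(
      weight_p = t_sum / n, beta = drop(beta_hat),
      theta2 = max(ar1$theta2, VAR_FLOOR), rho = ar1$rho,
      sigma2 = 0, d2 = 0,
      period_omega = cp$period_omega)
  }
  new_mixture_model(comps, model$design, variance_structure = "ar1-residual")
}

#' Fit the AR(1)-residual mixture baseline
#'
#' EM for a g-component multivariate-normal mixture with mean `X_h beta_h`
#' and covariance `theta2_h * A(rho_h)`: temporal dependence is carried
#' entirely by the residual autocorrelation, with no gene-specific or
#' cluster-shared variance components. Same convergence rule as
#' [fit_emmix_ar1()].
#'
#' @inheritParams fit_emmix_ar1
#' @param init As in [fit_emmix_ar1()]; use `init = "model"` with
#'   `init_model` to start from known parameter values.
#' @return A `tc_fit` object.
#' @export
fit_ar1_residual <- function(data, g, design,
                             init = c("kmeans", "true-partition",
                                      "random-starts", "model"),
                             labels = NULL, init_model = NULL, n_starts = 10L,
                             seed = NULL, tol = 1e-5, max_iter = 1000L) {
  init <- match.arg(init)
  model0 <- initialize_model(data, g, design, strategy = init, labels = labels,
                             init_model = init_model, n_starts = n_starts,
                             seed = seed, variance_structure = "ar1-residual",
                             tol = tol)
  if (model0$variance_structure != "ar1-residual") {
    stop("`init_model` must have variance_structure = \"ar1-residual\"",
         call. = FALSE)
  }
  run <- em_engine(model0, data, tol, max_iter, kim_step)
  finish_fit(run, data)
}

#' k-means baseline on the raw profiles
#'
#' Runs `stats::kmeans` with `n_starts` restarts on the gene-by-time matrix
#' and returns the hard labels. This is a reference method, not part of the
#' mixture-model machinery.
#'
#' @param data A [time_course_matrix()].
#' @param g Number of clusters.
#' @param seed Optional integer seed.
#' @param n_starts Number of k-means restarts (default 10).
#' @return Integer vector of cluster labels.
#' @export
fit_kmeans_profiles <- function(data, g, seed = NULL, n_starts = 10L) {
  stopifnot(inherits(data, "tc_matrix"))
  if (nrow(data$values) < g) stop("need at least g genes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stats::kmeans(data$values, centers = g, nstart = n_starts)$cluster
}
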