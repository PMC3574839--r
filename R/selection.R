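# Model selection: BIC over the number of components, and a global grid
# search over candidate periods (fit at every grid point, keep the fit with
# the highest working log-likelihood).

# Free-parameter count: (g - 1) mixing proportions, g * (design columns)
# regression coefficients, and per component the variance-structure
# parameters: 4 (theta2, rho, sigma2, d2) for the full model, 2 for the
# AR(1)-residual baseline. Fixed periods are not counted.
n_free_params <- function(model) {
  g <- model$g
  n_var <- if (model$variance_structure == "full") 4L else 2L
  (g - 1L) + g * n_design_cols(model$design) + g * n_var
}

model_bic_value <- function(loglik, model, n_genes) {
  -2 * loglik + n_free_params(model) * log(n_genes)
}

#' Bayesian Information Criterion of a fit
#'
#' `-2 logL + nu log(n_genes)` where `nu` counts the free parameters
#' (mixing proportions, regression coefficients, and the per-component
#' variance parameters: 4 for the full model, 2 for the AR(1)-residual
#' baseline). The sample size is the number of genes, since the mixture is
#' over genes. Lower is better.
#'
#' @param fit A `tc_fit` object.
#' @param n_genes Number of genes the model was fitted to.
#' @return A scalar.
#' @export
model_bic <- function(fit, n_genes) {
  stopifnot(inherits(fit, "tc_fit"))
  model_bic_value(fit$loglik, fit$model, n_genes)
}

#' BIC sweep over the number of components
#'
#' Fits the model for each candidate `g` and tabulates log-likelihood,
#' parameter count and BIC.
#'
#' @param data A [time_course_matrix()].
#' @param g_values Candidate component counts.
#' @param design_builder Function of `g` returning the [design_spec()] to
#'   use (a constant design can be wrapped with `function(g) design`).
#' @param fitter [fit_emmix_ar1()] or [fit_ar1_residual()].
#' @param seed Base seed; candidate `g` uses `seed + g`.
#' @param ... Passed to the fitter.
#' @return List with `table` (data frame `g`, `loglik`, `n_params`, `bic`),
#'   `best_g` and `best_fit`.
#' @export
bic_sweep <- function(data, g_values, design_builder, fitter = fit_emmix_ar1,
                      seed = 1L, ...) {
  fits <- vector("list", length(g_values))
  rows <- vector("list", length(g_values))
  for (i in seq_along(g_values)) {
    g <- g_values[i]
    design <- design_builder(g)
    fit <- fitter(data, g = g, design = design, seed = replicate_seed(seed, g), ...)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(g = g, loglik = fit$loglik,
                            n_params = n_free_params(fit$model), bic = fit$bic)
  }
  tab <- do.call(rbind, rows)
  best <- which.min(tab$bic)
  list(table = tab, best_g = g_values[best], best_fit = fits[[best]])
}

#' Global grid search over component periods
#'
#' For every candidate period vector the model is fitted with the periods
#' held fixed; the fit with the highest working log-likelihood wins. With
#' `share_across_components = TRUE` (default) all components share one
#' period and the grid is swept directly; otherwise the full Cartesian
#' product over per-component periods is evaluated, which grows as
#' `length(grid)^g`.
#'
#' @param data A [time_course_matrix()].
#' @param g Number of components.
#' @param candidate_periods Vector of admissible periods.
#' @param share_across_components All components share one period (default
#'   `TRUE`).
#' @param order_k Fourier order.
#' @param fitter [fit_emmix_ar1()] or [fit_ar1_residual()].
#' @param seed Base seed; grid point i uses `seed + i`.
#' @param ... Passed to the fitter (initialization, tolerance, ...).
#' @return List with `best_fit`, `best_periods`, and `table` (one row per
#'   grid point with its log-likelihood and BIC).
#' @export
grid_search_periods <- function(data, g, candidate_periods,
                                share_across_components = TRUE, order_k = 1L,
                                fitter = fit_emmix_ar1, seed = 1L, ...) {
  if (length(candidate_periods) == 0L) {
    stop("`candidate_periods` must be non-empty", call. = FALSE)
  }
  if (any(candidate_periods <= 0)) {
    stop("candidate periods must be positive", call. = FALSE)
  }
  grid <- if (share_across_components) {
    matrix(candidate_periods, ncol = 1)[, rep(1, g), drop = FALSE]
  } else {
    as.matrix(do.call(expand.grid, rep(list(candidate_periods), g)))
  }
  best_fit <- NULL
  best_ll <- -Inf
  best_periods <- NULL
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    periods <- as.numeric(grid[i, ])
    design <- design_spec("fourier", data$times, order_k = order_k,
                          periods = periods)
    fit <- fitter(data, g = g, design = design, seed = replicate_seed(seed, i), ...)
    rows[[i]] <- data.frame(t(stats::setNames(periods, paste0("omega", seq_len(g)))),
                            loglik = fit$loglik, bic = fit$bic)
    if (fit$loglik > best_ll) {
      best_ll <- fit$loglik
      best_fit <- fit
      best_periods <- periods
    }
  }
  list(best_fit = best_fit, best_periods = best_periods,
       table = do.call(rbind, rows))
}
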