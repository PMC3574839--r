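# EM algorithm for the AR(1) random-effects mixture.
#
# The complete data augment the profiles with the component labels z, the
# gene-specific AR(1) effects u and the cluster-shared effects v. The
# complete-data log-likelihood splits into four blocks (labels; measurement
# error; u; v) that are maximized separately in the M-step. The E-step uses
# the conditional-Gaussian identities of the linear mixed model, proceeding
# conditionally on the estimated shared effect: with
# `S_uO = theta2 A(rho) + sigma2 I` and responsibilities tau,
#   v_hat_h  = (I/d2 + T_h S_uO^-1)^-1  S_uO^-1 sum_j tau_jh (y_j - X beta)
#   E[u_j|y] = theta2 A S_uO^-1 (y_j - X beta - v_hat)
# and the second moments carry both the conditional variance of u given v
# and the propagated uncertainty of v, so that for a single component the
# moments coincide with exact joint-Gaussian conditioning on the stacked
# (u_1..u_n, v) vector.

VAR_FLOOR <- 1e-10

# Validation-free internal constructors used inside the EM loop, where the
# parameters are produced by the updates themselves (the exported
# constructors re-validate on entry and exit of a fit).
new_component <- function(weight_p, beta, theta2, rho, sigma2, d2,
                          period_omega) {
  structure(list(weight_p = weight_p, beta = as.numeric(beta), theta2 = theta2,
                 rho = rho, sigma2 = sigma2, d2 = d2,
                 period_omega = period_omega),
            class = "tc_component")
}

new_mixture_model <- function(components, design, variance_structure) {
  structure(list(g = length(components), components = components,
                 design = design, variance_structure = variance_structure),
            class = "tc_model")
}

# ar1_matrix without argument checking, for the inner loop.
ar1_matrix_fast <- function(rho, m) {
  idx <- seq_len(m)
  rho^abs(outer(idx, idx, "-")) / (1 - rho^2)
}

# Membership log-densities conditional on the estimated shared effects:
# component h contributes log p_h + log phi(y_j; X beta_h + v_h, theta2 A + sigma2 I).
# Conditioning on v is what separates clusters whose realized shared effect
# has moved them away from their Fourier mean.
cond_component_logdens <- function(model, data, V) {
  Y <- data$values
  m <- ncol(Y)
  out <- matrix(NA_real_, nrow(Y), model$g)
  for (h in seq_len(model$g)) {
    cp <- model$components[[h]]
    X <- design_matrix(model$design, h)
    mu <- drop(X %*% cp$beta) + V[h, ]
    th2 <- cp$theta2
    s2 <- max(cp$sigma2, VAR_FLOOR)
    Sigma <- if (th2 > VAR_FLOOR) {
      th2 * ar1_matrix(cp$rho, m) + diag(s2, m)
    } else {
      diag(s2, m)
    }
    out[, h] <- log(cp$weight_p) + mvn_logdens_rows(Y, mu, Sigma)
  }
  out
}

# Working objective of the EM scheme: gene-wise mixture log-likelihood
# conditional on the estimated shared effects.
cond_loglik <- function(model, data, V) {
  sum(log_row_sum_exp(cond_component_logdens(model, data, V)))
}

#' E-step: responsibilities and conditional moments of the random effects
#'
#' Responsibilities are computed conditionally on the estimated
#' cluster-shared effects `v_prev` (mean `X beta_h + v_h`, covariance
#' `theta2 A(rho) + sigma2 I`); when `v_prev` is `NULL` (no estimate yet)
#' the marginal posteriors of [posterior_probs()] are used. The shared
#' effect is then re-estimated from the new responsibilities and the
#' conditional moments of the gene-specific effects follow.
#'
#' @param model A [mixture_model()] with `variance_structure = "full"`.
#' @param data A [time_course_matrix()].
#' @param v_prev Optional `g x m` matrix of shared-effect estimates from
#'   the previous iteration.
#' @param Xs,Yt Optional precomputed per-component design matrices and
#'   transposed data matrix; the fitting loop passes these to avoid
#'   rebuilding them every iteration.
#' @return An object of class `tc_estep`: list with `tau` (n x g) and
#'   `comps`, a per-component list holding `u_mean` (m x n), `u_var`
#'   (m x m, shared across genes), `S` (accumulated
#'   `sum_j tau_jh E[u u^T | y]`), `v_mean`, `v_var`, `mu` (mean profile
#'   used), `E` (m x n matrix of expected residuals
#'   `y - X beta - E[u] - v_hat`), `var_uv_tr` (trace of
#'   `Var[u + v | y]`, per gene) and `t_sum` (total responsibility);
#'   `objective` holds the summed log mixture densities the
#'   responsibilities were computed from.
#' @export
e_step <- function(model, data, v_prev = NULL, Xs = NULL, Yt = NULL) {
  check_model_data(model, data)
  Y <- data$values
  n <- nrow(Y)
  m <- ncol(Y)
  g <- model$g
  if (is.null(Yt)) Yt <- t(Y)

  # first pass: per-component algebra shared by the responsibilities and
  # the moment computations
  pre <- vector("list", g)
  lp <- matrix(NA_real_, n, g)
  cst <- m * log(2 * pi)
  for (h in seq_len(g)) {
    cp <- model$components[[h]]
    X <- if (is.null(Xs)) design_matrix(model$design, h) else Xs[[h]]
    mu <- drop(X %*% cp$beta)
    R0 <- Yt - mu                          # m x n residuals about the mean
    th2 <- cp$theta2
    s2 <- max(cp$sigma2, VAR_FLOOR)
    A <- if (th2 > VAR_FLOOR) ar1_matrix_fast(cp$rho, m) else NULL
    SuO <- if (is.null(A)) diag(s2, m) else th2 * A + diag(s2, m)
    L <- chol(SuO)                         # Cov(u + eps) factor
    SuO_inv <- chol2inv(L)
    B <- if (is.null(A)) matrix(0, m, m) else th2 * (A %*% SuO_inv)
    B <- (B + t(B)) / 2
    if (is.null(v_prev)) {
      # no shared-effect estimate yet: marginal membership densities
      Lm <- chol(SuO + diag(cp$d2, m))
      Z <- backsolve(Lm, R0, transpose = TRUE)
      lp[, h] <- log(cp$weight_p) -
        0.5 * (cst + 2 * sum(log(diag(Lm))) + colSums(Z^2))
    } else {
      Rp <- R0 - v_prev[h, ]
      lp[, h] <- log(cp$weight_p) -
        0.5 * (cst + 2 * sum(log(diag(L))) + colSums((SuO_inv %*% Rp) * Rp))
    }
    pre[[h]] <- list(cp = cp, X = X, mu = mu, R0 = R0, SuO_inv = SuO_inv,
                     B = B, s2 = s2)
  }
  lse <- log_row_sum_exp(lp)
  tau <- exp(lp - lse)

  # second pass: conditional moments of the random effects
  comps <- vector("list", g)
  for (h in seq_len(g)) {
    ph <- pre[[h]]
    tau_h <- tau[, h]
    t_sum <- sum(tau_h)
    if (t_sum < 1e-8) {
      stop("component ", h, " has vanishing responsibility mass (sum tau = ",
           format(t_sum), ")", call. = FALSE)
    }
    B <- ph$B
    if (ph$cp$d2 > VAR_FLOOR) {
      V_v <- chol2inv(chol(diag(1 / ph$cp$d2, m) + t_sum * ph$SuO_inv))
      v_hat <- drop(V_v %*% (ph$SuO_inv %*% (ph$R0 %*% tau_h)))
    } else {
      V_v <- matrix(0, m, m)
      v_hat <- numeric(m)
    }
    Rv <- ph$R0 - v_hat
    U <- B %*% Rv                          # E[u_j | y_j], one column per gene
    ImB <- diag(m) - B
    u_var <- ph$s2 * B + B %*% V_v %*% B   # Var[u_j | y], gene-independent
    u_var <- (u_var + t(u_var)) / 2
    S <- U %*% (t(U) * tau_h) + t_sum * u_var
    S <- (S + t(S)) / 2
    var_uv_tr <- ph$s2 * sum(diag(B)) + sum(diag(ImB %*% V_v %*% ImB))
    E <- Rv - U                            # expected measurement residual

    comps[[h]] <- list(u_mean = U, u_var = u_var, S = S,
                       v_mean = v_hat, v_var = V_v,
                       mu = ph$mu, X = ph$X, E = E,
                       var_uv_tr = var_uv_tr, t_sum = t_sum)
  }
  structure(list(tau = tau, comps = comps, n = n, m = m,
                 objective = sum(lse)),
            class = "tc_estep")
}

# Profile maximization of the expected u-block of the complete-data
# log-likelihood: for fixed rho the innovation variance has the closed form
# theta2(rho) = tr(A(rho)^-1 S) / (m T), with the trace expanded through the
# tridiagonal inverse; rho is then found by bounded 1-D maximization of
# -(m log theta2(rho) + logdet A(rho)).
profile_ar1_update <- function(S, t_sum) {
  m <- nrow(S)
  tr_S <- sum(diag(S))
  if (tr_S < 1e-300) {
    return(list(theta2 = 0, rho = 0))
  }
  off_S <- 2 * sum(S[cbind(1:(m - 1), 2:m)])
  cor_S <- S[1, 1] + S[m, m]
  tr_AinvS <- function(rho) (1 + rho^2) * tr_S - rho * off_S - rho^2 * cor_S
  obj <- function(rho) -(m * log(tr_AinvS(rho) / (m * t_sum)) + ar1_logdet(rho))
  opt <- stats::optimize(obj, interval = c(-RHO_BOUND, RHO_BOUND),
                         maximum = TRUE, tol = 1e-9)
  rho_hat <- opt$maximum
  list(theta2 = tr_AinvS(rho_hat) / (m * t_sum), rho = rho_hat)
}

#' M-step: closed-form parameter updates
#'
#' Updates the mixing proportions from the responsibilities, the regression
#' coefficients by least squares on the expectation-adjusted profiles, the
#' measurement-error variance from the expected residual sum of squares
#' (including the conditional-variance traces), the AR(1) pair
#' `(theta2, rho)` by the profile scheme of the u-block, and the
#' cluster-effect variance from `tr(E[v v^T | y]) / m`.
#'
#' @param state An [e_step()] result.
#' @param data The [time_course_matrix()] the state was computed from.
#' @param design The [design_spec()] of the model.
#' @param periods Optional per-component periods carried into the updated
#'   model (Fourier designs).
#' @return A [mixture_model()] with updated parameters.
#' @export
m_step <- function(state, data, design, periods = NULL) {
  stopifnot(inherits(state, "tc_estep"))
  n <- state$n
  m <- state$m
  g <- length(state$comps)
  comps <- vector("list", g)
  for (h in seq_len(g)) {
    st <- state$comps[[h]]
    tau_h <- state$tau[, h]
    t_sum <- st$t_sum
    X <- if (is.null(st$X)) design_matrix(design, h) else st$X

    p_hat <- t_sum / n
    ybar_adj <- st$mu + drop(st$E %*% tau_h) / t_sum
    beta_hat <- drop(solve(crossprod(X), crossprod(X, ybar_adj)))
    mu_new <- drop(X %*% beta_hat)

    E_new <- st$E + (st$mu - mu_new)
    resid_q <- sum(tau_h * colSums(E_new^2))
    sigma2_hat <- (resid_q + t_sum * st$var_uv_tr) / (m * t_sum)

    ar1 <- profile_ar1_update(st$S, t_sum)
    d2_hat <- (sum(st$v_mean^2) + sum(diag(st$v_var))) / m

    comps[[h]] <- new_component(
      weight_p = p_hat, beta = beta_hat,
      theta2 = max(ar1$theta2, 0), rho = ar1$rho,
      sigma2 = max(sigma2_hat, 0), d2 = max(d2_hat, 0),
      period_omega = if (design$kind == "fourier") {
        design$periods[[min(h, length(design$periods))]]
      } else NULL)
  }
  new_mixture_model(comps, design, variance_structure = "full")
}

# Flat parameter vector used by the convergence test (relative change of
# every estimate between consecutive iterations).
par_vec <- function(model) {
  unlist(lapply(model$components, function(cp) {
    base <- c(cp$weight_p, cp$beta, cp$theta2, cp$rho)
    if (model$variance_structure == "full") c(base, cp$sigma2, cp$d2) else base
  }))
}

rel_change <- function(new, old) {
  max(abs(new - old) / (abs(old) + 1e-12))
}

em_engine <- function(model, data, tol, max_iter,
                      step_fun, loglik_fun = mixture_loglik) {
  trace <- numeric(0)
  old_par <- par_vec(model)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    model <- step_fun(model, data)
    ll <- loglik_fun(model, data)
    if (!is.finite(ll)) {
      stop("non-finite objective at iteration ", iter, call. = FALSE)
    }
    trace <- c(trace, ll)
    new_par <- par_vec(model)
    if (rel_change(new_par, old_par) < tol) {
      converged <- TRUE
      break
    }
    old_par <- new_par
  }
  list(model = model, trace = trace, n_iter = iter, converged = converged)
}

# Assemble the FitResult. Membership (tau, labels) is conditional on the
# final shared-effect estimates when these exist; the reported loglik (and
# hence BIC) is the marginal mixture log-likelihood, while loglik_trace
# records the EM scheme's working objective.
finish_fit <- function(run, data, V = NULL) {
  if (is.null(V)) {
    tau <- posterior_probs(run$model, data)
  } else {
    lp <- cond_component_logdens(run$model, data, V)
    lse <- log_row_sum_exp(lp)
    tau <- exp(lp - lse)
    run$trace <- c(run$trace, sum(lse) + shared_effect_penalty(run$model, V))
  }
  labels <- map_labels(tau)
  ll <- mixture_loglik(run$model, data)
  structure(list(model = run$model, loglik = ll, loglik_trace = run$trace,
                 n_iter = run$n_iter, converged = run$converged,
                 tau = tau, labels = labels, v_hat = V,
                 bic = model_bic_value(ll, run$model, nrow(data$values))),
            class = "tc_fit")
}

# Log-density of the estimated shared effects under their N(0, d2 I)
# distribution; together with the conditional mixture log-likelihood this
# is the working objective the EM scheme ascends.
shared_effect_penalty <- function(model, V) {
  m <- ncol(V)
  sum(vapply(seq_len(model$g), function(h) {
    d2 <- model$components[[h]]$d2
    if (d2 <= VAR_FLOOR) return(0)
    -0.5 * (m * log(2 * pi * d2) + sum(V[h, ]^2) / d2)
  }, numeric(1)))
}

# Full-model EM run: the estimated shared effects persist across
# iterations; each E-step computes responsibilities conditional on them and
# then re-estimates them. The traced objective is the penalized conditional
# working log-likelihood F(parameters, v_hat) — the mixture log-likelihood
# given the shared effects plus their log-density — evaluated after each
# iteration (the e_step entering iteration t+1 supplies the conditional
# term for the state left by iteration t; finish_fit appends the final
# value).
full_em_run <- function(model, data, tol, max_iter) {
  Xs <- lapply(seq_len(model$g), function(h) design_matrix(model$design, h))
  Yt <- t(data$values)
  V <- NULL
  pen <- 0
  trace <- numeric(0)
  old_par <- par_vec(model)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    state <- e_step(model, data, v_prev = V, Xs = Xs, Yt = Yt)
    if (!is.finite(state$objective)) {
      stop("non-finite objective at iteration ", iter, call. = FALSE)
    }
    if (!is.null(V)) trace <- c(trace, state$objective + pen)
    V <- do.call(rbind, lapply(state$comps, `[[`, "v_mean"))
    model <- m_step(state, data, model$design)
    pen <- shared_effect_penalty(model, V)
    new_par <- par_vec(model)
    if (rel_change(new_par, old_par) < tol) {
      converged <- TRUE
      break
    }
    old_par <- new_par
  }
  list(model = model, trace = trace, n_iter = iter, converged = converged,
       V = V)
}

# Compiled fast path of full_em_run (identical scheme; see src/em_core.cpp).
# The reference R loop above is kept as the documented, oracle-tested
# implementation and the two are compared in the test suite.
full_em_run_compiled <- function(model, data, tol, max_iter) {
  g <- model$g
  Xs <- lapply(seq_len(g), function(h) design_matrix(model$design, h))
  res <- .em_ar1_core(
    t(data$values), Xs,
    weight = vapply(model$components, `[[`, numeric(1), "weight_p"),
    beta = vapply(model$components, `[[`, numeric(length(model$components[[1]]$beta)), "beta"),
    theta2 = vapply(model$components, `[[`, numeric(1), "theta2"),
    rho = vapply(model$components, `[[`, numeric(1), "rho"),
    sigma2 = vapply(model$components, `[[`, numeric(1), "sigma2"),
    d2 = vapply(model$components, `[[`, numeric(1), "d2"),
    tol = tol, max_iter = as.integer(max_iter))
  comps <- lapply(seq_len(g), function(h) {
    new_component(weight_p = res$weight[h], beta = res$beta[, h],
                  theta2 = res$theta2[h], rho = res$rho[h],
                  sigma2 = res$sigma2[h], d2 = res$d2[h],
                  period_omega = model$components[[h]]$period_omega)
  })
  list(model = new_mixture_model(comps, model$design, model$variance_structure),
       trace = as.numeric(res$trace), n_iter = res$n_iter,
       converged = res$converged, V = res$V)
}

#' @export
print.tc_fit <- function(x, ...) {
  cat("Fitted ", x$model$g, "-component ", x$model$variance_structure,
      " mixture\n", sep = "")
  cat(sprintf("  logLik %.4f  BIC %.4f  iterations %d (%s)\n",
              x$loglik, x$bic, x$n_iter,
              if (x$converged) "converged" else "max iterations reached"))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$model$g), collapse = ", "),
      "\n")
  invisible(x)
}

#' Fit the AR(1) random-effects mixture model by EM
#'
#' Alternates [e_step()] and [m_step()] from an initial model until the
#' largest relative change across all scalar parameters between consecutive
#' iterations drops below `tol`, or `max_iter` is reached. Membership
#' probabilities, and hence the MAP labels, are conditional on the final
#' shared-effect estimates (see [e_step()]); `loglik_trace` records the
#' EM scheme's working objective per iteration (the conditional mixture
#' log-likelihood given the shared effects plus the shared effects'
#' log-density, the quantity the scheme ascends), while the reported
#' `loglik` (used for `bic` and for model comparison) is the marginal
#' mixture log-likelihood of [mixture_loglik()] at the estimate.
#'
#' @param data A [time_course_matrix()].
#' @param g Number of components.
#' @param design A [design_spec()].
#' @param init Initialization strategy: `"kmeans"` (k-means on the profiles,
#'   then per-cluster estimation), `"true-partition"` (per-cluster
#'   estimation from `labels`), `"random-starts"` (best of `n_starts` short
#'   EM runs from random partitions), or `"model"` (start from
#'   `init_model`).
#' @param labels Hard labels for `init = "true-partition"`.
#' @param init_model Starting [mixture_model()] for `init = "model"`.
#' @param n_starts Number of starts for `"kmeans"` / `"random-starts"`.
#' @param seed Optional integer seed for the stochastic initializers.
#' @param tol Convergence tolerance on the relative parameter changes
#'   (default `1e-5`).
#' @param max_iter Iteration cap (default 1000).
#' @param engine `"compiled"` (default) runs the iteration loop in
#'   compiled code; `"reference"` runs the pure-R loop built from
#'   [e_step()] and [m_step()]. The two implement the identical scheme
#'   and are cross-checked in the test suite.
#' @return A `tc_fit` object: the fitted model, log-likelihood trace,
#'   iteration count and convergence flag, posterior matrix `tau`, MAP
#'   `labels`, and `bic`.
#' @export
fit_emmix_ar1 <- function(data, g, design,
                          init = c("kmeans", "true-partition", "random-starts", "model"),
                          labels = NULL, init_model = NULL, n_starts = 10L,
                          seed = NULL, tol = 1e-5, max_iter = 1000L,
                          engine = c("compiled", "reference")) {
  init <- match.arg(init)
  engine <- match.arg(engine)
  model0 <- initialize_model(data, g, design, strategy = init, labels = labels,
                             init_model = init_model, n_starts = n_starts,
                             seed = seed, variance_structure = "full",
                             tol = tol)
  runner <- if (engine == "compiled") full_em_run_compiled else full_em_run
  run <- runner(model0, data, tol, max_iter)
  finish_fit(run, data, V = run$V)
}

#' Initialize a mixture model
#'
#' `"true-partition"` estimates every component's parameters from the given
#' hard labels (regression coefficients by least squares on the cluster mean
#' profile; variance parameters by moment matching on the cluster
#' residuals). `"kmeans"` obtains the hard labels from a k-means run on the
#' profiles first. `"random-starts"` draws `n_starts` random partitions,
#' runs a short EM from each and keeps the start with the highest working
#' log-likelihood. `"model"` passes `init_model` through after validation.
#'
#' @inheritParams fit_emmix_ar1
#' @param strategy One of `"kmeans"`, `"true-partition"`, `"random-starts"`,
#'   `"model"`.
#' @param variance_structure `"full"` or `"ar1-residual"`.
#' @param tol Tolerance used by the short runs of `"random-starts"`.
#' @return A [mixture_model()].
#' @export
initialize_model <- function(data, g, design,
                             strategy = c("kmeans", "true-partition",
                                          "random-starts", "model"),
                             labels = NULL, init_model = NULL, n_starts = 10L,
                             seed = NULL,
                             variance_structure = c("full", "ar1-residual"),
                             tol = 1e-5) {
  strategy <- match.arg(strategy)
  variance_structure <- match.arg(variance_structure)
  stopifnot(inherits(data, "tc_matrix"))
  if (nrow(data$values) < g) stop("need at least g genes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  switch(strategy,
    "model" = {
      if (is.null(init_model)) stop("`init_model` is required", call. = FALSE)
      stopifnot(inherits(init_model, "tc_model"))
      init_model
    },
    "true-partition" = {
      if (is.null(labels)) {
        stop("`labels` is required for the true-partition initializer",
             call. = FALSE)
      }
      init_from_labels(data, g, design, labels, variance_structure)
    },
    "kmeans" = {
      km <- stats::kmeans(data$values, centers = g, nstart = n_starts)
      labels <- match_clusters_to_designs(data, g, design, km$cluster)
      init_from_labels(data, g, design, labels, variance_structure)
    },
    "random-starts" = {
      n <- nrow(data$values)
      best <- NULL
      best_ll <- -Inf
      runner <- if (variance_structure == "full") {
        function(model0) full_em_run_compiled(model0, data, tol, 10L)
      } else {
        function(model0) em_engine(model0, data, tol, 10L, kim_step)
      }
      for (s in seq_len(n_starts)) {
        lab <- sample.int(g, n, replace = TRUE)
        lab[sample.int(n, g)] <- seq_len(g)   # every cluster non-empty
        model0 <- init_from_labels(data, g, design, lab, variance_structure)
        run <- tryCatch(runner(model0), error = function(e) NULL)
        if (!is.null(run)) {
          ll <- mixture_loglik(run$model, data)
          if (ll > best_ll) {
            best_ll <- ll
            best <- run$model
          }
        }
      }
      if (is.null(best)) stop("all random starts failed", call. = FALSE)
      best
    })
}

# When components carry distinct periods, an arbitrary cluster order from
# k-means may pair a cluster with the wrong period. Relabel clusters by
# the one-to-one assignment minimizing the total residual sum of squares
# of each cluster's mean profile under each component's design.
match_clusters_to_designs <- function(data, g, design, labels) {
  if (design$kind != "fourier" || length(unique(design$periods)) <= 1L) {
    return(labels)
  }
  rss <- matrix(0, g, g)
  for (cl in seq_len(g)) {
    ybar <- colMeans(data$values[labels == cl, , drop = FALSE])
    for (h in seq_len(g)) {
      X <- design_matrix(design, h)
      beta <- qr.solve(X, ybar)
      rss[cl, h] <- sum((ybar - drop(X %*% beta))^2)
    }
  }
  perms <- permutations(g)
  best <- which.min(apply(perms, 1L, function(p) {
    sum(rss[cbind(seq_len(g), p)])
  }))
  assignment <- perms[best, ]          # assignment[cl] = component for cluster cl
  assignment[labels]
}

# Moment-matching parameter estimates from a hard partition. The cluster
# mean residual profile estimates the realized shared effect; the lag-1 and
# lag-2 autocovariances of the de-meaned residuals identify rho and the
# AR(1)/white-noise variance split.
init_from_labels <- function(data, g, design, labels, variance_structure) {
  labels <- as.integer(labels)
  if (length(labels) != nrow(data$values)) {
    stop("`labels` length must equal the number of genes", call. = FALSE)
  }
  n <- nrow(data$values)
  m <- ncol(data$values)
  comps <- vector("list", g)
  for (h in seq_len(g)) {
    idx <- which(labels == h)
    if (length(idx) == 0L) {
      stop("initial partition leaves component ", h, " empty", call. = FALSE)
    }
    Yh <- data$values[idx, , drop = FALSE]
    X <- design_matrix(design, h)
    beta0 <- qr.solve(X, colMeans(Yh))
    R <- sweep(Yh, 2L, drop(X %*% beta0))
    if (variance_structure == "full") {
      v0 <- colMeans(R)
      Rc <- sweep(R, 2L, v0)
      d2_0 <- max(mean(v0^2), 1e-4)
    } else {
      Rc <- R
      d2_0 <- 0
    }
    c0 <- mean(Rc^2)
    c1 <- mean(Rc[, 1:(m - 1), drop = FALSE] * Rc[, 2:m, drop = FALSE])
    c2 <- if (m > 2) {
      mean(Rc[, 1:(m - 2), drop = FALSE] * Rc[, 3:m, drop = FALSE])
    } else c1^2 / max(c0, 1e-8)
    # lag-2/lag-1 ratio identifies rho under AR(1)-plus-white-noise, but is
    # ill-conditioned when the lag-1 autocovariance is small; fall back to
    # the plain lag-1 autocorrelation there, with an even variance split
    well_conditioned <- abs(c1) > 0.05 * c0
    rho0 <- if (well_conditioned) c2 / c1 else c1 / max(c0, 1e-8)
    rho0 <- max(min(rho0, 0.9), -0.9)
    if (variance_structure == "full") {
      gam <- if (well_conditioned && abs(rho0) > 1e-6) c1 / rho0 else c0 / 2
      gam <- max(min(gam, 0.95 * c0), 0.01 * c0)
      theta2_0 <- max(gam * (1 - rho0^2), 1e-4)
      sigma2_0 <- max(c0 - gam, 1e-4)
    } else {
      theta2_0 <- max(c0 * (1 - rho0^2), 1e-4)
      sigma2_0 <- 0
    }
    comps[[h]] <- component_params(
      weight_p = length(idx) / n, beta = beta0,
      theta2 = theta2_0, rho = rho0, sigma2 = sigma2_0, d2 = d2_0,
      period_omega = if (design$kind == "fourier") {
        design$periods[[min(h, length(design$periods))]]
      } else NULL)
  }
  mixture_model(comps, design, variance_structure = variance_structure)
}

#' MAP cluster labels from a posterior matrix
#'
#' Argmax per row; ties are broken by the lowest component index.
#'
#' @param tau An `n x g` matrix of posterior membership probabilities.
#' @return Integer vector of component indices in `1..g`.
#' @export
map_labels <- function(tau) {
  tau <- as.matrix(tau)
  if (any(abs(rowSums(tau) - 1) > 1e-6)) {
    stop("posterior rows must sum to 1", call. = FALSE)
  }
  max.col(tau, ties.method = "first")
}
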