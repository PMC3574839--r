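# EM machinery: E-step conditional moments against exact joint-Gaussian
# conditioning, M-step updates against grid-search oracles, objective
# monotonicity, convergence control, initialization, and the reduction to
# a plain mixture of regressions.

single_comp_model <- function(theta2, rho, sigma2, d2, beta = c(0.2, 0.5, -0.3),
                              times = 0:1, period = 4) {
  design <- design_spec("fourier", times, periods = period)
  mixture_model(list(component_params(1, beta, theta2 = theta2, rho = rho,
                                      sigma2 = sigma2, d2 = d2,
                                      period_omega = period)), design)
}

toy_em_model <- function() {
  design <- design_spec("fourier", 0:2, periods = c(8, 12))
  mixture_model(list(
    component_params(0.5, c(0.5, 1, 0.2), theta2 = 0.5, rho = 0.6,
                     sigma2 = 1, d2 = 0.4, period_omega = 8),
    component_params(0.5, c(-0.3, 0.8, -0.1), theta2 = 0.3, rho = -0.2,
                     sigma2 = 0.7, d2 = 0.1, period_omega = 12)),
    design)
}

test_that("E-step moments vanish without random effects", {
  model <- toy_em_model()
  for (h in 1:2) {
    model$components[[h]]$theta2 <- 0
    model$components[[h]]$d2 <- 0
  }
  data <- time_course_matrix(matrix(rnorm(24, sd = 2), 8, 3), times = 0:2)
  st <- e_step(model, data)
  for (h in 1:2) {
    expect_equal(st$comps[[h]]$u_mean, matrix(0, 3, 8))
    expect_equal(st$comps[[h]]$v_mean, rep(0, 3))
  }
  expect_equal(st$tau, posterior_probs(model, data), tolerance = 1e-12)
})

test_that("E-step matches exact joint-Gaussian conditioning (g = 1)", {
  model <- single_comp_model(theta2 = 0.7, rho = 0.4, sigma2 = 0.9, d2 = 0.5)
  cp <- model$components[[1]]
  X <- design_matrix(model$design, 1)
  set.seed(3)
  Y <- matrix(rnorm(4), 2, 2)
  data <- time_course_matrix(Y, times = 0:1)
  st <- e_step(model, data)
  or <- oracle_joint_conditioning(cp, X, Y)
  expect_equal(st$comps[[1]]$u_mean, or$u_mean, tolerance = 1e-8)
  expect_equal(st$comps[[1]]$v_mean, or$v_mean, tolerance = 1e-8)
  expect_equal(st$comps[[1]]$v_var, or$v_var, tolerance = 1e-8)
  expect_equal(st$comps[[1]]$u_var, or$u_var[[1]], tolerance = 1e-8)
  # accumulated second-moment matrix
  S_oracle <- Reduce(`+`, lapply(1:2, function(j) {
    or$u_mean[, j] %*% t(or$u_mean[, j]) + or$u_var[[j]]
  }))
  expect_equal(st$comps[[1]]$S, S_oracle, tolerance = 1e-8)
})

test_that("E-step moments match the conditioning oracle at m = 3", {
  model <- single_comp_model(theta2 = 0.5, rho = -0.6, sigma2 = 0.4, d2 = 0.25,
                             times = 0:2, period = 7)
  cp <- model$components[[1]]
  X <- design_matrix(model$design, 1)
  set.seed(8)
  Y <- matrix(rnorm(9), 3, 3)
  data <- time_course_matrix(Y, times = 0:2)
  st <- e_step(model, data)
  or <- oracle_joint_conditioning(cp, X, Y)
  expect_equal(st$comps[[1]]$u_mean, or$u_mean, tolerance = 1e-8)
  expect_equal(st$comps[[1]]$v_mean, or$v_mean, tolerance = 1e-8)
  expect_equal(st$comps[[1]]$u_var, or$u_var[[1]], tolerance = 1e-8)
})

test_that("gene-effect estimates shrink toward zero as noise grows", {
  set.seed(5)
  Y <- matrix(rnorm(6), 2, 3)
  data <- time_course_matrix(Y, times = 0:2)
  norms <- sapply(c(0.5, 2, 10, 50), function(s2) {
    model <- single_comp_model(theta2 = 0.6, rho = 0.3, sigma2 = s2, d2 = 0,
                               times = 0:2, period = 7)
    sum(e_step(model, data)$comps[[1]]$u_mean^2)
  })
  expect_true(all(diff(norms) < 0))
})

test_that("M-step reduces to per-cluster least squares without random effects", {
  set.seed(21)
  design <- design_spec("fourier", 0:5, periods = 6)
  X <- design_matrix(design, 1)
  Y <- matrix(rnorm(60), 10, 6)
  data <- time_course_matrix(Y, times = 0:5)
  model <- mixture_model(list(component_params(1, c(0, 0, 0), theta2 = 0,
                                               rho = 0, sigma2 = 1, d2 = 0,
                                               period_omega = 6)), design)
  st <- e_step(model, data)
  new <- m_step(st, data, design)
  ols <- drop(solve(crossprod(X), crossprod(X, colMeans(Y))))
  expect_equal(new$components[[1]]$beta, unname(ols), tolerance = 1e-10)
})

test_that("AR(1) profile update matches exhaustive grid maximization", {
  m <- 3
  t_sum <- 5
  # hand-built accumulated moment matrices
  S_list <- list(
    diag(2.4, m),
    {
      S <- matrix(c(3, 1.2, 0.3, 1.2, 2.8, 1.1, 0.3, 1.1, 2.5), m)
      (S + t(S)) / 2
    })
  for (S in S_list) {
    upd <- tcarmix:::profile_ar1_update(S, t_sum)
    # independent 2-D grid search over (rho, theta2) of the expected
    # u-block objective
    obj <- function(theta2, rho) {
      -0.5 * (t_sum * (m * log(theta2) + ar1_logdet(rho)) +
                sum(diag(ar1_inverse(rho, m) %*% S)) / theta2)
    }
    grid_rho <- seq(-0.99, 0.99, by = 0.001)
    grid_t2 <- seq(0.05, 3, by = 0.002)
    vals <- outer(grid_t2, grid_rho, Vectorize(obj))
    best <- arrayInd(which.max(vals), dim(vals))
    expect_equal(upd$rho, grid_rho[best[2]], tolerance = 2e-3)
    expect_equal(upd$theta2, grid_t2[best[1]], tolerance = 5e-3)
  }
  # diagonal S with equal entries: independence is optimal
  updd <- tcarmix:::profile_ar1_update(diag(1.7, 4), 3)
  expect_equal(updd$rho, 0, tolerance = 1e-4)
  expect_equal(updd$theta2, 1.7 / 3, tolerance = 1e-6)
})

test_that("compiled and reference EM loops implement the same scheme", {
  tw <- toy_sim(seed = 3, n_genes = 120)
  f_r <- fit_emmix_ar1(tw$sim$data, 3, tw$design, init = "true-partition",
                       labels = tw$sim$true_labels, max_iter = 50,
                       engine = "reference")
  f_c <- fit_emmix_ar1(tw$sim$data, 3, tw$design, init = "true-partition",
                       labels = tw$sim$true_labels, max_iter = 50,
                       engine = "compiled")
  expect_lt(max(abs(par_vec_of(f_r$model) - par_vec_of(f_c$model))), 1e-6)
  expect_equal(f_c$loglik_trace, f_r$loglik_trace, tolerance = 1e-7)
  expect_identical(f_c$labels, f_r$labels)
})

test_that("an infinite tolerance stops after exactly one EM iteration", {
  tw <- toy_sim(seed = 1, n_genes = 60)
  fit <- fit_emmix_ar1(tw$sim$data, 3, tw$design, init = "true-partition",
                       labels = tw$sim$true_labels, tol = Inf)
  expect_equal(fit$n_iter, 1L)
})

test_that("the objective trace is non-decreasing on fitted datasets", {
  for (sd in c(2, 9)) {
    tw <- toy_sim(seed = sd, n_genes = 150)
    fit <- fit_emmix_ar1(tw$sim$data, 3, tw$design, init = "true-partition",
                         labels = tw$sim$true_labels, max_iter = 300)
    expect_gt(min(diff(fit$loglik_trace)), -1e-6)
  }
})

test_that("single-component fit recovers the generating coefficients", {
  cfg <- sim_config("full", n_genes = 500, times = 0:23, periods = 10,
                    p = 1, a0 = 0.5, a1 = 1, b1 = 0.4,
                    theta2 = 0.5, rho = 0.6, sigma2 = 1, d2 = 0.3, seed = 17)
  sim <- sim_generate(cfg)
  design <- design_spec("fourier", cfg$times, periods = 10)
  fit <- fit_emmix_ar1(sim$data, 1, design, init = "true-partition",
                       labels = sim$true_labels)
  beta_hat <- fit$model$components[[1]]$beta
  # Monte-Carlo standard error of the profile mean coefficients:
  # per-time-point marginal variance / n, conservatively inflated
  mc_se <- sqrt((0.5 / (1 - 0.36) + 1 + 0.3) / 500)
  expect_lt(abs(beta_hat[2] - 1), 3 * mc_se)
  expect_lt(abs(beta_hat[3] - 0.4), 3 * mc_se)
  expect_lt(abs(fit$model$components[[1]]$rho - 0.6), 0.15)
})

test_that("with zero random-effect variances the fit is a mixture of regressions", {
  set.seed(31)
  cfg <- sim_config("no-cluster-effect", n_genes = 90, theta2 = 0, sigma2 = 1,
                    d2 = 0, seed = 31)
  sim <- sim_generate(cfg)
  design <- design_spec("fourier", cfg$times, periods = cfg$periods)
  start <- tcarmix:::init_from_labels(sim$data, 3, design, sim$true_labels,
                                      "full")
  for (h in 1:3) {
    start$components[[h]]$theta2 <- 0
    start$components[[h]]$d2 <- 0
  }
  fit <- fit_emmix_ar1(sim$data, 3, design, init = "model", init_model = start,
                       tol = 1e-8, max_iter = 400)
  # the reduced family is closed under the EM updates
  for (h in 1:3) {
    expect_equal(fit$model$components[[h]]$theta2, 0)
    expect_equal(fit$model$components[[h]]$d2, 0)
  }
  Xs <- lapply(1:3, function(h) design_matrix(design, h))
  ref <- oracle_mixreg_em(
    sim$data$values, Xs,
    weights = sapply(start$components, `[[`, "weight_p"),
    betas = lapply(start$components, `[[`, "beta"),
    sigma2s = sapply(start$components, `[[`, "sigma2"),
    n_iter = 400)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("initialization strategies behave as documented", {
  tw <- toy_sim(seed = 4, n_genes = 80)
  # true partition on noiseless data gives the exact per-cluster fit
  cfg0 <- sim_config("full", n_genes = 60, theta2 = 0, sigma2 = 0, d2 = 0,
                     seed = 6)
  sim0 <- sim_generate(cfg0)
  design0 <- design_spec("fourier", cfg0$times, periods = cfg0$periods)
  m0 <- initialize_model(sim0$data, 3, design0, strategy = "true-partition",
                         labels = sim0$true_labels)
  for (h in 1:3) {
    expect_equal(m0$components[[h]]$beta,
                 c(cfg0$a0[h], cfg0$a1[h], cfg0$b1[h]), tolerance = 1e-8)
  }
  # k-means initialization is deterministic under a seed
  m1 <- initialize_model(tw$sim$data, 3, tw$design, strategy = "kmeans",
                         seed = 123)
  m2 <- initialize_model(tw$sim$data, 3, tw$design, strategy = "kmeans",
                         seed = 123)
  expect_identical(par_vec_of(m1), par_vec_of(m2))
  # more random starts can only improve the best short-run objective
  obj_of <- function(n_starts, seed) {
    m <- initialize_model(tw$sim$data, 3, tw$design, strategy = "random-starts",
                          n_starts = n_starts, seed = seed)
    mixture_loglik(m, tw$sim$data)
  }
  expect_gte(obj_of(5, 55), obj_of(1, 55) - 1e-6)
  expect_error(initialize_model(tw$sim$data, 3, tw$design,
                                strategy = "true-partition"), "labels")
})

test_that("non-periodic profiles can be fitted with the B-spline design", {
  # two clusters of smooth non-periodic trajectories
  set.seed(61)
  times <- 0:17
  mu1 <- 0.1 * times - 0.005 * times^2
  mu2 <- 1.5 - 0.12 * times + 0.004 * times^2
  Y <- rbind(t(replicate(40, mu1)), t(replicate(30, mu2))) +
    matrix(rnorm(70 * 18, sd = 0.3), 70, 18)
  data <- time_course_matrix(Y, times = times)
  truth <- rep(1:2, c(40, 30))
  design <- design_spec("bspline", times, spline_df = 6)
  fit <- fit_emmix_ar1(data, 2, design, init = "true-partition",
                       labels = truth, max_iter = 200)
  expect_equal(error_rate(truth, fit$labels), 0)
  expect_gt(min(diff(fit$loglik_trace)), -1e-6)
  expect_length(fit$model$components[[1]]$beta, 6L)
})

test_that("MAP labels break ties toward the lower component index", {
  expect_equal(map_labels(matrix(c(0.9, 0.1), 1)), 1L)
  expect_equal(map_labels(matrix(c(0.5, 0.5), 1)), 1L)
  expect_equal(map_labels(diag(3)), 1:3)
  expect_error(map_labels(matrix(c(0.4, 0.4), 1)), "sum to 1")
})

test_that("components losing all responsibility mass raise a clear error", {
  tw <- toy_sim(seed = 12, n_genes = 40)
  model <- tcarmix:::init_from_labels(tw$sim$data, 3, tw$design,
                                      tw$sim$true_labels, "full")
  # push one component far away from all data
  model$components[[2]]$beta <- c(500, 0, 0)
  model$components[[2]]$sigma2 <- 1e-4
  model$components[[2]]$theta2 <- 1e-4
  model$components[[2]]$d2 <- 0
  expect_error(e_step(model, tw$sim$data, v_prev = matrix(0, 3, 24)),
               "vanishing responsibility")
})
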