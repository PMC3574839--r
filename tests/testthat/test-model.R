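# Component covariance assembly, mixture log-likelihood, posterior
# membership probabilities, and the plain-text model serialization.

toy_model <- function() {
  design <- design_spec("fourier", 0:2, periods = c(8, 12))
  mixture_model(list(
    component_params(0.6, c(0.5, 1, 0.2), theta2 = 0.5, rho = 0.6,
                     sigma2 = 1, d2 = 0.4, period_omega = 8),
    component_params(0.4, c(-0.3, 0.8, -0.1), theta2 = 0.3, rho = -0.2,
                     sigma2 = 0.7, d2 = 0.1, period_omega = 12)),
    design)
}

toy_data <- function(n = 4, m = 3, seed = 11) {
  set.seed(seed)
  time_course_matrix(matrix(rnorm(n * m), n, m), times = seq_len(m) - 1)
}

test_that("component covariance combines AR(1), cluster and noise terms", {
  p <- list(theta2 = 0, rho = 0, sigma2 = 1, d2 = 0)
  expect_equal(component_covariance(p, 5), diag(5))
  p2 <- list(theta2 = 0.5, rho = 0.6, sigma2 = 1, d2 = 0.4)
  S <- component_covariance(p2, 3)
  expect_equal(S, 0.5 * ar1_matrix(0.6, 3) + 1.4 * diag(3))
  expect_equal(diag(S), rep(0.5 / (1 - 0.36) + 1.4, 3))
  expect_equal(S[1, 1], 2.18125)
  # AR(1)-residual regime: covariance is exactly theta2 * A(rho)
  p3 <- list(theta2 = 0.5, rho = 0.6, sigma2 = 0, d2 = 0)
  expect_equal(component_covariance(p3, 4), 0.5 * ar1_matrix(0.6, 4))
  expect_error(component_covariance(list(theta2 = 0, rho = 0, sigma2 = 0,
                                         d2 = 0), 3), "singular")
})

test_that("adding noise variance shifts every covariance eigenvalue", {
  p <- list(theta2 = 0.5, rho = 0.6, sigma2 = 1, d2 = 0.4)
  ev1 <- eigen(component_covariance(p, 6), symmetric = TRUE)$values
  p$sigma2 <- p$sigma2 + 0.25
  ev2 <- eigen(component_covariance(p, 6), symmetric = TRUE)$values
  expect_equal(ev2, ev1 + 0.25)
})

test_that("mixture log-likelihood matches closed forms and the density oracle", {
  # standard-normal single component at the origin
  design <- design_spec("fourier", 0:1, periods = 4)
  m1 <- mixture_model(list(component_params(1, c(0, 0, 0), theta2 = 0,
                                            rho = 0, sigma2 = 1, d2 = 0,
                                            period_omega = 4)), design)
  d0 <- time_course_matrix(matrix(0, 1, 2), times = 0:1)
  expect_equal(mixture_loglik(m1, d0), -log(2 * pi))

  model <- toy_model()
  data <- toy_data()
  expect_equal(mixture_loglik(model, data), oracle_mixture(model, data)$loglik,
               tolerance = 1e-10)
  # additivity over genes: duplicating the dataset doubles the value
  dup <- time_course_matrix(rbind(data$values, data$values), times = data$times)
  expect_equal(mixture_loglik(model, dup), 2 * mixture_loglik(model, data))
})

test_that("posterior probabilities follow the Bayes rule", {
  model <- toy_model()
  data <- toy_data(n = 6)
  tau <- posterior_probs(model, data)
  expect_equal(rowSums(tau), rep(1, 6), tolerance = 1e-10)
  expect_equal(tau, oracle_mixture(model, data)$tau, tolerance = 1e-12)

  # single component: all mass on it
  design <- design_spec("fourier", 0:2, periods = 8)
  m1 <- mixture_model(list(component_params(1, c(0, 0, 0), theta2 = 0.2,
                                            rho = 0.1, sigma2 = 1, d2 = 0,
                                            period_omega = 8)), design)
  expect_equal(drop(posterior_probs(m1, data)), rep(1, 6))

  # two identical components split by their mixing weights
  cp <- component_params(0.7, c(0.1, 0.5, -0.2), theta2 = 0.4, rho = 0.3,
                         sigma2 = 0.8, d2 = 0.2, period_omega = 8)
  cp2 <- cp
  cp2$weight_p <- 0.3
  m2 <- mixture_model(list(cp, cp2), design)
  tau2 <- posterior_probs(m2, data)
  expect_equal(tau2, matrix(rep(c(0.7, 0.3), each = 6), 6, 2))
})

test_that("posterior rows sum to one for random admissible models", {
  set.seed(99)
  for (rep in 1:5) {
    g <- sample(2:4, 1)
    design <- design_spec("fourier", 0:7, periods = runif(g, 4, 20))
    comps <- lapply(seq_len(g), function(h) {
      component_params(1 / g, rnorm(3), theta2 = runif(1, 0.1, 2),
                       rho = runif(1, -0.8, 0.8), sigma2 = runif(1, 0.1, 2),
                       d2 = runif(1, 0, 1))
    })
    model <- mixture_model(comps, design)
    data <- time_course_matrix(matrix(rnorm(80), 10, 8), times = 0:7)
    expect_equal(rowSums(posterior_probs(model, data)), rep(1, 10),
                 tolerance = 1e-10)
  }
})

test_that("model parameters round-trip bit-exactly through text", {
  model <- toy_model()
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(par_vec_of(back), par_vec_of(model))
  expect_identical(back$design$times, model$design$times)
  expect_identical(back$variance_structure, model$variance_structure)
})

test_that("model construction enforces the invariants", {
  design <- design_spec("fourier", 0:2, periods = 8)
  good <- component_params(0.5, c(0, 0, 0), 0.1, 0, 1, 0)
  expect_error(mixture_model(list(good, good, good), design), "sum to 1")
  expect_error(component_params(0.5, c(0, 0, 0), -0.1, 0, 1, 0),
               "non-negative")
  expect_error(component_params(0.5, c(0, 0, 0), 0.1, 1.2, 1, 0), "rho")
  bad_beta <- component_params(1, c(0, 0), 0.1, 0, 1, 0)
  expect_error(mixture_model(list(bad_beta), design), "beta")
})
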