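# Synthetic-data generator: presets, determinism, and moment matching
# against the model covariance.

test_that("presets carry the six parameter blocks", {
  t1 <- sim_preset("t1")
  expect_equal(t1$theta2, rep(0.5, 3))
  expect_equal(t1$d2, c(0.4, 0.2, 0.3))
  expect_equal(t1$sigma2, rep(1, 3))
  expect_equal(t1$p, c(0.585, 0.1, 0.315))
  expect_equal(t1$periods, c(6, 10, 16))
  expect_equal(t1$rho, rep(0.6, 3))
  expect_equal(t1$times, 0:23)
  t2 <- sim_preset("t2")
  expect_equal(t2$theta2, rep(1.3, 3))
  expect_equal(t2$regime, "full")
  t4 <- sim_preset("t4")
  expect_equal(t4$theta2, rep(1.3, 3))
  expect_equal(t4$d2, rep(0, 3))
  t5 <- sim_preset("t5")
  expect_equal(t5$sigma2, rep(0, 3))
  expect_equal(t5$regime, "ar1-residual")
  expect_error(sim_preset("t7"))
})

test_that("regime constraints are enforced", {
  expect_error(sim_config("no-cluster-effect", d2 = 0.1, sigma2 = 1),
               "d2 = 0")
  expect_error(sim_config("ar1-residual", d2 = 0, sigma2 = 1),
               "sigma2 = 0")
  expect_error(sim_config("full", p = c(0.5, 0.4)), "sum to 1")
})

test_that("the noiseless limit reproduces the mean profiles exactly", {
  cfg <- sim_config("full", n_genes = 50, theta2 = 0, sigma2 = 0, d2 = 0,
                    seed = 9)
  sim <- sim_generate(cfg)
  for (h in 1:3) {
    idx <- which(sim$true_labels == h)
    X <- design_matrix(sim$true_model$design, h)
    mu <- drop(X %*% sim$true_model$components[[h]]$beta)
    for (j in idx) expect_equal(sim$data$values[j, ], mu)
  }
})

test_that("generation is bit-reproducible under a seed", {
  cfg <- sim_preset("t1", n_genes = 50)
  s1 <- sim_generate(cfg, seed = 77)
  s2 <- sim_generate(cfg, seed = 77)
  expect_identical(s1$data$values, s2$data$values)
  expect_identical(s1$true_labels, s2$true_labels)
  s3 <- sim_generate(cfg, seed = 78)
  expect_false(identical(s1$data$values, s3$data$values))
})

test_that("cluster proportions follow the law of large numbers", {
  cfg <- sim_preset("t1", n_genes = 10000)
  sim <- sim_generate(cfg, seed = 5)
  props <- tabulate(sim$true_labels, 3) / 10000
  for (h in 1:3) {
    se <- sqrt(cfg$p[h] * (1 - cfg$p[h]) / 10000)
    expect_lt(abs(props[h] - cfg$p[h]), 3 * se)
  }
})

test_that("single-component empirical covariance matches the model covariance", {
  cfg <- sim_config("full", n_genes = 10000, times = 0:5, periods = 10,
                    p = 1, a0 = 0.3, a1 = 1, b1 = 0.2,
                    theta2 = 0.5, rho = 0.6, sigma2 = 1, d2 = 0, seed = 31)
  sim <- sim_generate(cfg)
  emp <- cov(sim$data$values)
  theo <- component_covariance(sim$true_model$components[[1]], 6)
  # entrywise Monte-Carlo tolerance: 3 * SE of a covariance entry
  se <- 3 * sqrt((outer(diag(theo), diag(theo)) + theo^2) / 10000)
  expect_true(all(abs(emp - theo) < se + 0.02))
})

test_that("the shared effect induces cross-gene covariance of size d2", {
  # within a component, two different genes covary at a fixed time point
  # through the shared draw only: Cov(y_i(t), y_j(t)) = d2
  cfg <- sim_config("full", n_genes = 2, times = 0:3, periods = c(10, 14),
                    p = c(0.5, 0.5), a0 = c(0, 0), a1 = c(0, 0), b1 = c(0, 0),
                    theta2 = 0.2, rho = 0.3, sigma2 = 0.5, d2 = c(0.4, 0.4),
                    seed = 1)
  reps <- 3000
  prods <- matrix(NA_real_, reps, 4)
  kept <- 0
  for (r in seq_len(reps)) {
    sim <- sim_generate(cfg, seed = r)
    idx1 <- which(sim$true_labels == 1)
    if (length(idx1) == 2) {
      kept <- kept + 1
      prods[kept, ] <- sim$data$values[idx1[1], ] * sim$data$values[idx1[2], ]
    }
  }
  est <- mean(prods[seq_len(kept), ])
  expect_lt(abs(est - 0.4), 3 * 0.5 / sqrt(kept * 4))
  # and vanishes in the no-cluster-effect regime
  cfg0 <- sim_config("no-cluster-effect", n_genes = 2, times = 0:3,
                     periods = c(10, 14), p = c(0.5, 0.5), a0 = c(0, 0),
                     a1 = c(0, 0), b1 = c(0, 0), theta2 = 0.2, rho = 0.3,
                     sigma2 = 0.5, d2 = 0, seed = 1)
  kept0 <- 0
  prods0 <- matrix(NA_real_, reps, 4)
  for (r in seq_len(reps)) {
    sim <- sim_generate(cfg0, seed = r)
    idx1 <- which(sim$true_labels == 1)
    if (length(idx1) == 2) {
      kept0 <- kept0 + 1
      prods0[kept0, ] <- sim$data$values[idx1[1], ] * sim$data$values[idx1[2], ]
    }
  }
  expect_lt(abs(mean(prods0[seq_len(kept0), ])), 3 * 0.5 / sqrt(kept0 * 4))
})

test_that("replicate seeds are derived by the documented splitting rule", {
  expect_identical(tcarmix:::replicate_seed(100L, 7L), 107L)
  cfg <- sim_preset("t1", n_genes = 30)
  s <- sim_generate(cfg, seed = tcarmix:::replicate_seed(1L, 3L))
  s2 <- sim_generate(cfg, seed = 4L)
  expect_identical(s$data$values, s2$data$values)
})
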