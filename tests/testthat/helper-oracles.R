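# Independent oracles used by the tests. These deliberately avoid the
# package's own computational paths: dense linear algebra via solve() and
# determinant(), pair counting by explicit enumeration, and conditional
# Gaussian moments by brute-force block conditioning.

# Multivariate normal log-density via solve()/determinant() (not Cholesky).
oracle_mvn_logdens <- function(y, mu, Sigma) {
  m <- length(y)
  d <- y - mu
  q <- drop(t(d) %*% solve(Sigma, d))
  ld <- determinant(Sigma, logarithm = TRUE)$modulus
  -0.5 * (m * log(2 * pi) + ld + q)
}

# Mixture log-likelihood and posteriors by direct density summation.
oracle_mixture <- function(model, data) {
  n <- nrow(data$values)
  g <- model$g
  dens <- matrix(0, n, g)
  for (h in seq_len(g)) {
    cp <- model$components[[h]]
    X <- design_matrix(model$design, h)
    mu <- drop(X %*% cp$beta)
    Sigma <- component_covariance(cp, ncol(data$values))
    for (j in seq_len(n)) {
      dens[j, h] <- cp$weight_p * exp(oracle_mvn_logdens(data$values[j, ], mu, Sigma))
    }
  }
  list(loglik = sum(log(rowSums(dens))), tau = dens / rowSums(dens))
}

# Exact conditional moments of (u_1, ..., u_n, v) given all profiles for a
# single-component model, by stacked joint-Gaussian conditioning.
oracle_joint_conditioning <- function(cp, X, Y) {
  n <- nrow(Y)
  m <- ncol(Y)
  A <- ar1_matrix(cp$rho, m)
  mu <- drop(X %*% cp$beta)
  # latent vector w = (u_1, ..., u_n, v), observed y = (y_1, ..., y_n)
  d_lat <- n * m + m
  Sig_w <- matrix(0, d_lat, d_lat)
  for (j in seq_len(n)) {
    idx <- (j - 1) * m + seq_len(m)
    Sig_w[idx, idx] <- cp$theta2 * A
  }
  vi <- n * m + seq_len(m)
  Sig_w[vi, vi] <- diag(cp$d2, m)
  # y_j = mu + u_j + v + eps_j
  H <- matrix(0, n * m, d_lat)
  for (j in seq_len(n)) {
    idx <- (j - 1) * m + seq_len(m)
    H[idx, idx] <- diag(m)
    H[idx, vi] <- diag(m)
  }
  Sig_yy <- H %*% Sig_w %*% t(H) + diag(cp$sigma2, n * m)
  Sig_wy <- Sig_w %*% t(H)
  yc <- as.numeric(t(Y)) - rep(mu, n)
  K <- Sig_wy %*% solve(Sig_yy)
  w_mean <- drop(K %*% yc)
  w_var <- Sig_w - K %*% t(Sig_wy)
  list(
    u_mean = vapply(seq_len(n), function(j) w_mean[(j - 1) * m + seq_len(m)],
                    numeric(m)),
    u_var = lapply(seq_len(n), function(j) {
      idx <- (j - 1) * m + seq_len(m)
      w_var[idx, idx]
    }),
    v_mean = w_mean[vi],
    v_var = w_var[vi, vi])
}

# Pair-counting agreement by explicit enumeration over all item pairs.
oracle_pair_counts <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  list(n11 = sum(same_a & same_b), n00 = sum(!same_a & !same_b),
       total = choose(n, 2))
}

oracle_rand <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  (pc$n11 + pc$n00) / pc$total
}

oracle_ari <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / pc$total
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - exp_idx) < 1e-300) return(0)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# Minimum mismatch fraction by exhaustive search over relabelings of the
# predicted clusters (independent of the package's confusion-matrix path:
# applies each permutation to the label vector itself).
oracle_error_rate <- function(true_labels, pred_labels) {
  lev <- sort(unique(c(true_labels, pred_labels)))
  k <- length(lev)
  true_i <- match(true_labels, lev)
  pred_i <- match(pred_labels, lev)
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == k), ,
                 drop = FALSE]
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    err <- mean(perms[r, pred_i] != true_i)
    if (err < best) best <- err
  }
  best
}

# Reference EM for a mixture of regressions with spherical noise
# (independent implementation of the theta2 = d2 = 0 reduction).
oracle_mixreg_em <- function(Y, Xs, weights, betas, sigma2s, n_iter = 50) {
  n <- nrow(Y)
  m <- ncol(Y)
  g <- length(weights)
  for (it in seq_len(n_iter)) {
    logd <- sapply(seq_len(g), function(h) {
      mu <- drop(Xs[[h]] %*% betas[[h]])
      -0.5 * (m * log(2 * pi * sigma2s[h]) +
                rowSums(sweep(Y, 2, mu)^2) / sigma2s[h]) + log(weights[h])
    })
    mx <- apply(logd, 1, max)
    tau <- exp(logd - mx) / rowSums(exp(logd - mx))
    for (h in seq_len(g)) {
      w <- tau[, h]
      ybar <- colSums(Y * w) / sum(w)
      betas[[h]] <- solve(crossprod(Xs[[h]]), crossprod(Xs[[h]], ybar))
      mu <- drop(Xs[[h]] %*% betas[[h]])
      sigma2s[h] <- sum(w * rowSums(sweep(Y, 2, mu)^2)) / (m * sum(w))
      weights[h] <- sum(w) / n
    }
  }
  logd <- sapply(seq_len(g), function(h) {
    mu <- drop(Xs[[h]] %*% betas[[h]])
    -0.5 * (m * log(2 * pi * sigma2s[h]) +
              rowSums(sweep(Y, 2, mu)^2) / sigma2s[h]) + log(weights[h])
  })
  mx <- apply(logd, 1, max)
  list(loglik = sum(mx + log(rowSums(exp(logd - mx)))),
       weights = weights, betas = betas, sigma2s = sigma2s)
}

# Flat numeric view of all component parameters (round-trip comparisons).
par_vec_of <- function(model) {
  unlist(lapply(model$components, function(cp) {
    c(cp$weight_p, cp$beta, cp$theta2, cp$rho, cp$sigma2, cp$d2,
      cp$period_omega)
  }))
}

# Small labelled dataset used across the EM tests.
toy_sim <- function(seed = 42, n_genes = 120, regime = "full") {
  cfg <- sim_config(regime, n_genes = n_genes,
                    sigma2 = if (regime == "ar1-residual") 0 else 1,
                    d2 = switch(regime, "full" = c(0.4, 0.2, 0.3), 0),
                    seed = seed)
  list(cfg = cfg, sim = sim_generate(cfg),
       design = design_spec("fourier", cfg$times, periods = cfg$periods))
}
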