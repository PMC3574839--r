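# Replicated simulation studies: generate datasets from a preset, fit the
# AR(1) random-effects model (initialized at the true partition) and the
# AR(1)-residual baseline (initialized at the true parameter values),
# optionally k-means, and summarize clustering metrics and parameter
# recovery across replicates.

# Best one-to-one matching of predicted clusters to true clusters:
# perm[h] is the predicted label assigned to true component h.
match_components <- function(true_labels, pred_labels, g) {
  tab <- matrix(0, g, g)
  tt <- table(factor(true_labels, levels = seq_len(g)),
              factor(pred_labels, levels = seq_len(g)))
  tab[seq_len(nrow(tt)), seq_len(ncol(tt))] <- tt
  perms <- permutations(g)
  best_r <- 1L
  best <- -1
  for (r in seq_len(nrow(perms))) {
    hit <- sum(tab[cbind(seq_len(g), perms[r, ])])
    if (hit > best) {
      best <- hit
      best_r <- r
    }
  }
  perms[best_r, ]
}

# True-parameter AR(1)-residual model matching a simulation configuration
# (the baseline has no sigma2/d2, so its "true values" are p, beta, theta2,
# rho of the generator).
kim_true_model <- function(config) {
  design <- design_spec("fourier", config$times, order_k = 1L,
                        periods = config$periods)
  comps <- lapply(seq_len(config$g), function(h) {
    component_params(weight_p = config$p[h],
                     beta = c(config$a0[h], config$a1[h], config$b1[h]),
                     theta2 = config$theta2[h], rho = config$rho[h],
                     sigma2 = 0, d2 = 0, period_omega = config$periods[h])
  })
  mixture_model(comps, design, variance_structure = "ar1-residual")
}

extract_estimates <- function(fit, perm, method, replicate) {
  g <- fit$model$g
  do.call(rbind, lapply(seq_len(g), function(h) {
    cp <- fit$model$components[[perm[h]]]
    data.frame(replicate = replicate, method = method, component = h,
               param = c("p", "a0", "a1", "b1", "theta2", "rho", "sigma2", "d2"),
               value = c(cp$weight_p, cp$beta[1], cp$beta[2], cp$beta[3],
                         cp$theta2, cp$rho, cp$sigma2, cp$d2))
  }))
}

#' Run a replicated simulation study
#'
#' Generates `n_replicates` datasets from a preset (or any
#' [sim_config()]), fits the AR(1) random-effects model starting from the
#' true partition and, optionally, the AR(1)-residual baseline starting
#' from the true parameter values and a k-means baseline, and collects
#' per-replicate clustering metrics and component-aligned parameter
#' estimates. Replicate `r` uses seed `seed + r`, so any replicate can be
#' regenerated in isolation. Per-replicate fit failures are counted and
#' reported, not fatal.
#'
#' @param preset A preset id (`"t1"` .. `"t6"`, see [sim_preset()]) or a
#'   [sim_config()] object.
#' @param n_replicates Number of replicate datasets.
#' @param seed Master seed.
#' @param n_genes Genes per replicate (default 400).
#' @param fit_baseline Also fit the AR(1)-residual baseline (default
#'   `TRUE`).
#' @param fit_kmeans Also run the k-means baseline (default `FALSE`).
#' @param tol,max_iter EM control, passed to the fitters.
#' @return A list of class `tc_study`: `metrics` (one row per replicate and
#'   method with `error_rate`, `rand`, `adjusted_rand`), `estimates`
#'   (aligned per-replicate parameter estimates), `summary` (per metric and
#'   method: mean, RMSE about the ideal value, sample SD, and the fraction
#'   of replicates where the proposed model beats the baseline), `bias`
#'   (parameter-recovery table for the proposed model), `n_failed`, and the
#'   `config` used.
#' @export
replicate_study <- function(preset, n_replicates = 100L, seed = 1L,
                            n_genes = 400L, fit_baseline = TRUE,
                            fit_kmeans = FALSE, tol = 1e-5, max_iter = 1000L) {
  config <- if (inherits(preset, "tc_sim_config")) {
    preset
  } else {
    sim_preset(preset, n_genes = n_genes, seed = seed)
  }
  g <- config$g
  design <- design_spec("fourier", config$times, order_k = 1L,
                        periods = config$periods)
  kim0 <- if (fit_baseline) kim_true_model(config) else NULL

  metrics <- list()
  estimates <- list()
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    rep_seed <- replicate_seed(seed, r)
    sim <- sim_generate(config, seed = rep_seed)
    res <- tryCatch({
      rows <- list()
      est <- list()
      fit_w <- fit_emmix_ar1(sim$data, g, design, init = "true-partition",
                             labels = sim$true_labels, tol = tol,
                             max_iter = max_iter)
      perm_w <- match_components(sim$true_labels, fit_w$labels, g)
      rows$emw <- data.frame(
        replicate = r, method = "em_w",
        error_rate = error_rate(sim$true_labels, fit_w$labels),
        rand = rand_index(sim$true_labels, fit_w$labels),
        adjusted_rand = adjusted_rand_index(sim$true_labels, fit_w$labels))
      est$emw <- extract_estimates(fit_w, perm_w, "em_w", r)
      if (fit_baseline) {
        fit_k <- fit_ar1_residual(sim$data, g, design, init = "model",
                                  init_model = kim0, tol = tol,
                                  max_iter = max_iter)
        perm_k <- match_components(sim$true_labels, fit_k$labels, g)
        rows$kim <- data.frame(
          replicate = r, method = "ar1_residual",
          error_rate = error_rate(sim$true_labels, fit_k$labels),
          rand = rand_index(sim$true_labels, fit_k$labels),
          adjusted_rand = adjusted_rand_index(sim$true_labels, fit_k$labels))
        est$kim <- extract_estimates(fit_k, perm_k, "ar1_residual", r)
      }
      if (fit_kmeans) {
        km_labels <- fit_kmeans_profiles(sim$data, g, seed = rep_seed,
                                         n_starts = 10L)
        rows$km <- data.frame(
          replicate = r, method = "kmeans",
          error_rate = error_rate(sim$true_labels, km_labels),
          rand = rand_index(sim$true_labels, km_labels),
          adjusted_rand = adjusted_rand_index(sim$true_labels, km_labels))
      }
      list(rows = do.call(rbind, rows), est = do.call(rbind, est))
    }, error = function(e) {
      message("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      metrics[[length(metrics) + 1L]] <- res$rows
      estimates[[length(estimates) + 1L]] <- res$est
    }
  }
  metrics <- do.call(rbind, metrics)
  estimates <- do.call(rbind, estimates)
  rownames(metrics) <- rownames(estimates) <- NULL

  not_worse <- config$regime == "ar1-residual"
  summary_tab <- study_summary(metrics, not_worse = not_worse)
  bias_tab <- study_bias(estimates, config, method = "em_w")

  structure(list(metrics = metrics, estimates = estimates,
                 summary = summary_tab, bias = bias_tab,
                 n_failed = n_failed, config = config,
                 not_worse = not_worse),
            class = "tc_study")
}

# Footer-style metric summary: one row per metric and method, with the
# fraction of replicates where the proposed model beats the baseline.
study_summary <- function(metrics, not_worse = FALSE) {
  specs <- list(error_rate = list(ref = 0, better = "lower"),
                rand = list(ref = 1, better = "higher"),
                adjusted_rand = list(ref = 1, better = "higher"))
  rows <- list()
  for (mname in names(specs)) {
    sp <- specs[[mname]]
    a <- metrics[metrics$method == "em_w", mname]
    for (meth in unique(metrics$method)) {
      x <- metrics[metrics$method == meth, mname]
      prop <- if (meth != "em_w" && length(x) == length(a) && length(a) >= 2) {
        s <- summarize_replicates(a, x, reference = sp$ref,
                                  better = sp$better, not_worse = not_worse)
        attr(s, "proportion_better")
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        metric = mname, method = meth, mean = mean(x),
        rmse = sqrt(mean((x - sp$ref)^2)),
        sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
        proportion_emw_better = prop)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Parameter-recovery table: bias, RMSE and Monte-Carlo standard error of
# the component-aligned estimates against the generating values.
study_bias <- function(estimates, config, method = "em_w") {
  truth <- data.frame(
    component = rep(seq_len(config$g), each = 8L),
    param = rep(c("p", "a0", "a1", "b1", "theta2", "rho", "sigma2", "d2"),
                config$g),
    true = c(vapply(seq_len(config$g), function(h) {
      c(config$p[h], config$a0[h], config$a1[h], config$b1[h],
        config$theta2[h], config$rho[h], config$sigma2[h], config$d2[h])
    }, numeric(8L))))
  est <- estimates[estimates$method == method, ]
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    sel <- est[est$component == truth$component[i] &
                 est$param == truth$param[i], "value"]
    if (length(sel) == 0L) next
    dev <- sel - truth$true[i]
    rows[[length(rows) + 1L]] <- data.frame(
      component = truth$component[i], param = truth$param[i],
      true = truth$true[i], bias = mean(dev),
      rmse = sqrt(mean(dev^2)),
      mc_se = if (length(dev) >= 2) stats::sd(dev) / sqrt(length(dev)) else NA_real_,
      n = length(dev))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.tc_study <- function(x, ...) {
  cat("Replicated simulation study (", x$config$regime, " regime, ",
      length(unique(x$metrics$replicate)), " replicates, ",
      x$config$n_genes, " genes)\n", sep = "")
  if (x$n_failed > 0) cat("  failed replicates:", x$n_failed, "\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write the study summary to a tab-delimited report
#'
#' @param study A [replicate_study()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_study_summary <- function(study, path) {
  stopifnot(inherits(study, "tc_study"))
  utils::write.table(study$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
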