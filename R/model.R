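#' Time-course expression matrix
#'
#' Container for an n-genes by m-time-points expression matrix with its time
#' coordinates and gene identifiers. Values are typically log-scale
#' expression; missing values are not allowed (drop incomplete genes
#' upstream, e.g. in [read_time_course()]).
#'
#' @param values Numeric `n x m` matrix.
#' @param times Numeric vector of length m.
#' @param gene_ids Character vector of length n (defaults to row names or
#'   `g1..gn`).
#' @return An object of class `tc_matrix`: a list with elements `values`,
#'   `times`, `gene_ids`.
#' @export
time_course_matrix <- function(values, times = NULL, gene_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  if (anyNA(values)) stop("`values` must not contain missing entries", call. = FALSE)
  if (ncol(values) < 2L) stop("need at least two time points", call. = FALSE)
  if (is.null(times)) times <- seq_len(ncol(values)) - 1
  times <- as.numeric(times)
  if (length(times) != ncol(values)) {
    stop("`times` length (", length(times), ") must match ncol(values) (",
         ncol(values), ")", call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  }
  if (length(gene_ids) != nrow(values)) {
    stop("`gene_ids` length must match nrow(values)", call. = FALSE)
  }
  dimnames(values) <- NULL
  structure(list(values = values, times = times, gene_ids = as.character(gene_ids)),
            class = "tc_matrix")
}

#' @export
print.tc_matrix <- function(x, ...) {
  cat("Time-course matrix:", nrow(x$values), "genes x", length(x$times),
      "time points\n")
  cat("  times:", paste(utils::head(x$times, 8), collapse = ", "),
      if (length(x$times) > 8) "...", "\n")
  invisible(x)
}

#' @export
dim.tc_matrix <- function(x) dim(x$values)

#' Parameters of one mixture component
#'
#' @param weight_p Mixing proportion in (0, 1).
#' @param beta Regression coefficients for the component's design matrix
#'   (for a first-order Fourier design: `(a0, a1, b1)`).
#' @param theta2 Innovation-scale variance of the gene-specific AR(1) random
#'   effect (non-negative); the effect's covariance is `theta2 * A(rho)`.
#' @param rho AR(1) autocorrelation in (-1, 1).
#' @param sigma2 Measurement-error variance (non-negative, white noise).
#' @param d2 Variance of the cluster-shared random effect (non-negative);
#'   measures coregulation strength within the cluster.
#' @param period_omega Period of the component's Fourier mean (optional for
#'   B-spline designs).
#' @return An object of class `tc_component`.
#' @export
component_params <- function(weight_p, beta, theta2, rho, sigma2, d2,
                             period_omega = NULL) {
  if (weight_p <= 0 || weight_p >= 1) {
    # single-component models are allowed weight 1
    if (!(isTRUE(all.equal(weight_p, 1)))) {
      stop("`weight_p` must lie in (0, 1]", call. = FALSE)
    }
  }
  if (theta2 < 0 || sigma2 < 0 || d2 < 0) {
    stop("variances `theta2`, `sigma2`, `d2` must be non-negative", call. = FALSE)
  }
  if (abs(rho) >= 1) stop("`rho` must lie strictly inside (-1, 1)", call. = FALSE)
  structure(list(weight_p = weight_p, beta = as.numeric(beta), theta2 = theta2,
                 rho = rho, sigma2 = sigma2, d2 = d2, period_omega = period_omega),
            class = "tc_component")
}

#' Mixture model of linear mixed components
#'
#' A g-component normal mixture in which component h has mean `X_h beta_h`
#' and covariance `theta2_h * A(rho_h) + d2_h * I + sigma2_h * I`
#' (the gene-level AR(1) random effect, the cluster-shared effect and white
#' measurement noise; the random-effect design matrices are identities).
#'
#' @param components List of [component_params()] objects.
#' @param design A [design_spec()] object shared by all components (each
#'   Fourier component uses its own period).
#' @param variance_structure `"full"` for the AR(1) random-effects model,
#'   `"ar1-residual"` for the baseline whose covariance is `theta2 * A(rho)`
#'   only.
#' @return An object of class `tc_model`.
#' @export
mixture_model <- function(components, design,
                          variance_structure = c("full", "ar1-residual")) {
  variance_structure <- match.arg(variance_structure)
  stopifnot(inherits(design, "tc_design"), length(components) >= 1L)
  for (cp in components) stopifnot(inherits(cp, "tc_component"))
  w <- vapply(components, `[[`, numeric(1), "weight_p")
  if (abs(sum(w) - 1) > 1e-10) {
    stop("mixing proportions must sum to 1 (got ", sum(w), ")", call. = FALSE)
  }
  p_design <- n_design_cols(design)
  for (cp in components) {
    if (length(cp$beta) != p_design) {
      stop("`beta` length ", length(cp$beta), " does not match the design (",
           p_design, " columns)", call. = FALSE)
    }
  }
  structure(list(g = length(components), components = components,
                 design = design, variance_structure = variance_structure),
            class = "tc_model")
}

#' @export
print.tc_model <- function(x, ...) {
  cat(x$g, "-component ", x$variance_structure, " mixture (",
      x$design$kind, " design)\n", sep = "")
  for (h in seq_len(x$g)) {
    cp <- x$components[[h]]
    cat(sprintf("  [%d] p=%.3f theta2=%.3f rho=%.3f sigma2=%.3f d2=%.3f%s\n",
                h, cp$weight_p, cp$theta2, cp$rho, cp$sigma2, cp$d2,
                if (!is.null(cp$period_omega)) sprintf(" omega=%g", cp$period_omega) else ""))
  }
  invisible(x)
}

#' Marginal covariance matrix of one component
#'
#' Assembles `theta2 * A(rho) + d2 * I + sigma2 * I`. With all three
#' variances zero the covariance would be singular, which is rejected.
#' For the AR(1)-residual baseline pass `sigma2 = d2 = 0` with
#' `theta2 > 0`.
#'
#' @param params A [component_params()] object (or any list with elements
#'   `theta2`, `rho`, `sigma2`, `d2`).
#' @param m Number of time points.
#' @return A symmetric positive-definite `m x m` matrix.
#' @export
component_covariance <- function(params, m) {
  m <- check_m(m)
  th2 <- params$theta2
  diag_add <- params$sigma2 + params$d2
  if (th2 <= 0 && diag_add <= 0) {
    stop("singular component covariance: theta2, sigma2 and d2 are all zero",
         call. = FALSE)
  }
  if (th2 > 0) {
    th2 * ar1_matrix(params$rho, m) + diag(diag_add, m)
  } else {
    diag(diag_add, m)
  }
}

# Log multivariate-normal densities of the rows of Y under N(mu, Sigma),
# via one Cholesky factorization shared across rows.
mvn_logdens_rows <- function(Y, mu, Sigma) {
  L <- tryCatch(chol(Sigma), error = function(e) {
    stop("singular component covariance in density evaluation: ",
         conditionMessage(e), call. = FALSE)
  })
  m <- ncol(Y)
  Z <- backsolve(L, t(Y) - mu, transpose = TRUE)
  -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(L))) + colSums(Z^2))
}

# n x g matrix of log(p_h) + log phi_h(y_j) for all genes and components.
component_logdens <- function(model, data) {
  Y <- data$values
  m <- ncol(Y)
  out <- matrix(NA_real_, nrow(Y), model$g)
  for (h in seq_len(model$g)) {
    cp <- model$components[[h]]
    X <- design_matrix(model$design, h)
    mu <- drop(X %*% cp$beta)
    Sigma <- component_covariance(cp, m)
    out[, h] <- log(cp$weight_p) + mvn_logdens_rows(Y, mu, Sigma)
  }
  out
}

#' Mixture log-likelihood
#'
#' The working log-likelihood of the model: the sum over genes of the log
#' mixture density with component covariance from
#' [component_covariance()]. Because the cluster-shared effect makes genes
#' within a cluster marginally dependent, this gene-wise sum is the
#' EMMIX-WIRE working objective rather than an exact joint likelihood; it is
#' the quantity traced and reported as "log-likelihood" throughout the
#' package.
#'
#' @param model A [mixture_model()].
#' @param data A [time_course_matrix()].
#' @return A scalar.
#' @export
mixture_loglik <- function(model, data) {
  check_model_data(model, data)
  lp <- component_logdens(model, data)
  sum(log_row_sum_exp(lp))
}

#' Posterior membership probabilities
#'
#' Computes `tau[j, h] = p_h phi_h(y_j) / sum_l p_l phi_l(y_j)` with
#' log-sum-exp stabilization; rows sum to 1.
#'
#' @inheritParams mixture_loglik
#' @return An `n x g` matrix.
#' @export
posterior_probs <- function(model, data) {
  check_model_data(model, data)
  lp <- component_logdens(model, data)
  lse <- log_row_sum_exp(lp)
  exp(lp - lse)
}

log_row_sum_exp <- function(lp) {
  mx <- lp[, 1L]
  if (ncol(lp) > 1L) {
    for (h in 2:ncol(lp)) mx <- pmax(mx, lp[, h])
  }
  mx + log(rowSums(exp(lp - mx)))
}

check_model_data <- function(model, data) {
  stopifnot(inherits(model, "tc_model"), inherits(data, "tc_matrix"))
  if (length(model$design$times) != length(data$times)) {
    stop("model design has ", length(model$design$times),
         " time points but data has ", length(data$times), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read model parameters as structured text
#'
#' One record per component (weight, beta, theta2, rho, sigma2, d2, period),
#' numbers printed with 17 significant digits so the round trip is
#' bit-exact.
#'
#' @param model A [mixture_model()].
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   a `tc_model`.
#' @export
write_model <- function(model, path) {
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  lines <- c(
    paste0("variance_structure\t", model$variance_structure),
    paste0("design_kind\t", model$design$kind),
    paste0("order_k\t", model$design$order_k),
    paste0("spline_df\t", if (is.null(model$design$spline_df)) "NA" else model$design$spline_df),
    paste0("times\t", paste(fmt(model$design$times), collapse = ",")),
    paste0("g\t", model$g))
  for (h in seq_len(model$g)) {
    cp <- model$components[[h]]
    lines <- c(lines, paste0(
      "component\t", h,
      "\tweight=", fmt(cp$weight_p),
      "\tbeta=", paste(fmt(cp$beta), collapse = ","),
      "\ttheta2=", fmt(cp$theta2),
      "\trho=", fmt(cp$rho),
      "\tsigma2=", fmt(cp$sigma2),
      "\td2=", fmt(cp$d2),
      "\tperiod=", if (is.null(cp$period_omega)) "NA" else fmt(cp$period_omega)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t")
  field <- function(name) {
    hit <- which(vapply(kv, `[[`, character(1), 1L) == name)[1]
    kv[[hit]][-1L]
  }
  vs <- field("variance_structure")
  kind <- field("design_kind")
  order_k <- as.integer(field("order_k"))
  sdf <- field("spline_df")
  spline_df <- if (identical(sdf, "NA")) NULL else as.integer(sdf)
  times <- as.numeric(strsplit(field("times"), ",")[[1]])
  comp_lines <- kv[vapply(kv, `[[`, character(1), 1L) == "component"]
  comps <- lapply(comp_lines, function(fields) {
    vals <- fields[-1L]
    get <- function(key) {
      hit <- grep(paste0("^", key, "="), vals, value = TRUE)[1]
      sub(paste0("^", key, "="), "", hit)
    }
    period <- get("period")
    component_params(
      weight_p = as.numeric(get("weight")),
      beta = as.numeric(strsplit(get("beta"), ",")[[1]]),
      theta2 = as.numeric(get("theta2")),
      rho = as.numeric(get("rho")),
      sigma2 = as.numeric(get("sigma2")),
      d2 = as.numeric(get("d2")),
      period_omega = if (identical(period, "NA")) NULL else as.numeric(period))
  })
  periods <- vapply(comps, function(cp) {
    if (is.null(cp$period_omega)) NA_real_ else cp$period_omega
  }, numeric(1))
  design <- design_spec(kind, times, order_k = order_k,
                        periods = if (kind == "fourier") periods else NULL,
                        spline_df = spline_df)
  mixture_model(comps, design, variance_structure = vs)
}
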