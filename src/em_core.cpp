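// Compiled inner loop of the EM algorithm for the AR(1) random-effects
// mixture. Mirrors the reference R implementation (e_step / m_step /
// full_em_run) exactly; the R path remains the documented API and the
// two are compared in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double VAR_FLOOR = 1e-10;
static const double RHO_BOUND = 1.0 - 1e-6;

// scaled AR(1) covariance: A(i,j) = rho^|i-j| / (1 - rho^2)
static mat ar1_cov(double rho, int m) {
  mat A(m, m);
  double s = 1.0 / (1.0 - rho * rho);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j <= i; ++j) {
      double v = std::pow(rho, i - j) * s;
      A(i, j) = v;
      A(j, i) = v;
    }
  }
  return A;
}

// profiled expected u-block objective in rho (to maximize)
static double profile_obj(double rho, double tr_S, double off_S, double cor_S,
                          double m, double t_sum) {
  double tr_AinvS = (1.0 + rho * rho) * tr_S - rho * off_S - rho * rho * cor_S;
  return -(m * std::log(tr_AinvS / (m * t_sum)) - std::log(1.0 - rho * rho));
}

// golden-section maximization on [-RHO_BOUND, RHO_BOUND]
static double golden_max(double tr_S, double off_S, double cor_S,
                         double m, double t_sum) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = -RHO_BOUND, b = RHO_BOUND;
  double c = b - gr * (b - a);
  double d = a + gr * (b - a);
  double fc = profile_obj(c, tr_S, off_S, cor_S, m, t_sum);
  double fd = profile_obj(d, tr_S, off_S, cor_S, m, t_sum);
  while (b - a > 1e-9) {
    if (fc > fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = profile_obj(c, tr_S, off_S, cor_S, m, t_sum);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = profile_obj(d, tr_S, off_S, cor_S, m, t_sum);
    }
  }
  return 0.5 * (a + b);
}

// [[Rcpp::export(name = ".em_ar1_core")]]
Rcpp::List em_ar1_core(const arma::mat& Yt,          // m x n profiles
                       const Rcpp::List& Xs,         // per-component m x p designs
                       arma::vec weight, arma::mat beta,  // p x g
                       arma::vec theta2, arma::vec rho,
                       arma::vec sigma2, arma::vec d2,
                       double tol, int max_iter) {
  const int m = Yt.n_rows;
  const int n = Yt.n_cols;
  const int g = weight.n_elem;
  const int p = beta.n_rows;
  const double cst = m * std::log(2.0 * M_PI);

  std::vector<mat> X(g), XtXinv(g);
  for (int h = 0; h < g; ++h) {
    X[h] = Rcpp::as<mat>(Xs[h]);
    XtXinv[h] = inv_sympd(X[h].t() * X[h]);
  }

  mat V(m, g, fill::zeros);
  bool have_V = false;
  double pen = 0.0;
  std::vector<double> trace_vec;
  trace_vec.reserve(max_iter);

  const int npar = g * (1 + p + 4);
  vec old_par(npar), new_par(npar);
  auto pack = [&](vec& out) {
    int k = 0;
    for (int h = 0; h < g; ++h) {
      out(k++) = weight(h);
      for (int j = 0; j < p; ++j) out(k++) = beta(j, h);
      out(k++) = theta2(h);
      out(k++) = rho(h);
      out(k++) = sigma2(h);
      out(k++) = d2(h);
    }
  };
  pack(old_par);

  bool converged = false;
  int iter = 0;
  mat lp(n, g), tau(n, g);
  mat Vnew(m, g);

  while (iter < max_iter) {
    ++iter;

    // ---- E-step pass 1: responsibilities --------------------------------
    std::vector<mat> R0(g), SuO_inv(g), B(g);
    std::vector<double> s2v(g);
    for (int h = 0; h < g; ++h) {
      vec mu = X[h] * beta.col(h);
      R0[h] = Yt;
      R0[h].each_col() -= mu;
      double th2 = theta2(h);
      double s2 = std::max(sigma2(h), VAR_FLOOR);
      s2v[h] = s2;
      mat SuO;
      mat A;
      bool has_ar = th2 > VAR_FLOOR;
      if (has_ar) {
        A = ar1_cov(rho(h), m);
        SuO = th2 * A;
        SuO.diag() += s2;
      } else {
        SuO = mat(m, m, fill::zeros);
        SuO.diag() += s2;
      }
      mat L = chol(SuO);   // upper triangular
      SuO_inv[h] = inv_sympd(SuO);
      if (has_ar) {
        B[h] = th2 * (A * SuO_inv[h]);
        B[h] = 0.5 * (B[h] + B[h].t());
      } else {
        B[h] = mat(m, m, fill::zeros);
      }
      double logdet = 2.0 * accu(log(L.diag()));
      if (!have_V) {
        mat Sm = SuO;
        Sm.diag() += d2(h);
        mat Lm = chol(Sm);
        mat Z = solve(trimatl(Lm.t()), R0[h]);
        lp.col(h) = std::log(weight(h)) -
          0.5 * (cst + 2.0 * accu(log(Lm.diag())) + sum(Z % Z, 0).t());
      } else {
        mat Rp = R0[h];
        Rp.each_col() -= V.col(h);
        lp.col(h) = std::log(weight(h)) -
          0.5 * (cst + logdet + sum((SuO_inv[h] * Rp) % Rp, 0).t());
      }
    }
    vec mx = max(lp, 1);
    mat el = exp(lp.each_col() - mx);
    vec rs = sum(el, 1);
    tau = el.each_col() / rs;
    double objective = accu(mx + log(rs));
    if (!std::isfinite(objective)) {
      Rcpp::stop("non-finite objective at iteration %d", iter);
    }
    if (have_V) trace_vec.push_back(objective + pen);

    // ---- E-step pass 2 + M-step per component ---------------------------
    for (int h = 0; h < g; ++h) {
      vec tau_h = tau.col(h);
      double t_sum = accu(tau_h);
      if (t_sum < 1e-8) {
        Rcpp::stop("component %d has vanishing responsibility mass (sum tau = %g)",
                   h + 1, t_sum);
      }
      vec v_hat(m, fill::zeros);
      mat V_v(m, m, fill::zeros);
      if (d2(h) > VAR_FLOOR) {
        mat P = t_sum * SuO_inv[h];
        P.diag() += 1.0 / d2(h);
        V_v = inv_sympd(P);
        v_hat = V_v * (SuO_inv[h] * (R0[h] * tau_h));
      }
      mat Rv = R0[h];
      Rv.each_col() -= v_hat;
      mat U = B[h] * Rv;
      mat ImB = -B[h];
      ImB.diag() += 1.0;
      mat u_var = s2v[h] * B[h] + B[h] * V_v * B[h];
      u_var = 0.5 * (u_var + u_var.t());
      mat Uw = U.each_row() % tau_h.t();
      mat S = Uw * U.t() + t_sum * u_var;
      S = 0.5 * (S + S.t());
      double var_uv_tr = s2v[h] * trace(B[h]) + trace(ImB * V_v * ImB);
      mat E = Rv - U;
      Vnew.col(h) = v_hat;

      // M-step
      vec mu = X[h] * beta.col(h);
      weight(h) = t_sum / n;
      vec ybar_adj = mu + (E * tau_h) / t_sum;
      vec beta_new = XtXinv[h] * (X[h].t() * ybar_adj);
      vec mu_new = X[h] * beta_new;
      mat E_new = E;
      E_new.each_col() += (mu - mu_new);
      double resid_q = dot(tau_h, sum(E_new % E_new, 0).t());
      double sigma2_new = (resid_q + t_sum * var_uv_tr) / (m * t_sum);

      double tr_S = trace(S);
      double rho_new = 0.0, theta2_new = 0.0;
      if (tr_S >= 1e-300) {
        double off_S = 0.0;
        for (int i = 0; i + 1 < m; ++i) off_S += S(i, i + 1);
        off_S *= 2.0;
        double cor_S = S(0, 0) + S(m - 1, m - 1);
        rho_new = golden_max(tr_S, off_S, cor_S, (double) m, t_sum);
        double tr_AinvS = (1.0 + rho_new * rho_new) * tr_S -
          rho_new * off_S - rho_new * rho_new * cor_S;
        theta2_new = tr_AinvS / (m * t_sum);
      }
      double d2_new = (dot(v_hat, v_hat) + trace(V_v)) / m;

      beta.col(h) = beta_new;
      theta2(h) = std::max(theta2_new, 0.0);
      rho(h) = rho_new;
      sigma2(h) = std::max(sigma2_new, 0.0);
      d2(h) = std::max(d2_new, 0.0);
    }
    V = Vnew;
    have_V = true;

    // penalized objective bookkeeping: log-density of v_hat under N(0, d2 I)
    pen = 0.0;
    for (int h = 0; h < g; ++h) {
      if (d2(h) > VAR_FLOOR) {
        pen += -0.5 * (m * std::log(2.0 * M_PI * d2(h)) +
                       dot(V.col(h), V.col(h)) / d2(h));
      }
    }

    pack(new_par);
    double rc = 0.0;
    for (int k = 0; k < npar; ++k) {
      double r = std::abs(new_par(k) - old_par(k)) /
        (std::abs(old_par(k)) + 1e-12);
      if (r > rc) rc = r;
    }
    if (rc < tol) {
      converged = true;
      break;
    }
    old_par = new_par;
  }

  return Rcpp::List::create(
    Rcpp::Named("weight") = weight,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("theta2") = theta2,
    Rcpp::Named("rho") = rho,
    Rcpp::Named("sigma2") = sigma2,
    Rcpp::Named("d2") = d2,
    Rcpp::Named("V") = V.t(),          // g x m, as the R loop keeps it
    Rcpp::Named("trace") = trace_vec,
    Rcpp::Named("n_iter") = iter,
    Rcpp::Named("converged") = converged);
}
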