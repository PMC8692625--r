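// Kalman filter, RTS fixed-interval smoother and EM sufficient statistics
// for the linear-Gaussian state-space model
//   x_t = A x_{t-1} + w_t,  w ~ N(0, Q)
//   y_t = C x_t + v_t,      v ~ N(0, R), R diagonal
// Rows of Y containing any non-finite value are treated as missing: the
// correction step is skipped and the row is excluded from the observation
// sufficient statistics.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List kalman_estep_cpp(const arma::mat& Y, const arma::mat& A,
                            const arma::mat& C, const arma::mat& Q,
                            const arma::vec& rdiag, const arma::vec& mu0,
                            const arma::mat& P0, bool suffstats) {
  const uword T = Y.n_rows, p = Y.n_cols, k = A.n_rows;
  const mat R = diagmat(rdiag);
  const mat Ik = eye(k, k);

  mat xf(k, T), xp(k, T);
  cube Pf(k, k, T), Pp(k, k, T);
  uvec obs(T);
  double loglik = 0.0;
  const double l2pi = std::log(2.0 * M_PI);

  vec x = mu0;
  mat P = P0;
  for (uword t = 0; t < T; ++t) {
    if (t > 0) {
      x = A * x;
      P = A * P * A.t() + Q;
      P = 0.5 * (P + P.t());
    }
    xp.col(t) = x;
    Pp.slice(t) = P;
    rowvec yr = Y.row(t);
    bool have = yr.is_finite();
    obs(t) = have ? 1 : 0;
    if (have) {
      vec y = yr.t();
      vec e = y - C * x;
      mat S = C * P * C.t() + R;
      S = 0.5 * (S + S.t());
      mat Sc;
      if (!chol(Sc, S))
        Rcpp::stop("innovation covariance singular at t = %d", (int)(t + 1));
      double logdet = 2.0 * sum(log(Sc.diag()));
      vec z = solve(trimatl(Sc.t()), e);
      loglik += -0.5 * (p * l2pi + logdet + dot(z, z));
      mat K = P * C.t() * inv_sympd(S);
      x = x + K * e;
      P = (Ik - K * C) * P;
      P = 0.5 * (P + P.t());
    }
    xf.col(t) = x;
    Pf.slice(t) = P;
  }

  // RTS smoother
  mat xs(k, T);
  cube Ps(k, k, T);
  xs.col(T - 1) = xf.col(T - 1);
  Ps.slice(T - 1) = Pf.slice(T - 1);
  mat S10(k, k, fill::zeros), S00(k, k, fill::zeros), S11(k, k, fill::zeros);
  for (uword t = T - 1; t-- > 0;) {
    mat J = Pf.slice(t) * A.t() * inv_sympd(Pp.slice(t + 1) +
                                            1e-12 * eye(k, k));
    xs.col(t) = xf.col(t) + J * (xs.col(t + 1) - xp.col(t + 1));
    mat Pst = Pf.slice(t) + J * (Ps.slice(t + 1) - Pp.slice(t + 1)) * J.t();
    Ps.slice(t) = 0.5 * (Pst + Pst.t());
    if (suffstats) {
      // Cov(x_{t+1}, x_t | Y) = Ps_{t+1} J_t'
      mat Ct = Ps.slice(t + 1) * J.t();
      S10 += Ct + xs.col(t + 1) * xs.col(t).t();
      S00 += Ps.slice(t) + xs.col(t) * xs.col(t).t();
      S11 += Ps.slice(t + 1) + xs.col(t + 1) * xs.col(t + 1).t();
    }
  }

  mat xs_t = xs.t(); // T x k
  mat ps_var(T, k);
  for (uword t = 0; t < T; ++t) ps_var.row(t) = Ps.slice(t).diag().t();

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = loglik, Rcpp::Named("xs") = xs_t,
      Rcpp::Named("ps_var") = ps_var,
      Rcpp::Named("P1s") = Ps.slice(0), Rcpp::Named("x1s") = xs.col(0));
  if (suffstats) {
    mat Sxx(k, k, fill::zeros), Syx(p, k, fill::zeros);
    vec syy(p, fill::zeros);
    uword nobs = 0;
    for (uword t = 0; t < T; ++t) {
      if (!obs(t)) continue;
      ++nobs;
      Sxx += Ps.slice(t) + xs.col(t) * xs.col(t).t();
      Syx += Y.row(t).t() * xs.col(t).t();
      syy += square(Y.row(t).t());
    }
    out["S00"] = S00;
    out["S10"] = S10;
    out["S11"] = S11;
    out["Sxx"] = Sxx;
    out["Syx"] = Syx;
    out["syy"] = syy;
    out["nobs"] = (double)nobs;
  }
  return out;
}
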