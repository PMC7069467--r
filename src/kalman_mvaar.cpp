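// Kalman-filter estimation of a time-varying MVAR model.
//
// State: the vectorized coefficient matrices [A_1(t) ... A_p(t)] evolving as
// a random walk with process noise Q = uc * I. Observation at time t:
//   y(t) = A(t)' phi(t) + e(t),  phi(t) = [y(t-1); ...; y(t-p)]
// In "scalar" noise mode the observation noise is r * I and all sink
// channels share one state covariance P (exact decoupling of the vectorized
// state); in "diagonal" mode each sink channel carries its own P and r.
// An optional fixed-interval (RTS) smoothing pass refines the coefficient
// means using the whole trial (scalar mode only).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List kalman_mvaar_cpp(const arma::mat& y, int p, double uc,
                            double state_cov0, double obs_noise0,
                            bool smooth, std::string noise_mode) {
  const int n = y.n_rows;
  const int T = y.n_cols;
  const int d = n * p;
  if (T <= p) Rcpp::stop("trial must have more samples than the model order");

  cube W_all(d, n, T, fill::zeros);   // state per time step (post-update)
  vec r_trace(T, fill::zeros);
  mat resid_acc(n, n, fill::zeros);
  int n_resid = 0;

  double r0 = obs_noise0;
  if (r0 <= 0.0) {
    r0 = as_scalar(mean(var(y, 0, 1)));
    if (!(r0 > 0.0)) r0 = 1.0;
  }

  const bool scalar_mode = (noise_mode == "scalar");

  if (scalar_mode) {
    mat W(d, n, fill::zeros);
    mat P = state_cov0 * eye(d, d);
    double r = r0;
    cube Pf;
    if (smooth) Pf.set_size(d, d, T);

    vec phi(d), v(d), kg(d);
    rowvec e(n);
    for (int t = p; t < T; ++t) {
      for (int k = 0; k < p; ++k) phi.subvec(k * n, k * n + n - 1) = y.col(t - 1 - k);
      P.diag() += uc;                       // predict (random walk)
      v = P * phi;
      double s = dot(phi, v) + r;
      kg = v / s;
      e = y.col(t).t() - phi.t() * W;
      W += kg * e;
      P -= kg * v.t();
      if ((t & 63) == 0) P = 0.5 * (P + P.t());  // re-symmetrize periodically
      r = (1.0 - uc) * r + uc * as_scalar(mean(square(e), 1));
      W_all.slice(t) = W;
      r_trace(t) = r;
      resid_acc += e.t() * e;
      ++n_resid;
      if (smooth) Pf.slice(t) = P;
    }
    if (smooth) {
      // RTS backward pass for the mean: G_t = P_t (P_t + Q)^{-1}
      mat Ws_next = W_all.slice(T - 1);
      for (int t = T - 2; t >= p; --t) {
        mat Ppred = Pf.slice(t);
        Ppred.diag() += uc;
        mat G = solve(Ppred, Pf.slice(t), solve_opts::likely_sympd).t();
        mat Ws = W_all.slice(t) + G * (Ws_next - W_all.slice(t));
        W_all.slice(t) = Ws;
        Ws_next = Ws;
      }
    }
  } else {
    // diagonal observation noise: independent filter per sink channel
    std::vector<mat> P(n, state_cov0 * eye(d, d));
    vec r(n, fill::value(r0));
    mat W(d, n, fill::zeros);
    vec phi(d);
    for (int t = p; t < T; ++t) {
      for (int k = 0; k < p; ++k) phi.subvec(k * n, k * n + n - 1) = y.col(t - 1 - k);
      rowvec e(n);
      for (int i = 0; i < n; ++i) {
        P[i].diag() += uc;
        vec v = P[i] * phi;
        double s = dot(phi, v) + r(i);
        vec kg = v / s;
        double ei = y(i, t) - dot(phi, W.col(i));
        W.col(i) += kg * ei;
        P[i] -= kg * v.t();
        P[i] = 0.5 * (P[i] + P[i].t());
        r(i) = (1.0 - uc) * r(i) + uc * ei * ei;
        e(i) = ei;
      }
      W_all.slice(t) = W;
      r_trace(t) = as_scalar(mean(r));
      resid_acc += e.t() * e;
      ++n_resid;
    }
  }

  // back-fill t <= p with the first estimate so time grids stay aligned
  for (int t = 0; t < p; ++t) W_all.slice(t) = W_all.slice(p);
  for (int t = 0; t < p; ++t) r_trace(t) = r_trace(p);

  // coefficients as cube (n x n*p x T): row i = sink, col (k*n + j) = A_k[i,j]
  cube coef(n, d, T);
  for (int t = 0; t < T; ++t) coef.slice(t) = W_all.slice(t).t();

  return Rcpp::List::create(
    Rcpp::Named("coeffs") = coef,
    Rcpp::Named("obs_noise") = r_trace,
    Rcpp::Named("residual_cov") = resid_acc / std::max(1, n_resid)
  );
}
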