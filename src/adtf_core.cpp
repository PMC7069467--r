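// Band-integrated adaptive directed transfer function from time-varying MVAR
// coefficients.
//
// For each retained time point t and frequency f:
//   Abar(f,t) = I - sum_k A_k(t) exp(-i 2 pi f k / rate)
//   H(f,t)    = Abar(f,t)^{-1}
// Band integration (ratio of sums, preserves per-sink normalization):
//   theta2_ij(t) = sum_f |H_ij(f,t)|^2 / sum_f sum_m |H_im(f,t)|^2
//
// For order-1 models the inverse is evaluated through the eigendecomposition
// of A(t): H(f) = V diag(1/(1 - lambda e^{-iw})) V^{-1}, one decomposition
// per time point instead of one LU factorization per (t, f). Falls back to
// direct solves when A is ill-conditioned for eigenvector inversion.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static bool adtf_direct_point(const mat& A, int n, int p, double w,
                              double ridge, mat& S, int& n_regularized) {
  cx_mat Abar(n, n, fill::zeros);
  Abar.diag() += std::complex<double>(1.0, 0.0);
  for (int k = 0; k < p; ++k) {
    std::complex<double> ph(std::cos(-w * (k + 1)), std::sin(-w * (k + 1)));
    Abar -= ph * conv_to<cx_mat>::from(A.cols(k * n, k * n + n - 1));
  }
  cx_mat H;
  bool ok = inv(H, Abar);
  if (!ok || !H.is_finite()) {
    Abar.diag() += ridge;
    H = inv(Abar);
    ++n_regularized;
  }
  S += square(abs(H));
  return true;
}

// [[Rcpp::export]]
Rcpp::List adtf_band_cpp(const arma::cube& coeffs, const arma::uvec& time_idx,
                         const arma::vec& freqs_hz, double rate, double ridge) {
  const int n = coeffs.n_rows;
  const int d = coeffs.n_cols;
  const int p = d / n;
  const int nt = time_idx.n_elem;
  const int nf = freqs_hz.n_elem;

  cube theta(n, n, nt, fill::zeros);
  int n_regularized = 0;
  int n_zero_rows = 0;

  vec wgrid(nf);
  for (int fi = 0; fi < nf; ++fi) wgrid(fi) = 2.0 * datum::pi * freqs_hz(fi) / rate;

  for (int ti = 0; ti < nt; ++ti) {
    const mat& A = coeffs.slice(time_idx(ti));
    mat S(n, n, fill::zeros);

    bool eig_done = false;
    if (p == 1) {
      cx_vec lam;
      cx_mat V;
      if (eig_gen(lam, V, A)) {
        cx_mat Vi;
        if (inv(Vi, V) && Vi.is_finite()) {
          cx_mat scaled(n, n);
          for (int fi = 0; fi < nf; ++fi) {
            std::complex<double> z(std::cos(-wgrid(fi)), std::sin(-wgrid(fi)));
            cx_vec g = 1.0 / (1.0 - lam * z);
            if (!g.is_finite()) { ++n_regularized; g = 1.0 / (1.0 - lam * z + ridge); }
            // H = V diag(g) Vi
            for (int c = 0; c < n; ++c) scaled.col(c) = V.col(c) * g(c);
            cx_mat H = scaled * Vi;
            S += square(abs(H));
          }
          eig_done = true;
        }
      }
    }
    if (!eig_done) {
      for (int fi = 0; fi < nf; ++fi) {
        adtf_direct_point(A, n, p, wgrid(fi), ridge, S, n_regularized);
      }
    }

    vec rs = sum(S, 1);
    for (int i = 0; i < n; ++i) {
      if (rs(i) > 0.0) {
        theta.slice(ti).row(i) = S.row(i) / rs(i);
      } else {
        theta.slice(ti).row(i).fill(1.0 / n);
        ++n_zero_rows;
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("theta") = theta,
    Rcpp::Named("n_regularized") = n_regularized,
    Rcpp::Named("n_zero_rows") = n_zero_rows
  );
}
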