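// Wilson's iterative spectral matrix factorization: S(f) = H(f) Sigma H*(f)
// with H causal and minimum-phase, the workhorse of non-parametric Granger
// causality. Operates on a one-sided cross-spectral density sampled on an
// nfft-point circle.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// stack a cube (n x n x nfft) into a matrix (nfft x n*n) for columnwise FFT
static cx_mat cube_to_mat(const cx_cube& C) {
  const uword n = C.n_rows, nf = C.n_slices;
  cx_mat M(nf, n * n);
  for (uword s = 0; s < nf; ++s)
    M.row(s) = vectorise(C.slice(s)).st();
  return M;
}

static cx_cube mat_to_cube(const cx_mat& M, uword n) {
  const uword nf = M.n_rows;
  cx_cube C(n, n, nf);
  for (uword s = 0; s < nf; ++s)
    C.slice(s) = reshape(M.row(s).st(), n, n);
  return C;
}

// causal-part operator [g]_+ : zero negative lags, split lag 0 so that
// beta0 + beta0^H equals the lag-0 term (upper-triangular convention)
static cx_cube plus_operator(const cx_cube& g) {
  const uword n = g.n_rows, nfft = g.n_slices, half = nfft / 2;
  cx_mat G = cube_to_mat(g);
  cx_mat gam = ifft(G);
  cx_mat b0 = reshape(gam.row(0).st(), n, n);
  cx_mat beta0(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    beta0(i, i) = 0.5 * b0(i, i);
    for (uword j = i + 1; j < n; ++j) beta0(i, j) = b0(i, j);
  }
  gam.row(0) = vectorise(beta0).st();
  gam.row(half) *= 0.5;   // self-conjugate Nyquist lag: split evenly
  for (uword l = half + 1; l < nfft; ++l) gam.row(l).zeros();
  return mat_to_cube(fft(gam), n);
}

// [[Rcpp::export]]
Rcpp::List wilson_cpp(const arma::cx_cube& S1s, int nfft, double tol,
                      int maxiter) {
  const uword n = S1s.n_rows, nf = S1s.n_slices;
  if ((uword)nfft / 2 + 1 != nf)
    Rcpp::stop("one-sided spectrum must have nfft/2 + 1 frequencies");

  // two-sided extension: S(-f) = conj(S(f)) for a Hermitian CSD
  cx_cube S(n, n, (uword)nfft);
  for (uword m = 0; m < nf; ++m) S.slice(m) = S1s.slice(m);
  for (uword m = 1; m + 1 < nf; ++m) S.slice(nfft - m) = conj(S1s.slice(m));

  // init: psi(f) = chol(gamma0) from the lag-0 covariance
  cx_mat Smat = cube_to_mat(S);
  cx_mat Sifft = ifft(Smat);
  mat gam0 = real(reshape(Sifft.row(0).st(), n, n));
  gam0 = 0.5 * (gam0 + gam0.t());
  if (rcond(gam0) < 1e-10)
    Rcpp::stop("rank-deficient spectrum: lag-0 covariance not positive definite");
  mat R;
  if (!chol(R, gam0))
    Rcpp::stop("lag-0 covariance not positive definite");
  cx_cube psi(n, n, (uword)nfft);
  for (uword f = 0; f < (uword)nfft; ++f)
    psi.slice(f) = conv_to<cx_mat>::from(R);

  const cx_mat I = cx_mat(eye(n, n), mat(n, n, fill::zeros));
  double err = datum::inf;
  int it = 0;
  for (it = 0; it < maxiter; ++it) {
    cx_cube g(n, n, (uword)nfft);
    for (uword f = 0; f < (uword)nfft; ++f) {
      // analytic tiny-matrix inverse path is much faster than LAPACK
      // solves at the 2-11 channel sizes used here
      cx_mat P = inv(psi.slice(f));
      g.slice(f) = P * S.slice(f) * P.t() + I;
    }
    cx_cube gp = plus_operator(g);
    double num = 0, den = 0;
    cx_cube psin(n, n, (uword)nfft);
    for (uword f = 0; f < (uword)nfft; ++f) {
      psin.slice(f) = psi.slice(f) * gp.slice(f);
      num += std::pow(norm(psin.slice(f) - psi.slice(f), "fro"), 2);
      den += std::pow(norm(psi.slice(f), "fro"), 2);
    }
    psi = psin;
    err = std::sqrt(num / den);
    if (err < tol) { ++it; break; }
  }

  // A0 = causal lag-0 coefficient; Sigma = A0 A0^T; H = psi inv(A0)
  cx_mat psiIfft = ifft(cube_to_mat(psi));
  mat A0 = real(reshape(psiIfft.row(0).st(), n, n));
  mat Sigma = A0 * A0.t();
  cx_mat A0c = conv_to<cx_mat>::from(A0);
  cx_cube H(n, n, nf);
  const cx_mat A0inv = inv(A0c);
  double resid = 0;
  for (uword f = 0; f < nf; ++f) {
    H.slice(f) = psi.slice(f) * A0inv;
    cx_mat rec = H.slice(f) * conv_to<cx_mat>::from(Sigma) * H.slice(f).t();
    double d = norm(rec - S1s.slice(f), "fro") /
      std::max(norm(S1s.slice(f), "fro"), 1e-300);
    if (d > resid) resid = d;
  }

  return Rcpp::List::create(
    Rcpp::Named("H") = H, Rcpp::Named("Sigma") = Sigma,
    Rcpp::Named("iterations") = it, Rcpp::Named("relchange") = err,
    Rcpp::Named("residual") = resid);
}

// Multitaper CSD core: ens is (N x ntrials x nch) binned counts already
// mean-subtracted; tapers is (N x K). Returns one-sided CSD cube.
// [[Rcpp::export]]
arma::cx_cube csd_cpp(const arma::cube& ens, const arma::mat& tapers,
                      int nfft, double fs) {
  const uword N = ens.n_rows, ntr = ens.n_cols, nch = ens.n_slices;
  const uword K = tapers.n_cols, nf = (uword)nfft / 2 + 1;
  const uword R = ntr * K;
  // tapered zero-padded FFTs per channel
  std::vector<cx_mat> X(nch);
  for (uword c = 0; c < nch; ++c) {
    mat xt(nfft, R, fill::zeros);
    for (uword k = 0; k < K; ++k)
      xt.submat(0, k * ntr, N - 1, k * ntr + ntr - 1) =
        ens.slice(c).each_col() % tapers.col(k);
    cx_mat Xf = fft(conv_to<cx_mat>::from(xt));
    X[c] = Xf.rows(0, nf - 1);
  }
  const double scl = 1.0 / (fs * (double)R);
  cx_cube S(nch, nch, nf);
  for (uword a = 0; a < nch; ++a)
    for (uword b = a; b < nch; ++b) {
      cx_vec v = sum(X[a] % conj(X[b]), 1) * scl;
      for (uword f = 0; f < nf; ++f) {
        S(a, b, f) = v(f);
        if (b > a) S(b, a, f) = std::conj(v(f));
      }
    }
  return S;
}

// spectral conditional GC given the two factorizations; posR are 0-based
// positions of the reduced variables (i, k) within the full ordering
// [[Rcpp::export]]
arma::vec cgc_spectral_cpp(const arma::cx_cube& Hfull,
                           const arma::mat& Sfull,
                           const arma::cx_cube& Hred, double s2red) {
  const uword n = Hfull.n_rows, nf = Hfull.n_slices;
  const uword nr = Hred.n_rows;
  mat Pinv = eye(n, n);
  for (uword m = 1; m < n; ++m) Pinv(m, 0) = Sfull(m, 0) / Sfull(0, 0);
  uvec posR(nr);
  posR(0) = 0;
  for (uword t = 1; t < nr; ++t) posR(t) = t + 1;  // skip source at 1
  const double s3 = Sfull(0, 0);
  vec out(nf);
  for (uword f = 0; f < nf; ++f) {
    cx_mat G(n, n, fill::zeros);
    G.diag().ones();
    G.submat(posR, posR) = Hred.slice(f);
    cx_mat Q = inv(G) * Hfull.slice(f) *
      conv_to<cx_mat>::from(Pinv);
    out(f) = std::log(s2red / (std::norm(Q(0, 0)) * s3));
  }
  return out;
}
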