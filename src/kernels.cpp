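// Hot numerical kernels: multitaper eigenspectra over all channels/epochs of
// a session, and zero-phase IIR filtering of a multi-column matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Tapered spectra of every (channel, epoch) column of an epoched EEG array.
//
// arr:    numeric array [channel, epoch, sample]
// chsel:  1-based channel indices to include
// basisC: list of K matrices (bins x samples), cos basis with taper absorbed
// basisS: matching sin bases
// tapers: samples x K DPSS tapers (for the Parseval totals)
//
// Returns list with
//   P:     bins x (nch*nep) sum over tapers of (C x)^2 + (S x)^2
//   total: 1 x (nch*nep) sum over tapers of N * sum_t (v_k x_t)^2
// Columns are ordered channel-fastest. Each column is demeaned first.
// [[Rcpp::export]]
List cpp_tapered_spectra(NumericVector arr, IntegerVector chsel,
                         List basisC, List basisS, NumericMatrix tapers,
                         bool want_total) {
  IntegerVector dims = arr.attr("dim");
  const int nch_all = dims[0], nep = dims[1], nsamp = dims[2];
  const int nch = chsel.size();
  const int K = basisC.size();
  const int M = nch * nep;

  arma::mat X(nsamp, M);
  const double *a = arr.begin();
  for (int e = 0; e < nep; ++e) {
    for (int c = 0; c < nch; ++c) {
      const int ch = chsel[c] - 1;
      double *col = X.colptr(e * nch + c);
      double mean = 0.0;
      const double *base = a + ch + (long)e * nch_all;
      const long stride = (long)nch_all * nep;
      for (int t = 0; t < nsamp; ++t) {
        col[t] = base[t * stride];
        mean += col[t];
      }
      mean /= nsamp;
      for (int t = 0; t < nsamp; ++t) col[t] -= mean;
    }
  }

  arma::mat V = as<arma::mat>(tapers);
  const int nbins = as<arma::mat>(basisC[0]).n_rows;
  arma::mat P(nbins, M, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    arma::mat C = as<arma::mat>(basisC[k]);
    arma::mat S = as<arma::mat>(basisS[k]);
    arma::mat G = C * X;
    P += arma::square(G);
    G = S * X;
    P += arma::square(G);
  }
  arma::rowvec total(M, arma::fill::zeros);
  if (want_total) {
    arma::mat TT = arma::square(V).t() * arma::square(X);
    total = (double)nsamp * arma::sum(TT, 0);
  }
  return List::create(_["P"] = P, _["total"] = total);
}

// Same spectra for data already arranged as a samples x columns matrix.
// [[Rcpp::export]]
List cpp_tapered_spectra_mat(NumericMatrix Xin, List basisC, List basisS,
                             NumericMatrix tapers, bool want_total) {
  arma::mat X = as<arma::mat>(Xin);
  const int nsamp = X.n_rows;
  const int K = basisC.size();
  X.each_row() -= arma::mean(X, 0);
  arma::mat V = as<arma::mat>(tapers);
  const int nbins = as<arma::mat>(basisC[0]).n_rows;
  arma::mat P(nbins, X.n_cols, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    arma::mat C = as<arma::mat>(basisC[k]);
    arma::mat S = as<arma::mat>(basisS[k]);
    arma::mat G = C * X;
    P += arma::square(G);
    G = S * X;
    P += arma::square(G);
  }
  arma::rowvec total(X.n_cols, arma::fill::zeros);
  if (want_total) {
    arma::mat TT = arma::square(V).t() * arma::square(X);
    total = (double)nsamp * arma::sum(TT, 0);
  }
  return List::create(_["P"] = P, _["total"] = total);
}

// Mix iid innovations Z (n x p) through the per-row Cholesky factor of a
// correlation matrix that equals R0 except at the target pairs (ia, ib;
// 1-based), where row t uses rho(t, pair). Indefinite matrices fall back to
// eigenvalue clipping with diagonal renormalization.
// [[Rcpp::export]]
NumericMatrix cpp_tv_chol_mix(NumericMatrix R0in, IntegerVector ia,
                              IntegerVector ib, NumericMatrix rho,
                              NumericMatrix Zin) {
  arma::mat R0 = as<arma::mat>(R0in);
  arma::mat Z = as<arma::mat>(Zin);
  const int n = Z.n_rows, p = Z.n_cols, np = ia.size();
  arma::mat Y(n, p);
  arma::mat R(p, p), U;
  for (int t = 0; t < n; ++t) {
    R = R0;
    for (int q = 0; q < np; ++q) {
      R(ia[q] - 1, ib[q] - 1) = rho(t, q);
      R(ib[q] - 1, ia[q] - 1) = rho(t, q);
    }
    if (!arma::chol(U, R)) {
      arma::vec lam;
      arma::mat E;
      arma::eig_sym(lam, E, R);
      lam.transform([](double x) { return x < 1e-6 ? 1e-6 : x; });
      arma::mat R2 = E * arma::diagmat(lam) * E.t();
      arma::vec d = 1.0 / arma::sqrt(R2.diag());
      R2 = R2 % (d * d.t());
      U = arma::chol(R2);
    }
    Y.row(t) = Z.row(t) * U;
  }
  return wrap(Y);
}

// Synthesize the EEG signal matrix (samples x columns, channel-fastest):
// random-phase 1/f background from the cos/sin bases BC/BS scaled by
// `pink_scale`, plus three sinusoidal rhythms whose per-column amplitudes are
// the rows of AMP (alpha, theta, beta) and whose cos/sin carriers are the
// columns of M1, each with an independent uniform phase per column. Uses the
// R random number stream.
// [[Rcpp::export]]
NumericMatrix cpp_eeg_signal_matrix(NumericMatrix BCin, NumericMatrix BSin,
                                    double pink_scale, NumericMatrix M1in,
                                    NumericMatrix AMPin) {
  arma::mat BC = as<arma::mat>(BCin), BS = as<arma::mat>(BSin);
  arma::mat M1 = as<arma::mat>(M1in), AMP = as<arma::mat>(AMPin);
  const int nh = BC.n_cols;
  const int cols = AMP.n_cols;
  const double s2 = pink_scale * std::sqrt(2.0);
  arma::mat X;
  if (pink_scale > 0) {
    arma::mat Ac(nh, cols), As(nh, cols);
    for (long i = 0; i < (long)nh * cols; ++i) {
      const double phi = 2.0 * M_PI * unif_rand();
      Ac[i] = s2 * std::cos(phi);
      As[i] = s2 * std::sin(phi);
    }
    X = BC * Ac + BS * As;
  } else {
    X.zeros(BC.n_rows, cols);
  }
  arma::mat M2(6, cols);
  for (int r = 0; r < 3; ++r) {
    for (int j = 0; j < cols; ++j) {
      const double phi = 2.0 * M_PI * unif_rand();
      M2(2 * r, j) = AMP(r, j) * std::cos(phi);
      M2(2 * r + 1, j) = AMP(r, j) * std::sin(phi);
    }
  }
  X += M1 * M2;
  return wrap(X);
}

// Reshape a samples x (channel-fastest-by-epoch) matrix into the
// [channel, epoch, sample] array layout of the epoched-EEG container.
// [[Rcpp::export]]
NumericVector cpp_to_epoch_array(NumericMatrix Xin, int nch, int nep) {
  const int n = Xin.nrow(), M = Xin.ncol();
  NumericVector out((long)n * M);
  const double *x = Xin.begin();
  double *o = out.begin();
  for (int j = 0; j < M; ++j) {        // j = (epoch-1)*nch + (channel-1)
    const double *col = x + (long)j * n;
    for (int t = 0; t < n; ++t) o[(long)t * M + j] = col[t];
  }
  out.attr("dim") = IntegerVector::create(nch, nep, n);
  return out;
}

// Direct-form IIR filter applied down every column (zero initial state).
static void iir_inplace(const arma::vec &b, const arma::vec &a, arma::mat &X) {
  const int n = X.n_rows, p = X.n_cols;
  const int nb = b.n_elem, na = a.n_elem;
  arma::vec y(n);
  for (int j = 0; j < p; ++j) {
    double *x = X.colptr(j);
    for (int t = 0; t < n; ++t) {
      double acc = 0.0;
      const int jb = std::min(nb - 1, t);
      for (int i = 0; i <= jb; ++i) acc += b[i] * x[t - i];
      const int ja = std::min(na - 1, t);
      for (int i = 1; i <= ja; ++i) acc -= a[i] * y[t - i];
      y[t] = acc / a[0];
    }
    std::copy(y.begin(), y.end(), x);
  }
}

// Zero-phase (forward-backward) filtering of every column with odd
// reflection padding of `pad` samples at each end.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt(NumericVector b, NumericVector a,
                           NumericMatrix Xin, int pad) {
  arma::vec bb = as<arma::vec>(b), aa = as<arma::vec>(a);
  arma::mat X = as<arma::mat>(Xin);
  const int n = X.n_rows, p = X.n_cols;
  if (pad > n - 1) pad = n - 1;
  arma::mat E(n + 2 * pad, p);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < pad; ++i) {
      E(i, j) = 2.0 * X(0, j) - X(pad - i, j);
      E(n + pad + i, j) = 2.0 * X(n - 1, j) - X(n - 2 - i, j);
    }
    for (int t = 0; t < n; ++t) E(pad + t, j) = X(t, j);
  }
  iir_inplace(bb, aa, E);
  E = arma::flipud(E);
  iir_inplace(bb, aa, E);
  E = arma::flipud(E);
  return wrap(E.rows(pad, pad + n - 1));
}
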