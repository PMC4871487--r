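#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for the lasso on precomputed moments.
//
// Minimizes (1/2n) ||y_c - X w||^2 + lambda ||w||_1 given
//   C = X'X / n  (p x p) and q = X'y_c / n  (p),
// for a decreasing sequence of lambda values with warm starts.
// Convergence: max absolute coefficient change < tol, or max_sweeps sweeps.
// Columns with C[j,j] == 0 (zero variance) keep w_j = 0.
// [[Rcpp::export]]
List cd_lasso_cov(const NumericMatrix& C, const NumericVector& q,
                  const NumericVector& lambda_seq, double tol = 1e-8,
                  int max_sweeps = 100000, Nullable<NumericVector> warm = R_NilValue) {
  const int p = q.size();
  const int nl = lambda_seq.size();
  NumericMatrix beta(p, nl);
  NumericVector w(p);
  if (warm.isNotNull()) {
    NumericVector w0(warm);
    if (w0.size() != p) stop("warm start has wrong length");
    for (int j = 0; j < p; ++j) w[j] = w0[j];
  }
  // grad[j] = q[j] - (C w)[j], maintained incrementally
  NumericVector grad(p);
  for (int j = 0; j < p; ++j) {
    double s = q[j];
    for (int k = 0; k < p; ++k) s -= C(j, k) * w[k];
    grad[j] = s;
  }
  IntegerVector sweeps_used(nl);
  LogicalVector converged(nl);
  for (int l = 0; l < nl; ++l) {
    const double lambda = lambda_seq[l];
    int sweep = 0;
    bool conv = false;
    for (; sweep < max_sweeps; ++sweep) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double cjj = C(j, j);
        if (cjj <= 0.0) continue;
        const double z = cjj * w[j] + grad[j];
        const double wj_new = soft_threshold(z, lambda) / cjj;
        const double delta = wj_new - w[j];
        if (delta != 0.0) {
          w[j] = wj_new;
          for (int k = 0; k < p; ++k) grad[k] -= C(k, j) * delta;
          const double ad = std::fabs(delta);
          if (ad > max_delta) max_delta = ad;
        }
      }
      if (max_delta < tol) { conv = true; ++sweep; break; }
    }
    sweeps_used[l] = sweep;
    converged[l] = conv;
    for (int j = 0; j < p; ++j) beta(j, l) = w[j];
  }
  return List::create(_["beta"] = beta, _["sweeps"] = sweeps_used,
                      _["converged"] = converged);
}

// Sliding-window sums of per-position integer motif scores.
//
// seq_codes: 0..3 for A,C,G,T; negative for invalid characters.
// score: 4 x width integer matrix (base x motif position).
// Returns one value per window start (length n - width + 1);
// windows containing an invalid character yield NA.
// [[Rcpp::export]]
IntegerVector window_scores_int(const IntegerVector& seq_codes,
                                const IntegerMatrix& score) {
  const int n = seq_codes.size();
  const int w = score.ncol();
  const int nw = n - w + 1;
  if (nw <= 0) return IntegerVector(0);
  IntegerVector out(nw);
  for (int i = 0; i < nw; ++i) {
    long s = 0;
    bool ok = true;
    for (int k = 0; k < w; ++k) {
      const int b = seq_codes[i + k];
      if (b < 0 || b > 3) { ok = false; break; }
      s += score(b, k);
    }
    out[i] = ok ? (int)s : NA_INTEGER;
  }
  return out;
}
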