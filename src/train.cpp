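#include <Rcpp.h>
using namespace Rcpp;

// Units are rows of the weight matrix in lexicographic (j, k) order:
// 0-based linear index u = j * K + k. Squared distances accumulate in long
// double so BMU decisions agree with R's long-double colSums/rowSums, and
// ties resolve to the first (smallest (j, k)) minimum.
static inline int bmu_of(const NumericMatrix &W, const NumericMatrix &X,
                         int row, int I) {
  const int n = W.nrow();
  const int nx = X.nrow();
  const double *w = W.begin();
  const double *x = X.begin();
  long double best = 0.0L;
  int bu = 0;
  for (int u = 0; u < n; ++u) {
    long double d = 0.0L;
    for (int i = 0; i < I; ++i) {
      const long double diff = (long double)x[row + (R_xlen_t)i * nx] -
                               (long double)w[u + (R_xlen_t)i * n];
      d += diff * diff;
    }
    if (u == 0 || d < best) {
      best = d;
      bu = u;
    }
  }
  return bu;
}

// Online SOM training. All randomness (initial weights, presentation
// orders) is generated on the R side and passed in; this loop is pure
// deterministic arithmetic.
//
// data:   n x I samples
// W0:     (J*K) x I initial weights, linear unit index u = j*K + k (0-based)
// orders: O x n matrix of 1-based sample indices (presentation order/epoch)
// alpha:  length-O learning-rate schedule
// psi:    length-O integer neighborhood-radius schedule (Chebyshev, square)
// [[Rcpp::export(name = ".som_train_cpp")]]
NumericMatrix som_train_cpp(const NumericMatrix &data, const NumericMatrix &W0,
                            int J, int K, const IntegerMatrix &orders,
                            const NumericVector &alpha,
                            const IntegerVector &psi) {
  const int I = data.ncol();
  const int O = orders.nrow();
  const int n = orders.ncol();
  NumericMatrix W = clone(W0);
  for (int t = 0; t < O; ++t) {
    const double a = alpha[t];
    const int r = psi[t];
    for (int s = 0; s < n; ++s) {
      const int row = orders(t, s) - 1;
      const int bu = bmu_of(W, data, row, I);
      const int bj = bu / K, bk = bu % K;
      const int j0 = std::max(0, bj - r), j1 = std::min(J - 1, bj + r);
      const int k0 = std::max(0, bk - r), k1 = std::min(K - 1, bk + r);
      for (int j = j0; j <= j1; ++j) {
        for (int k = k0; k <= k1; ++k) {
          const int u = j * K + k;
          for (int i = 0; i < I; ++i) {
            W(u, i) += a * (data(row, i) - W(u, i));
          }
        }
      }
    }
  }
  return W;
}

// Recurrent SOM training on an ordered sequence (1-D chain of units).
// Activation recursion per unit: y(t) = b1*y(t-1) + b2*y(t-2) + b3*(x - w);
// BMU minimizes ||y(t)||^2. Update within chain radius psi[t] of the BMU:
//   gated: w += g * (x - w) * ||y_u|| / (1 + ||y_u||)
//   som:   w += g * (x - w)
// Histories are reset to zero at the start of each epoch.
// [[Rcpp::export(name = ".rsom_train_cpp")]]
NumericMatrix rsom_train_cpp(const NumericMatrix &seq, const NumericMatrix &W0,
                             double b1, double b2, double b3,
                             const NumericVector &gamma,
                             const IntegerVector &psi, bool gated) {
  const int T = seq.nrow();
  const int I = seq.ncol();
  const int n = W0.nrow();
  const int O = gamma.size();
  NumericMatrix W = clone(W0);
  NumericMatrix y1(n, I), y2(n, I), y(n, I);
  for (int t = 0; t < O; ++t) {
    const double g = gamma[t];
    const int r = psi[t];
    std::fill(y1.begin(), y1.end(), 0.0);
    std::fill(y2.begin(), y2.end(), 0.0);
    for (int s = 0; s < T; ++s) {
      long double best = 0.0L;
      int bu = 0;
      for (int u = 0; u < n; ++u) {
        long double d = 0.0L;
        for (int i = 0; i < I; ++i) {
          const double v =
              b1 * y1(u, i) + b2 * y2(u, i) + b3 * (seq(s, i) - W(u, i));
          y(u, i) = v;
          d += (long double)v * (long double)v;
        }
        if (u == 0 || d < best) {
          best = d;
          bu = u;
        }
      }
      const int u0 = std::max(0, bu - r), u1 = std::min(n - 1, bu + r);
      for (int u = u0; u <= u1; ++u) {
        double gain = g;
        if (gated) {
          double nrm2 = 0.0;
          for (int i = 0; i < I; ++i) nrm2 += y(u, i) * y(u, i);
          const double nrm = std::sqrt(nrm2);
          gain = g * nrm / (1.0 + nrm);
        }
        for (int i = 0; i < I; ++i) {
          W(u, i) += gain * (seq(s, i) - W(u, i));
        }
      }
      // shift activation history
      for (int u = 0; u < n; ++u) {
        for (int i = 0; i < I; ++i) {
          y2(u, i) = y1(u, i);
          y1(u, i) = y(u, i);
        }
      }
    }
  }
  return W;
}

// BMU (0-based linear unit index) of every row of `data`.
// [[Rcpp::export(name = ".bmu_all_cpp")]]
IntegerVector bmu_all_cpp(const NumericMatrix &data, const NumericMatrix &W) {
  const int n = data.nrow();
  const int I = data.ncol();
  IntegerVector out(n);
  for (int s = 0; s < n; ++s) out[s] = bmu_of(W, data, s, I);
  return out;
}
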