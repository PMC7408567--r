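#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian-kernel smoothed empirical CDF, evaluated per gene at each
// sample's own value: z[i,j] = mean_k Phi((x[i,j] - x[i,k]) / h[i]).
// O(p * n^2); the inner loops dominate scoring cost, hence C++.
// [[Rcpp::export(name = ".kcdf_gauss")]]
NumericMatrix kcdf_gauss(NumericMatrix x, NumericVector h) {
  const int p = x.nrow(), n = x.ncol();
  NumericMatrix z(p, n);
  static const double inv_sqrt2 = 0.7071067811865475244;
  for (int i = 0; i < p; ++i) {
    const double hi = h[i];
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      const double xij = x(i, j);
      for (int k = 0; k < n; ++k) {
        s += 0.5 * std::erfc(-(xij - x(i, k)) / hi * inv_sqrt2);
      }
      z(i, j) = s / n;
    }
  }
  return z;
}

// Kolmogorov-Smirnov-like weighted random walk over a per-sample gene
// ordering. ord: p x n matrix of 1-based gene indices, walk order (rank 1
// first) per sample. rstat: p x n symmetric rank statistic |p/2 - rank|.
// mask: p x m logical, gene-set membership by matrix row. tau: weight
// exponent. Returns n x m score matrix: max positive running deviation
// minus max absolute negative running deviation.
// [[Rcpp::export(name = ".walk_scores")]]
NumericMatrix walk_scores(IntegerMatrix ord, NumericMatrix rstat,
                          LogicalMatrix mask, double tau) {
  const int p = ord.nrow(), n = ord.ncol(), m = mask.ncol();
  NumericMatrix out(n, m);
  std::vector<double> w(p);
  std::vector<int> inset(p);
  for (int s = 0; s < m; ++s) {
    for (int j = 0; j < n; ++j) {
      double tot = 0.0;
      int k = 0;
      for (int l = 0; l < p; ++l) {
        const int g = ord(l, j) - 1;
        inset[l] = mask(g, s) ? 1 : 0;
        if (inset[l]) {
          w[l] = std::pow(std::fabs(rstat(g, j)), tau);
          tot += w[l];
          ++k;
        }
      }
      const double dec = (p > k) ? 1.0 / (p - k) : 0.0;
      double dev = 0.0, mpos = 0.0, mneg = 0.0;
      for (int l = 0; l < p; ++l) {
        if (inset[l]) dev += (tot > 0.0) ? w[l] / tot : 0.0;
        else dev -= dec;
        if (dev > mpos) mpos = dev;
        if (-dev > mneg) mneg = -dev;
      }
      double sc = mpos - mneg;
      // guard against accumulation drift (sums of 1/(p-k) terms can
      // overshoot the theoretical [-1, 1] bound by ~1e-16)
      if (sc > 1.0) sc = 1.0;
      if (sc < -1.0) sc = -1.0;
      out(j, s) = sc;
    }
  }
  return out;
}
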