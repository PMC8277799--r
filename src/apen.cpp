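#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Approximate entropy (Pincus): ApEn = Phi_m - Phi_{m+1}, where
// Phi_m = mean_i log( C_i^m ) and C_i^m is the fraction of templates of
// length m within Chebyshev distance r of template i, self-matches included.
// Joint counting for m and m+1 keeps the loop O(N^2).
// [[Rcpp::export]]
double apen_cpp(NumericVector u, int m, double r) {
  const int N = u.size();
  if (N <= m + 1) stop("series too short for embedding dimension m");
  const int nm = N - m + 1;   // templates of length m
  const int nm1 = N - m;      // templates of length m + 1
  std::vector<double> cm(nm, 1.0), cm1(nm1, 1.0); // self-matches

  for (int i = 0; i < nm; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(u[i + k] - u[j + k]);
        if (a > d) d = a;
        if (d > r) break;
      }
      if (d <= r) {
        cm[i] += 1.0; cm[j] += 1.0;
        if (i < nm1 && j < nm1) {
          double a = std::fabs(u[i + m] - u[j + m]);
          if (a <= r && d <= r) { cm1[i] += 1.0; cm1[j] += 1.0; }
        }
      }
    }
  }

  double phim = 0.0, phim1 = 0.0;
  for (int i = 0; i < nm; ++i)  phim  += std::log(cm[i] / nm);
  phim /= nm;
  for (int i = 0; i < nm1; ++i) phim1 += std::log(cm1[i] / nm1);
  phim1 /= nm1;
  return phim - phim1;
}
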