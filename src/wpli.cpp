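#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise pooled wPLI sums.  sinp/cosp hold sin and cos of the phases,
// observations (trial x sample) in rows, ROIs in columns.  For each ROI
// pair (i, j), sin(phi_i - phi_j) = sin_i cos_j - cos_i sin_j; returns the
// matrices of |sum| (num) and sum of absolute values (den) over all
// observations.
// [[Rcpp::export]]
List wpli_pair_sums(NumericMatrix sinp, NumericMatrix cosp) {
  const int m = sinp.nrow();
  const int p = sinp.ncol();
  if (cosp.nrow() != m || cosp.ncol() != p)
    stop("sin and cos matrices must have identical dimensions");
  NumericMatrix num(p, p), den(p, p);
  for (int i = 0; i < p; ++i) {
    const double* si = &sinp(0, i);
    const double* ci = &cosp(0, i);
    for (int j = i + 1; j < p; ++j) {
      const double* sj = &sinp(0, j);
      const double* cj = &cosp(0, j);
      double a = 0.0, b = 0.0;
      for (int k = 0; k < m; ++k) {
        const double v = si[k] * cj[k] - ci[k] * sj[k];
        a += v;
        b += std::fabs(v);
      }
      num(i, j) = num(j, i) = std::fabs(a);
      den(i, j) = den(j, i) = b;
    }
  }
  return List::create(_["num"] = num, _["den"] = den);
}
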