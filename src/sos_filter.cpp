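#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Zero-phase (forward-backward) second-order-section filtering of the
// columns of X, with odd-reflection padding of npad samples at both ends.
// sos: one row per section, columns b0 b1 b2 a0 a1 a2 with a0 == 1.
//
// Columns are processed in interleaved blocks so the per-sample recursive
// dependency chains of several series overlap, which is substantially
// faster than one column at a time. Section states are initialized at the
// steady state for a constant input equal to the first processed sample,
// so constant segments map exactly to the cascade's DC gain and there is
// no startup transient.

static const int BLK = 8;

// one biquad over an interleaved block buf[i*BLK + k], i = from..to
static void biquad_blk(std::vector<double>& buf, int from, int to, int step,
                       int nb, double b0, double b1, double b2,
                       double a1, double a2) {
  const double asum = 1.0 + a1 + a2;
  const double K = (asum != 0.0) ? (b0 + b1 + b2) / asum : 0.0;
  double z1[BLK], z2[BLK];
  for (int k = 0; k < nb; ++k) {
    const double x0 = buf[from * BLK + k];
    z1[k] = (K - b0) * x0;
    z2[k] = (b2 - a2 * K) * x0;
  }
  for (int i = from; i != to + step; i += step) {
    double* row = &buf[i * BLK];
    for (int k = 0; k < nb; ++k) {
      const double xi = row[k];
      const double y = b0 * xi + z1[k];
      z1[k] = b1 * xi - a1 * y + z2[k];
      z2[k] = b2 * xi - a2 * y;
      row[k] = y;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix sos_filtfilt_mat(NumericMatrix X, NumericMatrix sos, int npad) {
  const int n = X.nrow(), m = X.ncol(), ns = sos.nrow();
  if (n < 2) stop("series too short to filter");
  const int np = std::min(npad, n - 1);
  const int len = n + 2 * np;
  NumericMatrix out(n, m);
  std::vector<double> buf((size_t)len * BLK);
  for (int j0 = 0; j0 < m; j0 += BLK) {
    const int nb = std::min(BLK, m - j0);
    for (int k = 0; k < nb; ++k) {
      const double* x = &X(0, j0 + k);
      for (int i = 0; i < np; ++i)
        buf[(size_t)i * BLK + k] = 2.0 * x[0] - x[np - i];
      for (int i = 0; i < n; ++i)
        buf[(size_t)(np + i) * BLK + k] = x[i];
      for (int i = 0; i < np; ++i)
        buf[(size_t)(np + n + i) * BLK + k] = 2.0 * x[n - 1] - x[n - 2 - i];
    }
    for (int s = 0; s < ns; ++s)
      biquad_blk(buf, 0, len - 1, 1, nb,
                 sos(s, 0), sos(s, 1), sos(s, 2), sos(s, 4), sos(s, 5));
    for (int s = 0; s < ns; ++s)
      biquad_blk(buf, len - 1, 0, -1, nb,
                 sos(s, 0), sos(s, 1), sos(s, 2), sos(s, 4), sos(s, 5));
    for (int k = 0; k < nb; ++k) {
      double* o = &out(0, j0 + k);
      for (int i = 0; i < n; ++i)
        o[i] = buf[(size_t)(np + i) * BLK + k];
    }
  }
  return out;
}
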