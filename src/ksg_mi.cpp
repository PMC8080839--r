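#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double maxnorm_dist(const double *a, int i, int j, int n,
                                  int d) {
  double m = 0.0;
  for (int c = 0; c < d; ++c) {
    const double v = std::fabs(a[i + n * c] - a[j + n * c]);
    if (v > m) m = v;
  }
  return m;
}

// Kraskov-Stoegbauer-Grassberger mutual information, estimator variant 1.
// Max-norm throughout; eps_i is the distance to the k-th nearest neighbour
// in the joint space and marginal counts use the strict inequality
// ||.|| < eps_i. Returns the estimate in nats. Brute-force O(n^2) neighbour
// search; adequate at the series lengths used here.
//
// [[Rcpp::export]]
double ksg_mi_cpp(NumericMatrix X, NumericMatrix Y, int k) {
  const int n = X.nrow();
  if (Y.nrow() != n) stop("X and Y must have the same number of rows");
  if (n <= k + 1) stop("too few samples for k = %d", k);
  const int dx = X.ncol(), dy = Y.ncol();
  const double *px = X.begin(), *py = Y.begin();

  std::vector<double> dxv(n), dyv(n), djoint(n);
  double acc = 0.0;

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) {
        dxv[j] = dyv[j] = R_PosInf;
        djoint[j] = R_PosInf;
        continue;
      }
      const double ddx = maxnorm_dist(px, i, j, n, dx);
      const double ddy = maxnorm_dist(py, i, j, n, dy);
      dxv[j] = ddx;
      dyv[j] = ddy;
      djoint[j] = ddx > ddy ? ddx : ddy;
    }
    std::vector<double> tmp(djoint);
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double eps = tmp[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (dxv[j] < eps) ++nx;
      if (dyv[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
  }

  return R::digamma(static_cast<double>(k)) +
         R::digamma(static_cast<double>(n)) - acc / n;
}
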