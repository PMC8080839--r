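#include <Rcpp.h>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Euler-Maruyama integration of the bipartite facilitation-competition model.
//
// State layout: pollinators first (length SA), then plants (length SP).
// Drift per species: x * (r + g/(1 + h*g) - sum(c * guild)), g the
// gamma-weighted sum of partner-guild abundances. Noise is sigma*sqrt(dt)*Z
// (additive) or sigma*x*sqrt(dt)*Z (multiplicative); abundances are clipped
// at zero after every step. Rows are recorded every `record_every` steps
// after `burn_steps` burn-in steps. All inputs are copied to plain arrays:
// the loop runs for up to ~1e9 iterations and must not touch SEXP storage.
//
// [[Rcpp::export]]
NumericMatrix em_integrate_cpp(NumericVector rA_, NumericVector rP_,
                               NumericMatrix gA_, NumericMatrix gP_,
                               NumericMatrix cA_, NumericMatrix cP_,
                               NumericVector hA_, NumericVector hP_,
                               NumericVector sigma_, bool multiplicative,
                               NumericVector x0, double dt, int n_record,
                               int record_every, int burn_steps,
                               double seed_master, double seed_stream) {
  const int SA = rA_.size(), SP = rP_.size(), S = SA + SP;
  if (record_every <= 0) stop("record_every must be positive");
  XoshiroRNG rng(static_cast<uint64_t>(seed_master),
                 static_cast<uint64_t>(seed_stream));

  const std::vector<double> rA(rA_.begin(), rA_.end()),
      rP(rP_.begin(), rP_.end()), gA(gA_.begin(), gA_.end()),
      gP(gP_.begin(), gP_.end()), cA(cA_.begin(), cA_.end()),
      cP(cP_.begin(), cP_.end()), hA(hA_.begin(), hA_.end()),
      hP(hP_.begin(), hP_.end()), sigma(sigma_.begin(), sigma_.end());
  std::vector<double> x(x0.begin(), x0.end()), f(S);

  NumericMatrix out(n_record, S);
  double *pout = out.begin();
  const double sq = std::sqrt(dt);

  long long clipped = 0;
  int row = 0;
  while (row < n_record) {
    // run one recording interval (plus burn-in before the first row)
    const long long n_inner =
        (row == 0 ? burn_steps : 0) + static_cast<long long>(record_every);
    for (long long it = 0; it < n_inner; ++it) {
      for (int k = 0; k < SA; ++k) {
        double gs = 0.0, cs = 0.0;
        for (int i = 0; i < SP; ++i) gs += gA[k + SA * i] * x[SA + i];
        for (int l = 0; l < SA; ++l) cs += cA[k + SA * l] * x[l];
        f[k] = x[k] * (rA[k] + gs / (1.0 + hA[k] * gs) - cs);
      }
      for (int i = 0; i < SP; ++i) {
        double gs = 0.0, cs = 0.0;
        for (int k = 0; k < SA; ++k) gs += gP[i + SP * k] * x[k];
        for (int j = 0; j < SP; ++j) cs += cP[i + SP * j] * x[SA + j];
        f[SA + i] = x[SA + i] * (rP[i] + gs / (1.0 + hP[i] * gs) - cs);
      }
      for (int j = 0; j < S; ++j) {
        const double amp = multiplicative ? sigma[j] * x[j] : sigma[j];
        x[j] += f[j] * dt + amp * sq * rng.norm();
        if (x[j] < 0.0) {
          x[j] = 0.0;
          ++clipped;
        }
      }
    }
    for (int j = 0; j < S; ++j) {
      if (!std::isfinite(x[j]))
        stop("non-finite state at recorded row %d", row + 1);
      pout[row + static_cast<long long>(n_record) * j] = x[j];
    }
    ++row;
    if ((row & 255) == 0) Rcpp::checkUserInterrupt();
  }

  out.attr("n_clipped") = static_cast<double>(clipped);
  return out;
}
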