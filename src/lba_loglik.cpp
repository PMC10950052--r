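#include <Rcpp.h>
using namespace Rcpp;

static inline double phi(double x) {   // standard normal pdf
  return 0.39894228040143268 * std::exp(-0.5 * x * x);
}
static inline double Phi(double x) {   // standard normal cdf via erfc
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}

// Race log-likelihood for the linear ballistic accumulator with shared
// drift SD s = 1. Engaged accumulators within a trial share the cell's
// parameters, so each trial contributes
//   f(dt) * (1 - F(dt))^(m - 1) / (1 - Phi(-v)^m),
// with a floor of exp(-20) per trial; trials with dt <= 0 contribute -20.
// [[Rcpp::export]]
double lba_negll_cpp(const NumericVector& rt,
                     const IntegerVector& cell,   // 1-based cell index
                     const IntegerVector& m,      // engaged accumulators
                     const NumericVector& v,      // per-cell (length 4)
                     const NumericVector& b,
                     const NumericVector& z,
                     const NumericVector& t0) {
  const int n = rt.size();
  double total = 0.0;
  double renorm1[4], renorm3[4];       // 1 - Phi(-v)^m for m = 1, 3
  for (int c = 0; c < 4; ++c) {
    const double p = Phi(-v[c]);
    renorm1[c] = 1.0 - p;
    renorm3[c] = 1.0 - p * p * p;
  }
  const double floor_ll = -20.0, floor_lik = std::exp(-20.0);
  for (int i = 0; i < n; ++i) {
    const int c = cell[i] - 1;
    const double dt = rt[i] - t0[c];
    if (dt <= 0.0) { total += floor_ll; continue; }
    const double vv = v[c], bb = b[c], zz = z[c];
    const double a1 = bb - zz - dt * vv, a2 = bb - dt * vv;
    const double z1 = a1 / dt, z2 = a2 / dt;
    const double pz1 = Phi(z1), pz2 = Phi(z2);
    const double dz1 = phi(z1), dz2 = phi(z2);
    double lik = (vv * (pz2 - pz1) + dz1 - dz2) / zz;
    if (m[i] > 1) {
      double surv = -((a1 * pz1 - a2 * pz2 + dt * (dz1 - dz2)) / zz);
      if (surv < 0.0) surv = 0.0;
      if (surv > 1.0) surv = 1.0;
      lik *= surv * surv;
      lik /= renorm3[c];
    } else {
      lik /= renorm1[c];
    }
    if (!(lik >= floor_lik)) lik = floor_lik;
    total += std::log(lik);
  }
  return -total;
}
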