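#include <Rcpp.h>
using namespace Rcpp;

// Single-accumulator defective first-passage density and CDF.
// Same closed forms as the R-level lba_pdf/lba_cdf; duplicated here because
// the likelihood is the optimizer hot path.

static inline double lba_pdf1(double t, double b, double A, double v, double s) {
  const double ts = t * s;
  const double z1 = (b - A - t * v) / ts;
  const double z2 = (b - t * v) / ts;
  double f = (v * R::pnorm(z2, 0.0, 1.0, 1, 0) - v * R::pnorm(z1, 0.0, 1.0, 1, 0) +
              s * R::dnorm(z1, 0.0, 1.0, 0) - s * R::dnorm(z2, 0.0, 1.0, 0)) / A;
  return f > 0.0 ? f : 0.0;
}

static inline double lba_cdf1(double t, double b, double A, double v, double s) {
  const double ts = t * s;
  const double z1 = (b - A - t * v) / ts;
  const double z2 = (b - t * v) / ts;
  double F = 1.0 + (b - A - t * v) / A * R::pnorm(z1, 0.0, 1.0, 1, 0) -
             (b - t * v) / A * R::pnorm(z2, 0.0, 1.0, 1, 0) +
             ts / A * R::dnorm(z1, 0.0, 1.0, 0) -
             ts / A * R::dnorm(z2, 0.0, 1.0, 0);
  if (F < 0.0) F = 0.0;
  if (F > 1.0) F = 1.0;
  return F;
}

// Sum of -log race likelihoods over trials. Zero-likelihood trials (rt <= t0
// or numerical underflow) each contribute -log(1e-300).
// [[Rcpp::export]]
double lba_race_nll_cpp(NumericVector rt, NumericVector vc, NumericVector vo,
                        NumericVector bc, NumericVector bo,
                        double A, double t0, double s) {
  const double penalty = -std::log(1e-300);
  const int n = rt.size();
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    const double tau = rt[i] - t0;
    double L = 0.0;
    if (tau > 0.0) {
      const double norm = 1.0 - R::pnorm(-vc[i] / s, 0.0, 1.0, 1, 0) *
                                R::pnorm(-vo[i] / s, 0.0, 1.0, 1, 0);
      if (norm > 0.0) {
        L = lba_pdf1(tau, bc[i], A, vc[i], s) *
            (1.0 - lba_cdf1(tau, bo[i], A, vo[i], s)) / norm;
      }
    }
    if (L > 0.0 && R_finite(L)) nll -= std::log(L);
    else nll += penalty;
  }
  return nll;
}
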