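#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-pair counts for sample entropy (Eq. of Richman & Moorman).
// Both the length-m and length-(m+1) counts run over the same N - m*tau
// templates so the ratio A/B is a conditional probability. Chebyshev
// distance, strict "< r", self-matches excluded. Returns c(A, B).
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r, int tau = 1) {
  const int N = x.size();
  const int nt = N - m * tau;  // templates usable at both lengths
  NumericVector out(2);
  if (nt < 2) {
    out[0] = NA_REAL; out[1] = NA_REAL;
    return out;
  }
  double A = 0.0, B = 0.0;
  const double *xp = x.begin();
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool within = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(xp[i + k * tau] - xp[j + k * tau]);
        if (dd > d) d = dd;
        if (d >= r) { within = false; break; }
      }
      if (!within) continue;
      B += 1.0;
      if (std::fabs(xp[i + m * tau] - xp[j + m * tau]) < r) A += 1.0;
    }
  }
  out[0] = A; out[1] = B;
  return out;
}

// Fuzzy-entropy phi sums: templates are mean-removed, similarity is
// exp(-d^n / r) with d the Chebyshev distance between mean-removed
// templates. Returns c(phi_m, phi_m1), each the symmetric pair average
// 2/(nt*(nt-1)) * sum_{i<j} D_ij over the nt = N - m*tau templates.
// [[Rcpp::export]]
NumericVector fuzzen_phis(NumericVector x, int m, double r, double nexp,
                          int tau = 1) {
  const int N = x.size();
  const int nt = N - m * tau;
  NumericVector out(2);
  if (nt < 2 || N < (m + 1) * tau + 1) {
    out[0] = NA_REAL; out[1] = NA_REAL;
    return out;
  }
  const double *xp = x.begin();
  // window means for template lengths m and m+1
  std::vector<double> mu_m(nt), mu_m1(nt);
  for (int i = 0; i < nt; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += xp[i + k * tau];
    mu_m[i] = s / m;
    mu_m1[i] = (s + xp[i + m * tau]) / (m + 1);
  }
  const bool sq = (nexp == 2.0);
  double sum_m = 0.0, sum_m1 = 0.0;
  if (sq && m == 2 && tau == 1) {
    // hot path for the default parameters: unrolled, pointer arithmetic
    const double invr = 1.0 / r;
    for (int i = 0; i < nt - 1; ++i) {
      const double mi = mu_m[i], mi1 = mu_m1[i];
      const double xi0 = xp[i], xi1 = xp[i + 1], xi2 = xp[i + 2];
      for (int j = i + 1; j < nt; ++j) {
        const double dmu = mi - mu_m[j], dmu1 = mi1 - mu_m1[j];
        const double e0 = xi0 - xp[j], e1 = xi1 - xp[j + 1],
          e2 = xi2 - xp[j + 2];
        double a0 = std::fabs(e0 - dmu), a1 = std::fabs(e1 - dmu);
        const double dm = a0 > a1 ? a0 : a1;
        double b0 = std::fabs(e0 - dmu1), b1 = std::fabs(e1 - dmu1),
          b2 = std::fabs(e2 - dmu1);
        double dm1 = b0 > b1 ? b0 : b1;
        if (b2 > dm1) dm1 = b2;
        sum_m  += std::exp(-(dm * dm) * invr);
        sum_m1 += std::exp(-(dm1 * dm1) * invr);
      }
    }
    const double np = 0.5 * nt * (nt - 1.0);
    out[0] = sum_m / np;
    out[1] = sum_m1 / np;
    return out;
  }
  for (int i = 0; i < nt - 1; ++i) {
    const double mi = mu_m[i], mi1 = mu_m1[i];
    for (int j = i + 1; j < nt; ++j) {
      const double mj = mu_m[j], mj1 = mu_m1[j];
      double dm = 0.0, dm1 = 0.0;
      for (int k = 0; k <= m; ++k) {
        const double diff = xp[i + k * tau] - xp[j + k * tau];
        if (k < m) {
          double a = std::fabs(diff - mi + mj);
          if (a > dm) dm = a;
        }
        double b = std::fabs(diff - mi1 + mj1);
        if (b > dm1) dm1 = b;
      }
      if (sq) {
        sum_m  += std::exp(-(dm * dm) / r);
        sum_m1 += std::exp(-(dm1 * dm1) / r);
      } else {
        sum_m  += std::exp(-std::pow(dm, nexp) / r);
        sum_m1 += std::exp(-std::pow(dm1, nexp) / r);
      }
    }
  }
  const double npairs = 0.5 * nt * (nt - 1.0);
  out[0] = sum_m / npairs;
  out[1] = sum_m1 / npairs;
  return out;
}
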