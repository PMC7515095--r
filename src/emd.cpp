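#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Reusable buffers: sifting is envelope-bound, so allocation churn across
// the tens of thousands of sifts in an ensemble run matters.
struct EmdWork {
  std::vector<int> maxi, mini;
  std::vector<double> t, y, h, alpha, mu, z, M, upper, lower, cur, nxt, res;
};

// Strict interior extrema of a series (indices 0-based).
static void find_extrema(const std::vector<double> &x,
                         std::vector<int> &maxi, std::vector<int> &mini) {
  maxi.clear(); mini.clear();
  const int n = (int)x.size();
  for (int i = 1; i < n - 1; ++i) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) maxi.push_back(i);
    else if (x[i] < x[i - 1] && x[i] < x[i + 1]) mini.push_back(i);
  }
}

static int count_zero_crossings(const std::vector<double> &x) {
  int zc = 0, prev = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    int s = (x[i] > 0.0) - (x[i] < 0.0);
    if (s == 0) continue;
    if (prev != 0 && s != prev) ++zc;
    prev = s;
  }
  return zc;
}

// Natural cubic spline through (t, y), t strictly increasing; evaluated at
// integer query points 0..N-1 into out (end cubics extrapolate).
static void spline_eval(EmdWork &w, int N, std::vector<double> &out) {
  const std::vector<double> &t = w.t, &y = w.y;
  const int K = (int)t.size();
  out.resize(N);
  if (K == 1) { std::fill(out.begin(), out.end(), y[0]); return; }
  if (K == 2) {
    const double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int q = 0; q < N; ++q) out[q] = y[0] + slope * (q - t[0]);
    return;
  }
  std::vector<double> &h = w.h, &alpha = w.alpha, &mu = w.mu, &z = w.z,
    &M = w.M;
  h.resize(K - 1); alpha.resize(K); mu.resize(K); z.resize(K); M.resize(K);
  for (int i = 0; i < K - 1; ++i) h[i] = t[i + 1] - t[i];
  mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < K - 1; ++i) {
    alpha[i] = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
    const double l = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l;
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l;
  }
  M[K - 1] = 0.0;
  for (int i = K - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  M[0] = 0.0;  // natural boundary
  int seg = 0;
  for (int q = 0; q < N; ++q) {
    while (seg < K - 2 && t[seg + 1] < q) ++seg;
    const double hi = h[seg], inv = 1.0 / hi;
    const double a = (t[seg + 1] - q) * inv, b = (q - t[seg]) * inv;
    out[q] = a * y[seg] + b * y[seg + 1] +
      ((a * a * a - a) * M[seg] + (b * b * b - b) * M[seg + 1]) *
      (hi * hi) / 6.0;
  }
}

// Envelope through extrema with mirror extension of up to two extrema
// beyond each boundary (suppresses end swings before spline fitting).
static void envelope(EmdWork &w, const std::vector<double> &x,
                     const std::vector<int> &idx, int N,
                     std::vector<double> &env) {
  const int K = (int)idx.size();
  w.t.clear(); w.y.clear();
  const int nref = K < 2 ? K : 2;
  for (int k = nref - 1; k >= 0; --k) {        // reflect about sample 0
    const double tt = -(double)idx[k];
    if (w.t.empty() || tt > w.t.back()) { w.t.push_back(tt); w.y.push_back(x[idx[k]]); }
  }
  for (int k = 0; k < K; ++k) {
    const double tt = idx[k];
    if (w.t.empty() || tt > w.t.back()) { w.t.push_back(tt); w.y.push_back(x[idx[k]]); }
  }
  for (int k = 0; k < nref; ++k) {             // reflect about sample N-1
    const double tt = 2.0 * (N - 1) - idx[K - 1 - k];
    if (w.t.empty() || tt > w.t.back()) { w.t.push_back(tt); w.y.push_back(x[idx[K - 1 - k]]); }
  }
  spline_eval(w, N, env);
}

// Core EMD: sifting with the Cauchy SD criterion plus the IMF
// extrema/zero-crossing condition, hard cap max_sift passes per IMF.
// x is consumed; extracted IMFs are appended via the sink callback and
// the residue is left in w.res.
template <typename Sink>
static void emd_run(EmdWork &w, std::vector<double> &x, int max_imfs,
                    double sd_thresh, int max_sift, Sink sink) {
  const int N = (int)x.size();
  std::vector<double> &r = w.res, &h = w.cur, &hn = w.nxt;
  r = x;
  for (int j = 0; j < max_imfs; ++j) {
    find_extrema(r, w.maxi, w.mini);
    if ((int)w.maxi.size() < 2 || (int)w.mini.size() < 2) break;
    h = r;
    // extra passes beyond max_sift run only while the IMF
    // extrema/zero-crossing condition is still violated
    const int hard_cap = max_sift * 5;
    for (int it = 0; it < hard_cap; ++it) {
      find_extrema(h, w.maxi, w.mini);
      if ((int)w.maxi.size() < 2 || (int)w.mini.size() < 2) break;
      envelope(w, h, w.maxi, N, w.upper);
      envelope(w, h, w.mini, N, w.lower);
      double num = 0.0, den = 0.0;
      for (int q = 0; q < N; ++q) {
        const double mean_env = 0.5 * (w.upper[q] + w.lower[q]);
        hn[q] = h[q] - mean_env;
        num += mean_env * mean_env;  // (h - h_new)^2
        den += h[q] * h[q];
      }
      h.swap(hn);
      const bool sd_ok = den > 0.0 && num / den < sd_thresh;
      if (sd_ok || it + 1 >= max_sift) {
        // accept once the extrema/zero-crossing condition also holds
        find_extrema(h, w.maxi, w.mini);
        const int next = (int)w.maxi.size() + (int)w.mini.size();
        if (std::abs(next - count_zero_crossings(h)) <= 1) break;
      }
    }
    sink(j, h);
    for (int q = 0; q < N; ++q) r[q] -= h[q];
  }
}

// [[Rcpp::export]]
List emd_c(NumericVector x, int max_imfs, double sd_thresh = 0.2,
           int max_sift = 10) {
  const int N = x.size();
  EmdWork w;
  w.cur.resize(N); w.nxt.resize(N);
  std::vector<double> xv(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  emd_run(w, xv, max_imfs, sd_thresh, max_sift,
          [&](int, const std::vector<double> &h) { imfs.push_back(h); });
  const int m = (int)imfs.size();
  NumericMatrix im(N, m);
  for (int j = 0; j < m; ++j)
    for (int q = 0; q < N; ++q) im(q, j) = imfs[j][q];
  return List::create(_["imfs"] = im,
                      _["residue"] = NumericVector(w.res.begin(), w.res.end()));
}

// Ensemble loop in C++: noise is an N x E matrix supplied by the caller
// (drawn under R's RNG for reproducibility). IMFs are averaged index-wise
// across ensembles, zero-padding ensembles that stop early; residues are
// averaged likewise. Returns the count of IMFs per ensemble as well.
// [[Rcpp::export]]
List eemd_c(NumericVector x, NumericMatrix noise, int max_imfs,
            double sd_thresh = 0.2, int max_sift = 10) {
  const int N = x.size(), E = noise.ncol();
  EmdWork w;
  w.cur.resize(N); w.nxt.resize(N);
  NumericMatrix acc(N, max_imfs);
  std::vector<double> res_acc(N, 0.0), xv(N);
  IntegerVector counts(E);
  int mmax = 0;
  for (int e = 0; e < E; ++e) {
    for (int q = 0; q < N; ++q) xv[q] = x[q] + noise(q, e);
    int cnt = 0;
    emd_run(w, xv, max_imfs, sd_thresh, max_sift,
            [&](int j, const std::vector<double> &h) {
              double *col = &acc(0, j);
              for (int q = 0; q < N; ++q) col[q] += h[q];
              cnt = j + 1;
            });
    counts[e] = cnt;
    if (cnt > mmax) mmax = cnt;
    for (int q = 0; q < N; ++q) res_acc[q] += w.res[q];
  }
  NumericMatrix im(N, mmax);
  for (int j = 0; j < mmax; ++j)
    for (int q = 0; q < N; ++q) im(q, j) = acc(q, j) / E;
  NumericVector residue(N);
  for (int q = 0; q < N; ++q) residue[q] = res_acc[q] / E;
  return List::create(_["imfs"] = im, _["residue"] = residue,
                      _["counts"] = counts);
}

// Extrema and zero-crossing counts, for post-hoc IMF condition checks.
// [[Rcpp::export]]
IntegerVector extrema_zc_counts(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  std::vector<int> maxi, mini;
  find_extrema(v, maxi, mini);
  return IntegerVector::create((int)(maxi.size() + mini.size()),
                               count_zero_crossings(v));
}
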