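#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Workspace of reusable buffers: the sifting loop runs ~10^4 times per EEMD
// call, so per-iteration heap allocation would dominate the runtime.
struct SiftWorkspace {
  std::vector<int> maxima, minima;
  std::vector<double> xk, yk, upper, lower;
  std::vector<double> h2, alpha, l, mu, z, M;  // spline tridiagonal solve
};

// ---- local extrema -------------------------------------------------------
// Interior maxima/minima of y, 0-based indices; a flat extremum (plateau)
// contributes one extremum at its midpoint.
static void find_extrema(const std::vector<double>& y,
                         std::vector<int>& maxima,
                         std::vector<int>& minima) {
  maxima.clear(); minima.clear();
  const int n = (int)y.size();
  if (n < 3) return;
  int prev_sign = 0;
  int run_start = 0;  // first index of the run of equal values d ends on
  for (int i = 1; i < n; ++i) {
    double d = y[i] - y[i - 1];
    int s = (d > 0.0) - (d < 0.0);
    if (s == 0) continue;
    if (prev_sign > 0 && s < 0) maxima.push_back((run_start + (i - 1)) / 2);
    if (prev_sign < 0 && s > 0) minima.push_back((run_start + (i - 1)) / 2);
    prev_sign = s;
    run_start = i;
  }
}

// [[Rcpp::export(name = ".extrema_cpp")]]
List extrema_cpp(NumericVector x) {
  std::vector<double> y(x.begin(), x.end());
  std::vector<int> ma, mi;
  find_extrema(y, ma, mi);
  IntegerVector M(ma.begin(), ma.end()), m(mi.begin(), mi.end());
  return List::create(_["maxima"] = M + 1, _["minima"] = m + 1); // 1-based
}

// ---- natural cubic spline ------------------------------------------------
// Knots (xk strictly increasing), natural boundary (zero second derivative
// at both ends); evaluated on the integer grid 0..L-1.
static void natural_spline_envelope(SiftWorkspace& ws, int L,
                                    std::vector<double>& out) {
  const std::vector<double>& xk = ws.xk;
  const std::vector<double>& yk = ws.yk;
  const int n = (int)xk.size();
  out.resize(L);
  if (n == 1) { std::fill(out.begin(), out.end(), yk[0]); return; }
  if (n == 2) {
    double slope = (yk[1] - yk[0]) / (xk[1] - xk[0]);
    for (int t = 0; t < L; ++t) out[t] = yk[0] + slope * (t - xk[0]);
    return;
  }
  std::vector<double>& h = ws.h2;   std::vector<double>& alpha = ws.alpha;
  std::vector<double>& l = ws.l;    std::vector<double>& mu = ws.mu;
  std::vector<double>& z = ws.z;    std::vector<double>& M = ws.M;
  h.resize(n - 1); alpha.resize(n); l.resize(n); mu.resize(n);
  z.resize(n); M.resize(n);
  for (int i = 0; i < n - 1; ++i) h[i] = xk[i + 1] - xk[i];
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < n - 1; ++i) {
    alpha[i] = 3.0 * ((yk[i + 1] - yk[i]) / h[i] - (yk[i] - yk[i - 1]) / h[i - 1]);
    l[i] = 2.0 * (xk[i + 1] - xk[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[n - 1] = 0.0;
  for (int i = n - 2; i >= 1; --i) M[i] = z[i] - mu[i] * M[i + 1];
  M[0] = 0.0;
  // the recursion solves for the quadratic coefficients c_j = M_j / 2;
  // rescale to true second derivatives
  for (int i = 0; i < n; ++i) M[i] *= 2.0;
  // evaluate segment-wise with Horner on precomputed cubic coefficients
  // (no per-sample division)
  int t = 0;
  for (int seg = 0; seg < n - 1 && t < L; ++seg) {
    double x0 = xk[seg], x1 = xk[seg + 1];
    if (x1 < t && seg < n - 2) continue;
    double hi = h[seg], inv_h = 1.0 / hi;
    double c0 = yk[seg];
    double c1 = (yk[seg + 1] - yk[seg]) * inv_h - hi * (2.0 * M[seg] + M[seg + 1]) / 6.0;
    double c2 = M[seg] * 0.5;
    double c3 = (M[seg + 1] - M[seg]) * inv_h / 6.0;
    int t_end = (seg == n - 2) ? (L - 1) : (int)std::floor(x1);
    if (t_end > L - 1) t_end = L - 1;
    for (; t <= t_end; ++t) {
      double u = t - x0;
      out[t] = c0 + u * (c1 + u * (c2 + u * c3));
    }
  }
}

// Envelope through the extrema at positions pos, mirroring the two extrema
// nearest each end across the record boundaries so the spline brackets the
// whole sample grid.
static void build_envelope(SiftWorkspace& ws, const std::vector<int>& pos,
                           const std::vector<double>& y, int L,
                           std::vector<double>& env) {
  const int n = (int)pos.size();
  ws.xk.clear(); ws.yk.clear();
  for (int k = std::min(2, n) - 1; k >= 0; --k) {     // left mirror about 0
    double xm = -(double)pos[k];
    if (xm < (double)pos[0]) { ws.xk.push_back(xm); ws.yk.push_back(y[pos[k]]); }
  }
  for (int k = 0; k < n; ++k) {
    ws.xk.push_back((double)pos[k]); ws.yk.push_back(y[pos[k]]);
  }
  for (int k = 0; k < std::min(2, n); ++k) {          // right mirror about L-1
    double xm = 2.0 * (L - 1) - (double)pos[n - 1 - k];
    if (xm > (double)pos[n - 1]) { ws.xk.push_back(xm); ws.yk.push_back(y[pos[n - 1 - k]]); }
  }
  natural_spline_envelope(ws, L, env);
}

// ---- sifting -------------------------------------------------------------
// Fixed-count sifting: subtract the mean envelope `sift_iterations` times;
// stops early if either envelope loses support (< 2 maxima or minima).
static void sift(SiftWorkspace& ws, std::vector<double>& h, int sift_iterations) {
  const int L = (int)h.size();
  for (int it = 0; it < sift_iterations; ++it) {
    find_extrema(h, ws.maxima, ws.minima);
    if ((int)ws.maxima.size() < 2 || (int)ws.minima.size() < 2) break;
    build_envelope(ws, ws.maxima, h, L, ws.upper);
    build_envelope(ws, ws.minima, h, L, ws.lower);
    for (int t = 0; t < L; ++t) h[t] -= 0.5 * (ws.upper[t] + ws.lower[t]);
  }
}

static int count_extrema_of(SiftWorkspace& ws, const std::vector<double>& y) {
  find_extrema(y, ws.maxima, ws.minima);
  return (int)(ws.maxima.size() + ws.minima.size());
}

// Core EMD. Fills `imfs` (k rows of length L, k <= max_imfs; exactly
// max_imfs when force = true, zero-padded after extraction stops) and the
// residual. Extraction stops when the working residual has fewer than 3
// local extrema.
static void emd_core(SiftWorkspace& ws, const std::vector<double>& x,
                     int max_imfs, int sift_iterations, bool force,
                     std::vector< std::vector<double> >& imfs,
                     std::vector<double>& residual) {
  const int L = (int)x.size();
  residual = x;
  int k = 0;
  for (; k < max_imfs; ++k) {
    if (count_extrema_of(ws, residual) < 3) break;
    if ((int)imfs.size() <= k) imfs.push_back(std::vector<double>());
    std::vector<double>& h = imfs[k];
    h = residual;
    sift(ws, h, sift_iterations);
    for (int t = 0; t < L; ++t) residual[t] -= h[t];
  }
  if (force) {
    for (; k < max_imfs; ++k) {
      if ((int)imfs.size() <= k) imfs.push_back(std::vector<double>());
      imfs[k].assign(L, 0.0);
    }
  }
  imfs.resize(k);
}

// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector x, int max_imfs, int sift_iterations, bool force) {
  SiftWorkspace ws;
  std::vector<double> xv(x.begin(), x.end());
  std::vector< std::vector<double> > imfs;
  std::vector<double> residual;
  emd_core(ws, xv, max_imfs, sift_iterations, force, imfs, residual);
  const int L = (int)xv.size(), k = (int)imfs.size();
  NumericMatrix M(L, k);
  for (int j = 0; j < k; ++j)
    for (int t = 0; t < L; ++t) M(t, j) = imfs[j][t];
  return List::create(_["imfs"] = M,
                      _["residual"] = NumericVector(residual.begin(), residual.end()));
}

// Ensemble EMD: mean over `ensemble_size` trials of EMD applied to the
// signal plus Gaussian white noise of sd `noise_sd`, each trial forced to
// exactly `max_imfs` imfs so the per-index ensemble mean is well defined.
// Noise comes from R's RNG stream (seedable with set.seed()).
// [[Rcpp::export(name = ".eemd_cpp")]]
List eemd_cpp(NumericVector x, double noise_sd, int ensemble_size,
              int max_imfs, int sift_iterations) {
  const int L = x.size();
  SiftWorkspace ws;
  std::vector<double> xv(x.begin(), x.end()), noisy(L);
  std::vector< std::vector<double> > imfs;
  std::vector<double> residual;
  NumericMatrix acc(L, max_imfs);
  NumericVector acc_res(L);
  for (int k = 0; k < ensemble_size; ++k) {
    if (noise_sd > 0.0) {
      NumericVector w = rnorm(L, 0.0, noise_sd);
      for (int t = 0; t < L; ++t) noisy[t] = xv[t] + w[t];
    } else {
      noisy = xv;
    }
    emd_core(ws, noisy, max_imfs, sift_iterations, true, imfs, residual);
    for (int j = 0; j < max_imfs; ++j) {
      const std::vector<double>& src = imfs[j];
      for (int t = 0; t < L; ++t) acc(t, j) += src[t];
    }
    for (int t = 0; t < L; ++t) acc_res[t] += residual[t];
  }
  for (int j = 0; j < max_imfs; ++j)
    for (int t = 0; t < L; ++t) acc(t, j) /= ensemble_size;
  for (int t = 0; t < L; ++t) acc_res[t] /= ensemble_size;
  return List::create(_["imfs"] = acc, _["residual"] = acc_res);
}
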