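#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Local extrema of x with plateau handling: a run of equal samples bounded by
// a rise and a fall counts once, at the plateau midpoint. Endpoints are not
// extrema; they are handled by mirroring when envelopes are built.
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& maxima,
                         std::vector<int>& minima) {
  const int n = (int)x.size();
  maxima.clear();
  minima.clear();
  if (n < 3) return;
  int prev_sign = 0;          // sign of the last nonzero difference
  int plateau_start = 0;      // first index of the current flat run
  for (int i = 1; i < n; ++i) {
    double d = x[i] - x[i - 1];
    int s = (d > 0) - (d < 0);
    if (s == 0) continue;     // extend plateau, keep plateau_start
    if (prev_sign > 0 && s < 0) {
      // midpoint of the flat run [plateau_start, i-1] at the turning level
      maxima.push_back((plateau_start + (i - 1)) / 2);
    } else if (prev_sign < 0 && s > 0) {
      minima.push_back((plateau_start + (i - 1)) / 2);
    }
    prev_sign = s;
    plateau_start = i;
  }
}

// Natural cubic spline through (xi, yi), evaluated on integers 0..n-1.
// xi strictly increasing; Thomas algorithm for the second derivatives.
static std::vector<double> natural_spline(const std::vector<double>& xi,
                                          const std::vector<double>& yi,
                                          int n) {
  const int m = (int)xi.size();
  std::vector<double> out(n);
  if (m == 1) {
    std::fill(out.begin(), out.end(), yi[0]);
    return out;
  }
  if (m == 2) {
    double slope = (yi[1] - yi[0]) / (xi[1] - xi[0]);
    for (int q = 0; q < n; ++q) out[q] = yi[0] + slope * (q - xi[0]);
    return out;
  }
  std::vector<double> h(m - 1), alpha(m), l(m), mu(m), z(m), M(m);
  for (int i = 0; i < m - 1; ++i) h[i] = xi[i + 1] - xi[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((yi[i + 1] - yi[i]) / h[i] - (yi[i] - yi[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (xi[i + 1] - xi[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  // piecewise evaluation; queries 0..n-1 are sorted so walk the knots once
  int seg = 0;
  for (int q = 0; q < n; ++q) {
    double xq = (double)q;
    while (seg < m - 2 && xq > xi[seg + 1]) ++seg;
    double dx = xi[seg + 1] - xi[seg];
    double A = (xi[seg + 1] - xq) / dx;
    double B = (xq - xi[seg]) / dx;
    out[q] = A * yi[seg] + B * yi[seg + 1] +
             ((A * A * A - A) * M[seg] + (B * B * B - B) * M[seg + 1]) *
               (dx * dx) / 6.0;
  }
  return out;
}

// Envelope through the given extrema with mirrored boundary extrema:
// the first two and last two extrema are reflected about the signal ends to
// anchor the spline and suppress endpoint swings.
static std::vector<double> envelope(const std::vector<double>& x,
                                    const std::vector<int>& idx, int n) {
  std::vector<double> xi, yi;
  int k = (int)idx.size();
  int nmirror = std::min(2, k);
  for (int j = nmirror - 1; j >= 0; --j) {
    int i = idx[j];
    if (i > 0) { xi.push_back(-(double)i); yi.push_back(x[i]); }
  }
  for (int j = 0; j < k; ++j) { xi.push_back((double)idx[j]); yi.push_back(x[idx[j]]); }
  for (int j = 0; j < nmirror; ++j) {
    int i = idx[k - 1 - j];
    if (i < n - 1) { xi.push_back(2.0 * (n - 1) - i); yi.push_back(x[i]); }
  }
  return natural_spline(xi, yi, n);
}

static int n_extrema(const std::vector<double>& x) {
  std::vector<int> mx, mn;
  find_extrema(x, mx, mn);
  return (int)(mx.size() + mn.size());
}

static int n_zero_crossings(const std::vector<double>& x) {
  int count = 0, prev = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    int s = (x[i] > 0) - (x[i] < 0);
    if (s == 0) continue;
    if (prev != 0 && s != prev) ++count;
    prev = s;
  }
  return count;
}

// |#extrema - #zero-crossings| on a sub-range [lo, hi)
static int count_imbalance(const std::vector<double>& x, int lo, int hi) {
  std::vector<double> seg(x.begin() + lo, x.begin() + hi);
  return std::abs(n_extrema(seg) - n_zero_crossings(seg));
}

// IMF counting condition, checked on the full signal and on the interior
// with 1% edge margins (boundary effects must not hide riding waves)
static bool imf_condition_ok(const std::vector<double>& h) {
  const int n = (int)h.size();
  if (count_imbalance(h, 0, n) > 1) return false;
  int lo = std::max(0, (int)std::floor(n * 0.01) - 1);
  int hi = std::min(n, (int)std::ceil(n * 0.99));
  if (hi - lo > 3 && count_imbalance(h, lo, hi) > 1) return false;
  return true;
}

// One sifting pass sequence: subtract the mean envelope until the IMF
// counting condition (|#extrema - #zero-crossings| <= 1) holds together with
// the SD stopping criterion sum((h_prev - h_new)^2) / sum(h_prev^2) < sd_tol,
// or until max_iters. The SD criterion alone leaves riding waves that break
// the counting condition, so both are required.
// Returns the IMF candidate; status -1 flags fewer than 4 extrema at entry.
static int sift_core(std::vector<double>& h, int max_iters, double sd_tol) {
  const int n = (int)h.size();
  std::vector<int> mx, mn;
  find_extrema(h, mx, mn);
  if ((int)(mx.size() + mn.size()) < 4) return -1;
  for (int iter = 0; iter < max_iters; ++iter) {
    find_extrema(h, mx, mn);
    if (mx.empty() || mn.empty() || (int)(mx.size() + mn.size()) < 4) break;
    std::vector<double> up = envelope(h, mx, n);
    std::vector<double> lo = envelope(h, mn, n);
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = 0.5 * (up[i] + lo[i]);
      num += m * m;
      den += h[i] * h[i];
      h[i] -= m;
    }
    if (den <= 0.0) break;
    if (num / den < sd_tol && imf_condition_ok(h)) break;
  }
  return 0;
}

// [[Rcpp::export(name = ".sift_cpp")]]
List sift_cpp(NumericVector x, int max_iters, double sd_tol) {
  std::vector<double> h(x.begin(), x.end());
  int status = sift_core(h, max_iters, sd_tol);
  return List::create(_["imf"] = NumericVector(h.begin(), h.end()),
                      _["monotone"] = (status == -1));
}

// [[Rcpp::export(name = ".emd_cpp")]]
List emd_cpp(NumericVector x, int max_imfs, int max_sift_iters, double sd_tol) {
  const int n = x.size();
  std::vector<double> residue(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  for (int k = 0; k < max_imfs; ++k) {
    if (n_extrema(residue) < 4) break;
    std::vector<double> h = residue;
    int status = sift_core(h, max_sift_iters, sd_tol);
    if (status == -1) break;
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) residue[i] -= h[i];
  }
  NumericMatrix out(n, (int)imfs.size());
  for (int k = 0; k < (int)imfs.size(); ++k)
    for (int i = 0; i < n; ++i) out(i, k) = imfs[k][i];
  return List::create(_["imfs"] = out,
                      _["residue"] = NumericVector(residue.begin(), residue.end()));
}

// [[Rcpp::export(name = ".extrema_cpp")]]
List extrema_cpp(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  std::vector<int> mx, mn;
  find_extrema(v, mx, mn);
  IntegerVector maxima(mx.size()), minima(mn.size());
  for (size_t i = 0; i < mx.size(); ++i) maxima[i] = mx[i] + 1;
  for (size_t i = 0; i < mn.size(); ++i) minima[i] = mn[i] + 1;
  return List::create(_["maxima"] = maxima, _["minima"] = minima);
}
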