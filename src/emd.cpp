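#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Interior local extrema; plateaus contribute their midpoint.
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& maxima,
                         std::vector<int>& minima) {
  maxima.clear();
  minima.clear();
  const int n = (int)x.size();
  int i = 1;
  while (i < n - 1) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) {
      maxima.push_back(i);
      ++i;
    } else if (x[i] < x[i - 1] && x[i] < x[i + 1]) {
      minima.push_back(i);
      ++i;
    } else if (x[i] != x[i - 1] && x[i] == x[i + 1]) {
      // plateau: scan to its end, classify by the flanks
      int j = i;
      while (j < n - 1 && x[j + 1] == x[i]) ++j;
      if (j < n - 1) {
        int mid = (i + j) / 2;
        if (x[i] > x[i - 1] && x[i] > x[j + 1]) maxima.push_back(mid);
        if (x[i] < x[i - 1] && x[i] < x[j + 1]) minima.push_back(mid);
      }
      i = j + 1;
    } else {
      ++i;
    }
  }
}

// Natural cubic spline through (t, y), evaluated at 0..n-1.
// t strictly increasing; at least 2 knots.
static void natural_spline_eval(const std::vector<double>& t,
                                const std::vector<double>& y,
                                int n, std::vector<double>& out) {
  const int m = (int)t.size();
  out.assign(n, 0.0);
  if (m == 2) {  // straight line
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int k = 0; k < n; ++k) out[k] = y[0] + slope * (k - t[0]);
    return;
  }
  // second derivatives via tridiagonal solve (natural: y2[0]=y2[m-1]=0)
  std::vector<double> y2(m, 0.0), u(m, 0.0);
  for (int i = 1; i < m - 1; ++i) {
    double sig = (t[i] - t[i - 1]) / (t[i + 1] - t[i - 1]);
    double p = sig * y2[i - 1] + 2.0;
    y2[i] = (sig - 1.0) / p;
    double d = (y[i + 1] - y[i]) / (t[i + 1] - t[i]) -
               (y[i] - y[i - 1]) / (t[i] - t[i - 1]);
    u[i] = (6.0 * d / (t[i + 1] - t[i - 1]) - sig * u[i - 1]) / p;
  }
  for (int i = m - 2; i >= 1; --i) y2[i] = y2[i] * y2[i + 1] + u[i];
  // evaluate; knots bracket [0, n-1] by construction (mirrored ends)
  int lo = 0;
  for (int k = 0; k < n; ++k) {
    double xv = (double)k;
    while (lo < m - 2 && t[lo + 1] < xv) ++lo;
    double h = t[lo + 1] - t[lo];
    double a = (t[lo + 1] - xv) / h;
    double b = (xv - t[lo]) / h;
    out[k] = a * y[lo] + b * y[lo + 1] +
             ((a * a * a - a) * y2[lo] + (b * b * b - b) * y2[lo + 1]) *
                 (h * h) / 6.0;
  }
}

// Anchor knots for one envelope: up to two extrema mirrored about each end.
static void make_knots(const std::vector<int>& idx,
                       const std::vector<double>& x, int n,
                       std::vector<double>& t, std::vector<double>& y) {
  t.clear();
  y.clear();
  const int k = (int)idx.size();
  int nl = k >= 2 ? 2 : 1;
  for (int j = nl - 1; j >= 0; --j) {  // reflected about sample 0
    t.push_back(-(double)idx[j]);
    y.push_back(x[idx[j]]);
  }
  for (int j = 0; j < k; ++j) {
    t.push_back((double)idx[j]);
    y.push_back(x[idx[j]]);
  }
  for (int j = k - 1; j >= k - nl; --j) {  // reflected about sample n-1
    t.push_back(2.0 * (n - 1) - (double)idx[j]);
    y.push_back(x[idx[j]]);
  }
}

// One IMF by sifting; returns false if x is monotone (fewer than 2 extrema).
static bool sift_imf(const std::vector<double>& x, double tol, int max_sift,
                     std::vector<double>& imf) {
  const int n = (int)x.size();
  std::vector<int> mx, mn;
  find_extrema(x, mx, mn);
  if (mx.size() + mn.size() < 2 || mx.empty() || mn.empty()) return false;

  imf = x;
  std::vector<double> tup, yup, tlo, ylo, eup, elo;
  for (int it = 0; it < max_sift; ++it) {
    find_extrema(imf, mx, mn);
    if (mx.empty() || mn.empty()) break;
    make_knots(mx, imf, n, tup, yup);
    make_knots(mn, imf, n, tlo, ylo);
    natural_spline_eval(tup, yup, n, eup);
    natural_spline_eval(tlo, ylo, n, elo);
    double num = 0.0, den = 0.0;
    for (int k = 0; k < n; ++k) {
      double m = 0.5 * (eup[k] + elo[k]);
      num += m * m;
      den += imf[k] * imf[k];
      imf[k] -= m;
    }
    if (den <= 0.0 || num / den < tol) break;
  }
  return true;
}

// [[Rcpp::export(name = ".cpp_emd")]]
List cpp_emd(NumericVector x, int max_imfs, double tol, int max_sift) {
  const int n = x.size();
  std::vector<double> res(x.begin(), x.end()), imf;
  std::vector<std::vector<double> > imfs;
  while ((int)imfs.size() < max_imfs) {
    if (!sift_imf(res, tol, max_sift, imf)) break;
    imfs.push_back(imf);
    for (int k = 0; k < n; ++k) res[k] -= imf[k];
  }
  NumericMatrix M(n, (int)imfs.size());
  for (int j = 0; j < (int)imfs.size(); ++j)
    std::copy(imfs[j].begin(), imfs[j].end(), M.column(j).begin());
  return List::create(_["imfs"] = M,
                      _["residual"] = NumericVector(res.begin(), res.end()));
}

// [[Rcpp::export(name = ".cpp_sift1")]]
List cpp_sift1(NumericVector x, double tol, int max_sift) {
  std::vector<double> xs(x.begin(), x.end()), imf;
  bool ok = sift_imf(xs, tol, max_sift, imf);
  if (!ok) return List::create(_["ok"] = false, _["imf"] = NumericVector(0));
  return List::create(_["ok"] = true,
                      _["imf"] = NumericVector(imf.begin(), imf.end()));
}
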