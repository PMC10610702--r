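#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double int_pow(double base, int e) {
  double r = 1.0;
  while (e > 0) { if (e & 1) r *= base; base *= base; e >>= 1; }
  return r;
}

static inline double pow_r2(double d, double r2) {
  int ir2 = (int) r2;
  if (r2 == (double) ir2 && ir2 >= 0 && ir2 < 64) return int_pow(d, ir2);
  return std::pow(d, r2);
}

// SampEn pair proportions: returns c(p_m, p_m1) where p_k is the fraction of
// ordered template pairs (i != j, all N-k+1 constructible length-k templates)
// with Chebyshev distance <= r.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  NumericVector out(2);
  for (int q = 0; q < 2; ++q) {
    int mm = m + q, nt = n - mm + 1;
    if (nt < 2) { out[q] = NA_REAL; continue; }
    long long cnt = 0;
    for (int i = 0; i < nt - 1; ++i)
      for (int j = i + 1; j < nt; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double dd = std::fabs(x[i + k] - x[j + k]);
          if (dd > d) d = dd;
          if (d > r) break;
        }
        if (d <= r) ++cnt;
      }
    out[q] = (double) cnt * 2.0 / ((double) nt * (nt - 1));
  }
  return out;
}

// phi^m of FuzzyEn: mean over ordered pairs i != j of exp(-(d_ij^r2)/r),
// templates mean-centred, Chebyshev distance. Direct O(N^2 m).
static double fuzzy_phi(const std::vector<double>& x, int n, int mm,
                        double r, double r2) {
  int nt = n - mm + 1;
  if (nt < 2) return NA_REAL;
  // centred templates
  std::vector<double> T((size_t) nt * mm);
  for (int i = 0; i < nt; ++i) {
    double mu = 0.0;
    for (int k = 0; k < mm; ++k) mu += x[i + k];
    mu /= mm;
    for (int k = 0; k < mm; ++k) T[(size_t) i * mm + k] = x[i + k] - mu;
  }
  double s = 0.0;
  for (int i = 0; i < nt - 1; ++i)
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      const double *a = &T[(size_t) i * mm], *b = &T[(size_t) j * mm];
      for (int k = 0; k < mm; ++k) {
        double dd = std::fabs(a[k] - b[k]);
        if (dd > d) d = dd;
      }
      s += std::exp(-pow_r2(d, r2) / r);
    }
  return s * 2.0 / ((double) nt * (nt - 1));
}

// [[Rcpp::export(name = ".fuzzyen_direct")]]
double fuzzyen_direct(NumericVector x, int m, double r, double r2) {
  std::vector<double> xv(x.begin(), x.end());
  int n = xv.size();
  double pm = fuzzy_phi(xv, n, m, r, r2);
  double pm1 = fuzzy_phi(xv, n, m + 1, r, r2);
  if (!R_finite(pm) || !R_finite(pm1) || pm <= 0 || pm1 <= 0) return NA_REAL;
  return std::log(pm) - std::log(pm1);
}

// Fast exact path for m = 1: centred 2-templates are (+u_i, -u_i) with
// u_i = (x_i - x_{i+1})/2, so d_ij = |u_i - u_j| and phi^1 == 1 identically.
// Sorted traversal skips pairs whose membership underflows below exp(-50)
// (total truncation error < 1e-13 on the pair mean).
// [[Rcpp::export(name = ".fuzzyen_m1")]]
double fuzzyen_m1(NumericVector x, double r, double r2) {
  int n = x.size();
  int nt = n - 1;
  if (nt < 2) return NA_REAL;
  std::vector<double> u(nt);
  for (int i = 0; i < nt; ++i) u[i] = 0.5 * (x[i] - x[i + 1]);
  std::sort(u.begin(), u.end());
  double cutoff = std::pow(50.0 * r, 1.0 / r2);
  double s = 0.0;
  long long within = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = u[j] - u[i];
      if (d > cutoff) break;
      s += std::exp(-pow_r2(d, r2) / r);
      ++within;
    }
  }
  (void) within;
  double phi2 = s * 2.0 / ((double) nt * (nt - 1));
  if (phi2 <= 0) return NA_REAL;
  return -std::log(phi2);
}

// CoSiEn pair proportion B(m, r): fraction of ordered pairs of non-zero-norm
// templates with angular distance acos(cos_sim)/pi <= r. Returns
// c(B, n_valid_templates).
// [[Rcpp::export(name = ".cosien_b")]]
NumericVector cosien_b(NumericVector x, int m, double r) {
  int n = x.size(), nt = n - m + 1;
  std::vector<int> valid;
  std::vector<double> norms(nt);
  for (int i = 0; i < nt; ++i) {
    double s2 = 0.0;
    for (int k = 0; k < m; ++k) s2 += x[i + k] * x[i + k];
    norms[i] = std::sqrt(s2);
    if (norms[i] > 0) valid.push_back(i);
  }
  int nv = valid.size();
  NumericVector out(2);
  out[1] = nv;
  if (nv < 2) { out[0] = NA_REAL; return out; }
  long long cnt = 0;
  for (int a = 0; a < nv - 1; ++a)
    for (int b = a + 1; b < nv; ++b) {
      int i = valid[a], j = valid[b];
      double dot = 0.0;
      for (int k = 0; k < m; ++k) dot += x[i + k] * x[j + k];
      double c = dot / (norms[i] * norms[j]);
      if (c > 1.0) c = 1.0;
      if (c < -1.0) c = -1.0;
      double ang = std::acos(c) / M_PI;
      if (ang <= r) ++cnt;
    }
  out[0] = (double) cnt * 2.0 / ((double) nv * (nv - 1));
  return out;
}
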