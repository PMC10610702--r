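#include <Rcpp.h>
using namespace Rcpp;

// Full (zero-padded) linear convolution, length n + m - 1.
// [[Rcpp::export(name = ".conv_full")]]
NumericVector conv_full(NumericVector x, NumericVector f) {
  int n = x.size(), m = f.size();
  NumericVector y(n + m - 1);
  for (int j = 0; j < m; ++j) {
    double fj = f[j];
    if (fj == 0.0) continue;
    for (int i = 0; i < n; ++i) y[i + j] += fj * x[i];
  }
  return y;
}

// IIR filter, direct form II transposed, with initial state zi (length nf-1).
// b and a must be padded to common length nf and normalised so a[0] == 1.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x,
                         NumericVector zi) {
  int nf = b.size(), n = x.size();
  std::vector<double> z(zi.begin(), zi.end());
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nf > 1 ? z[0] : 0.0);
    for (int k = 0; k < nf - 2; ++k)
      z[k] = b[k + 1] * xi + z[k + 1] - a[k + 1] * yi;
    if (nf > 1) z[nf - 2] = b[nf - 1] * xi - a[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
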