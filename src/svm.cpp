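#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// C-SVC dual solver: sequential minimal optimisation with second-order
// working-set selection (LIBSVM-style WSS2) on a precomputed kernel matrix.
// Labels y in {-1, +1}. Returns alpha, bias b, and iteration count.
// Decision value for a point z is sum_t alpha_t y_t K(x_t, z) + b.
// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-3, int max_iter = 200000) {
  int n = y.size();
  std::vector<double> alpha(n, 0.0), u(n, 0.0); // u_t = sum_s alpha_s y_s K_st
  int iter = 0;
  double lo = 0.0, hi = 0.0;
  bool converged = false;
  const double TAU = 1e-12;
  while (iter < max_iter) {
    int i = -1;
    double gmax = -HUGE_VAL, gmin = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double g = y[t] - u[t]; // = b at optimum for free SVs
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (up && g > gmax) { gmax = g; i = t; }
      if (low && g < gmin) gmin = g;
    }
    hi = gmax; lo = gmin;
    if (i < 0 || gmax - gmin < tol) { converged = true; break; }
    // second-order choice of j among violating I_low
    int j = -1;
    double best = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (!low) continue;
      double g = y[t] - u[t];
      double diff = gmax - g;
      if (diff <= 0) continue;
      double eta = K(i, i) + K(t, t) - 2.0 * K(i, t);
      if (eta <= TAU) eta = TAU;
      double obj = -(diff * diff) / eta;
      if (obj < best) { best = obj; j = t; }
    }
    if (j < 0) { converged = true; break; }
    double Ei = u[i] - y[i], Ej = u[j] - y[j];
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= TAU) eta = TAU;
    double ai = alpha[i], aj = alpha[j];
    double L, H;
    if (y[i] != y[j]) { L = std::max(0.0, aj - ai); H = std::min(C, C + aj - ai); }
    else              { L = std::max(0.0, ai + aj - C); H = std::min(C, ai + aj); }
    double ajn = aj + y[j] * (Ei - Ej) / eta;
    if (ajn < L) ajn = L;
    if (ajn > H) ajn = H;
    double ain = ai + y[i] * y[j] * (aj - ajn);
    // snap to the box: clipped updates otherwise leave ~1e-17 residues that
    // keep a variable in the working set and cycle a zero-progress pair
    const double snap = 1e-12 * (1.0 + C);
    if (ajn < snap) ajn = 0.0; else if (ajn > C - snap) ajn = C;
    if (ain < snap) ain = 0.0; else if (ain > C - snap) ain = C;
    if (ain == ai && ajn == aj) break;  // no representable progress left
    double di = (ain - ai) * y[i], dj = (ajn - aj) * y[j];
    if (di != 0.0 || dj != 0.0)
      for (int t = 0; t < n; ++t) u[t] += di * K(i, t) + dj * K(j, t);
    alpha[i] = ain; alpha[j] = ajn;
    ++iter;
  }
  double b = (hi + lo) / 2.0;
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = converged);
}
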