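// Sequential minimal optimization for the soft-margin C-SVC dual with a
// precomputed kernel matrix. Working-set selection is the maximal
// violating pair; per-sample box constraints allow class weighting.
//
// Dual: min_a 1/2 a'Qa - e'a,  0 <= a_i <= C_i,  y'a = 0,
// with Q_ij = y_i y_j K_ij. Decision f(x) = sum_i a_i y_i K(x_i, x) + b.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double TAU = 1e-12;

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, IntegerVector y, NumericVector Cvec,
               double eps = 1e-3, int max_iter = 10000000) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int iter = 0;
  double m_val = 0, M_val = 0;

  while (iter < max_iter) {
    // maximal violating pair
    int i = -1, j = -1;
    m_val = -1e300; M_val = 1e300;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] == 1 && alpha[t] < Cvec[t]) ||
                (y[t] == -1 && alpha[t] > 0);
      bool low = (y[t] == 1 && alpha[t] > 0) ||
                 (y[t] == -1 && alpha[t] < Cvec[t]);
      if (up && v > m_val) { m_val = v; i = t; }
      if (low && v < M_val) { M_val = v; j = t; }
    }
    if (i < 0 || j < 0 || m_val - M_val < eps) break;

    const double Ci = Cvec[i], Cj = Cvec[j];
    const double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > Ci - Cj) {
        if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = Ci - diff; }
      } else {
        if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = Cj + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > Ci) { if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = sum - Ci; } }
      else          { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > Cj) { if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = sum - Cj; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai != 0.0 || daj != 0.0) {
      for (int t = 0; t < n; ++t)
        G[t] += y[t] * (y[i] * K(i, t) * dai + y[j] * K(j, t) * daj);
    }
    ++iter;
  }

  // bias: average of -y_i G_i over free support vectors, else midpoint
  double b = 0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-12 && alpha[t] < Cvec[t] - 1e-12) {
      b += -y[t] * G[t]; ++nfree;
    }
  }
  if (nfree > 0) b /= nfree; else b = (m_val + M_val) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
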