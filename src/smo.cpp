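#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Soft-margin C-SVC dual on a precomputed Gram matrix K (linear kernel):
//
//   min_a  1/2 a' Q a - e' a    s.t.  0 <= a_i <= C,  y' a = 0
//   Q_ij = y_i y_j K_ij
//
// solved by sequential minimal optimization with maximal-violating-pair
// working-set selection. The bias b is unpenalized (handled through the
// equality constraint), matching the classical SVM primal
//   1/2 ||w||^2 + C * sum_i max(0, 1 - y_i (w x_i + b)).
//
// Working on K rather than on the feature matrix lets the recursive
// feature elimination loop downdate K by a rank-r update when voxels are
// discarded, instead of recomputing the kernel at every retrain.
//
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-8, int max_iter = 2000000) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("K must be square");
  if (y.size() != n) stop("length(y) must equal nrow(K)");
  if (!(C > 0)) stop("C must be positive");

  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient of the dual objective
  const double *Kp = K.begin();

  int it = 0;
  double gmax = 0.0, gmin = 0.0;
  for (it = 0; it < max_iter; ++it) {
    // working-set selection: i is the maximal violator in I_up; j is chosen
    // in I_low by the second-order gain heuristic (largest decrease of the
    // quadratic model along the pair direction)
    gmax = -HUGE_VAL; gmin = HUGE_VAL;
    int i = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) gmin = v;
    }
    if (i < 0 || gmax - gmin < tol) break;

    const double *Ki = Kp + (std::size_t)i * n;
    int j = -1;
    double best_gain = -1.0;
    for (int t = 0; t < n; ++t) {
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (!low) continue;
      const double bdiff = gmax - (-y[t] * G[t]);
      if (bdiff <= 0) continue;
      double a = Ki[i] + Kp[(std::size_t)t * n + t] - 2.0 * Ki[t];
      if (a <= 1e-12) a = 1e-12;
      const double gain = bdiff * bdiff / a;
      if (gain > best_gain) { best_gain = gain; j = t; }
    }
    if (j < 0) break;

    // feasible direction d_i = y_i, d_j = -y_j keeps y'a constant
    const double *Kj = Kp + (std::size_t)j * n;
    double quad = Ki[i] + Kj[j] - 2.0 * Ki[j];
    if (quad <= 1e-12) quad = 1e-12;
    double step = (gmax - (-y[j] * G[j])) / quad;

    // box constraints on the step length
    const double cap_i = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    const double cap_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    if (step > cap_i) step = cap_i;
    if (step > cap_j) step = cap_j;
    if (step <= 0) break;  // numerically stuck at a box corner

    const double dai = y[i] * step;   // change in alpha_i
    const double daj = -y[j] * step;  // change in alpha_j
    alpha[i] += dai;
    alpha[j] += daj;

    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * Ki[t] * dai + y[j] * Kj[t] * daj);
  }

  // bias from the KKT conditions: average of y_t - f_raw_t over free vectors
  double bsum = 0.0; int bfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 0 && alpha[t] < C) { bsum += -y[t] * G[t]; ++bfree; }
  }
  double b = bfree > 0 ? bsum / bfree : 0.5 * (gmax + gmin);

  // dual objective value: sum(a) - 1/2 a'Qa = sum(a) + 1/2 sum(a_t (G_t - ... ))
  // use G = Qa - e  =>  a'Qa = a'(G + e)
  double aQa = 0.0, asum = 0.0;
  for (int t = 0; t < n; ++t) { aQa += alpha[t] * (G[t] + 1.0); asum += alpha[t]; }
  const double dual_obj = asum - 0.5 * aQa;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["bias"] = b,
                      _["iterations"] = it,
                      _["dual_objective"] = dual_obj,
                      _["kkt_gap"] = gmax - gmin);
}
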