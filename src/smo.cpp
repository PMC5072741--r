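#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for the generic dual
//
//   min_a  1/2 a' Q a + p' a,   Q_ij = y_i y_j K_ij
//   s.t.   y' a = delta,  0 <= a_i <= C_i
//
// with maximal-violating-pair working-set selection and the LIBSVM stopping
// rule m(a) - M(a) < eps. Covers both the soft-margin binary machine
// (p = -1, delta = 0, a = 0 feasible) and the one-class nu-formulation
// (p = 0, y = +1, sum a = 1, C_i = 1/(nu n)). The caller passes a feasible
// starting point. Returns alpha, the decision bias (so that
// f(x) = sum_i y_i a_i K(x_i, x) + bias), and convergence diagnostics.
//
// [[Rcpp::export(name = ".smo_solve_cpp")]]
List smo_solve_cpp(NumericMatrix K, IntegerVector y, NumericVector p,
                   NumericVector C, NumericVector alpha0, double eps,
                   int max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n || p.size() != n || C.size() != n ||
      alpha0.size() != n)
    stop("smo: inconsistent problem dimensions");
  std::vector<double> a(alpha0.begin(), alpha0.end());
  // gradient G_i = sum_j Q_ij a_j + p_i
  std::vector<double> G(n);
  for (int i = 0; i < n; ++i) {
    double g = p[i];
    for (int j = 0; j < n; ++j)
      if (a[j] != 0.0) g += (double)y[i] * (double)y[j] * K(i, j) * a[j];
    G[i] = g;
  }
  const double TAU = 1e-12;
  int iter = 0;
  bool converged = false;
  while (iter < max_iter) {
    // I_up: a_i < C_i with y=+1, or a_i > 0 with y=-1 (can move "up"
    // along y); I_low the mirror image.
    int i_up = -1, j_low = -1;
    double m_up = -HUGE_VAL, m_low = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double v = -(double)y[t] * G[t];
      bool in_up = (y[t] == 1) ? (a[t] < C[t] - TAU) : (a[t] > TAU);
      bool in_low = (y[t] == 1) ? (a[t] > TAU) : (a[t] < C[t] - TAU);
      if (in_up && v > m_up) { m_up = v; i_up = t; }
      if (in_low && v < m_low) { m_low = v; j_low = t; }
    }
    if (i_up < 0 || j_low < 0 || m_up - m_low < eps) { converged = true; break; }
    int i = i_up, j = j_low;
    double s = (double)y[i] * (double)y[j];
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 0) eta = TAU;
    // Newton step on a_i along the feasible pair direction
    // (da_j = -s * da_i); dObj/da_i = G_i - s G_j. Clip to the box after.
    double step = -(G[i] - s * G[j]) / eta;
    double ai_old = a[i], aj_old = a[j];
    double ai_new = ai_old + step;
    // box bounds on a_i induced by a_j = aj_old - s (a_i - ai_old)
    double lo = 0.0, hi = C[i];
    if (s > 0) {  // a_i + a_j conserved... a_j decreases as a_i grows
      lo = std::max(lo, ai_old + aj_old - C[j]);
      hi = std::min(hi, ai_old + aj_old);
    } else {      // a_i - a_j conserved
      lo = std::max(lo, ai_old - aj_old);
      hi = std::min(hi, C[j] + ai_old - aj_old);
    }
    if (ai_new < lo) ai_new = lo;
    if (ai_new > hi) ai_new = hi;
    double dai = ai_new - ai_old;
    if (std::fabs(dai) < TAU) { ++iter; continue; }
    double daj = -s * dai;
    a[i] = ai_new;
    a[j] = aj_old + daj;
    for (int t = 0; t < n; ++t)
      G[t] += (double)y[t] * ((double)y[i] * K(t, i) * dai +
                              (double)y[j] * K(t, j) * daj);
    ++iter;
  }
  // bias: for a free SV, -y_i G_i equals the bias of
  // f(x) = sum y_i a_i K + bias; average over free, else midpoint of bounds.
  double bias_sum = 0.0;
  int nfree = 0;
  double m_up = -HUGE_VAL, m_low = HUGE_VAL;
  for (int t = 0; t < n; ++t) {
    double v = -(double)y[t] * G[t];
    bool in_up = (y[t] == 1) ? (a[t] < C[t] - TAU) : (a[t] > TAU);
    bool in_low = (y[t] == 1) ? (a[t] > TAU) : (a[t] < C[t] - TAU);
    if (in_up && v > m_up) m_up = v;
    if (in_low && v < m_low) m_low = v;
    if (a[t] > TAU && a[t] < C[t] - TAU) { bias_sum += v; ++nfree; }
  }
  double bias = nfree > 0 ? bias_sum / nfree : 0.5 * (m_up + m_low);
  return List::create(_["alpha"] = wrap(a), _["bias"] = bias,
                      _["iterations"] = iter, _["converged"] = converged);
}
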