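#include <Rcpp.h>
using namespace Rcpp;

// Binary C-SVC dual solver (SMO with maximal-violating-pair selection).
//
// Minimises 0.5 a' Q a - e' a subject to 0 <= a_i <= C, y' a = 0, where
// Q_ij = y_i y_j K_ij. Selection and the stopping rule follow the usual
// first-order working-set criterion: with f_i = sum_j a_j y_j K_ij,
//   m = max_{i in I_up} (y_i - f_i),  M = min_{j in I_low} (y_j - f_j),
// stop when m - M < tol; the bias is b = (m + M) / 2 at the solution.
//
// K is the full kernel matrix of the training points (symmetric PSD),
// y in {-1, +1}. Returns alpha, b and the iteration count.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, IntegerVector y, double C,
               double tol = 1e-3, int max_iter = 100000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("kernel matrix must be square and match the label length");

  std::vector<double> alpha(n, 0.0), f(n, 0.0);
  int iter = 0;
  double m = 0.0, M = 0.0;

  for (iter = 0; iter < max_iter; ++iter) {
    // working-set selection: maximal violating pair
    int i = -1, j = -1;
    m = -std::numeric_limits<double>::infinity();
    M = std::numeric_limits<double>::infinity();
    const double eps = 1e-10 * C;
    for (int t = 0; t < n; ++t) {
      const double g = y[t] - f[t];
      const bool up = (y[t] == 1 && alpha[t] < C - eps) ||
                      (y[t] == -1 && alpha[t] > eps);
      const bool lo = (y[t] == -1 && alpha[t] < C - eps) ||
                      (y[t] == 1 && alpha[t] > eps);
      if (up && g > m) { m = g; i = t; }
      if (lo && g < M) { M = g; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) break;

    // analytic two-variable solve on (i, j)
    const double Ei = f[i] - y[i], Ej = f[j] - y[j];
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 0) eta = 1e-12;

    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    }
    double aj = alpha[j] + y[j] * (Ei - Ej) / eta;
    aj = std::min(H, std::max(L, aj));
    double ai = alpha[i] + y[i] * y[j] * (alpha[j] - aj);
    // snap to the box: round-off residues (e.g. C - 2e-16) would otherwise
    // leave a maximal-violating pair unable to move
    const double snap = 1e-10 * C;
    if (aj < snap) aj = 0.0; else if (C - aj < snap) aj = C;
    if (ai < snap) ai = 0.0; else if (C - ai < snap) ai = C;

    const double di = (ai - alpha[i]) * y[i];
    const double dj = (aj - alpha[j]) * y[j];
    if (std::abs(di) < 1e-15 && std::abs(dj) < 1e-15) break;  // numerically stuck
    alpha[i] = ai;
    alpha[j] = aj;
    for (int t = 0; t < n; ++t) f[t] += di * K(i, t) + dj * K(j, t);
  }

  const double b = (std::isfinite(m) && std::isfinite(M)) ? (m + M) / 2.0 : 0.0;
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = (m - M < tol));
}
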