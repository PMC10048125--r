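#include <Rcpp.h>
using namespace Rcpp;

// SMO solver for the C-SVC dual with a precomputed kernel matrix:
//
//   min_a  0.5 a' Q a - e' a,   Q_ij = y_i y_j K_ij
//   s.t.   0 <= a_i <= C,  sum_i y_i a_i = 0
//
// Second-order working-set selection (maximal violating pair with
// second-order gain for the partner), as in Fan, Chen & Lin (2005) and
// libsvm.  The kernel is passed explicitly so callers can amortize one
// Gram computation across many fits (grid scans, cross-validation folds).

static const double TAU = 1e-12;

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-3, int max_iter = 0) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("y length must match kernel dimension");
  if (max_iter <= 0) max_iter = std::max(10000000, 100 * n);

  std::vector<double> alpha(n, 0.0);
  // gradient of the objective: grad_i = (Q a)_i - 1; at a = 0 it is -1
  std::vector<double> grad(n, -1.0);

  auto Q = [&](int i, int j) { return y[i] * y[j] * K(i, j); };

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working-set selection
    int i = -1;
    double Gmax = -std::numeric_limits<double>::infinity();
    double Gmax2 = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      if (up && -y[t] * grad[t] > Gmax) {
        Gmax = -y[t] * grad[t];
        i = t;
      }
    }
    if (i == -1) break;  // no ascent direction: at the box boundary optimum
    int j = -1;
    double obj_min = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (!low) continue;
      double grad_diff = Gmax + y[t] * grad[t];
      if (y[t] * grad[t] > Gmax2) Gmax2 = y[t] * grad[t];
      if (grad_diff > 0) {
        double quad = Q(i, i) + Q(t, t) - 2.0 * y[i] * y[t] * Q(i, t);
        if (quad <= 0) quad = TAU;
        double obj = -(grad_diff * grad_diff) / quad;
        if (obj < obj_min) {
          obj_min = obj;
          j = t;
        }
      }
    }
    if (Gmax + Gmax2 < tol || j == -1) break;

    // analytic two-variable update, then clip to the box keeping
    // y_i a_i + y_j a_j constant
    double old_ai = alpha[i], old_aj = alpha[j];
    if (y[i] != y[j]) {
      double quad = Q(i, i) + Q(j, j) + 2.0 * Q(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-grad[i] - grad[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0 && alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      else if (diff <= 0 && alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Q(i, i) + Q(j, j) - 2.0 * Q(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (grad[i] - grad[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
        else if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        else if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) break;  // numerically stuck: KKT-optimal
    for (int t = 0; t < n; ++t)
      grad[t] += Q(t, i) * dai + Q(t, j) * daj;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
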