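// Sequential minimal optimization for the C-SVC dual on a precomputed
// kernel matrix. Working-set selection is the second-order rule
// (maximal violating pair i, then the j minimizing the quadratic gain),
// stopping when the KKT violation drops below eps. Both classes share the
// same box constraint C (no class weighting).

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static const double TAU = 1e-12;

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, double C,
               double eps = 1e-3, int max_iter = 0) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("label length does not match kernel size");
  if (max_iter <= 0) max_iter = std::max(10000000 / std::max(n, 1), 100000);

  std::vector<double> alpha(n, 0.0), G(n, -1.0), QD(n);
  const double *Kp = K.begin();
  for (int t = 0; t < n; ++t) QD[t] = Kp[(size_t)t * n + t];

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // select i: maximal -y_t G_t over I_up
    double Gmax = -DBL_MAX, Gmax2 = -DBL_MAX;
    int i = -1;
    for (int t = 0; t < n; ++t) {
      if (y[t] == 1) {
        if (alpha[t] < C && -G[t] >= Gmax) { Gmax = -G[t]; i = t; }
      } else {
        if (alpha[t] > 0 && G[t] >= Gmax) { Gmax = G[t]; i = t; }
      }
    }
    if (i < 0) break;
    const double *Ki = Kp + (size_t)i * n; // column i (K symmetric)

    // select j: minimal obj_diff over I_low with positive violation
    int j = -1;
    double obj_min = DBL_MAX;
    for (int t = 0; t < n; ++t) {
      bool in_low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      if (!in_low) continue;
      double yG = y[t] * G[t];
      if (yG >= Gmax2) Gmax2 = yG;
      double grad_diff = Gmax + yG;
      if (grad_diff > 0) {
        double quad = QD[i] + QD[t] - 2.0 * Ki[t];
        if (quad <= 0) quad = TAU;
        double obj = -(grad_diff * grad_diff) / quad;
        if (obj <= obj_min) { obj_min = obj; j = t; }
      }
    }
    if (Gmax + Gmax2 < eps || j < 0) break;

    const double *Kj = Kp + (size_t)j * n;
    double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double quad = QD[i] + QD[j] - 2.0 * Ki[j];
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = QD[i] + QD[j] - 2.0 * Ki[j];
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    // update gradient: G_t += Q_ti dai + Q_tj daj, Q_ti = y_t y_i K_ti
    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * Ki[t] * dai + y[j] * Kj[t] * daj);
    }
  }

  // rho from KKT conditions (libsvm calculate_rho)
  double ub = DBL_MAX, lb = -DBL_MAX, sum_free = 0.0;
  int nr_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= C) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 0) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++nr_free; sum_free += yG;
    }
  }
  double rho = nr_free > 0 ? sum_free / nr_free : (ub + lb) / 2.0;

  // training decision values: f_t = sum_j alpha_j y_j K_tj - rho
  //                              = y_t * (G_t + 1) - rho
  NumericVector decision(n), alpha_out(n);
  for (int t = 0; t < n; ++t) {
    decision[t] = y[t] * (G[t] + 1.0) - rho;
    alpha_out[t] = alpha[t];
  }

  return List::create(_["alpha"] = alpha_out, _["rho"] = rho,
                      _["iterations"] = iter, _["decision"] = decision);
}
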