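// Compact C-SVC solver (SMO with second-order working-set selection,
// LIBSVM-style) operating on precomputed kernel matrices.  Training sets in
// this package are tiny (n <= ~70 subjects), so the full kernel is always
// materialized and gradients kept dense.  The leave-one-out helper
// warm-starts every held-out subproblem from the full-data solution, which
// is what makes the nested-LOO forward selection affordable.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

struct SmoResult {
  arma::vec alpha;
  double rho;
  int iter;
};

// Minimize 1/2 a' Q a - e' a  s.t.  y'a = 0, 0 <= a <= C,  Q_ij = y_i y_j K_ij.
// alpha0 may carry a warm start (it is clipped to the box; the equality
// constraint is restored by projection onto feasibility via a simple repair).
static SmoResult smo_solve(const arma::mat& K, const arma::ivec& y, double C,
                           double eps = 1e-3, int max_iter = 20000,
                           const arma::vec* alpha0 = nullptr) {
  const int n = K.n_rows;
  arma::vec alpha(n, arma::fill::zeros);
  if (alpha0 && (int)alpha0->n_elem == n) {
    alpha = arma::clamp(*alpha0, 0.0, C);
    // repair y'a = 0 by shifting mass off the violating side
    double s = arma::dot(alpha, arma::conv_to<arma::vec>::from(y));
    for (int t = 0; t < n && std::abs(s) > 1e-12; ++t) {
      double adj = y[t] * s;               // reduce alpha_t by adj if possible
      double lo = 0.0, hi = C;
      double newa = std::min(hi, std::max(lo, alpha[t] - adj));
      s += y[t] * (newa - alpha[t]);
      alpha[t] = newa;
    }
  }

  arma::vec yv = arma::conv_to<arma::vec>::from(y);
  arma::vec G(n);
  if (arma::any(alpha > 0)) {
    arma::vec coef = alpha % yv;
    G = yv % (K * coef) - 1.0;             // Q a - e
  } else {
    G.fill(-1.0);
  }

  const double TAU = 1e-12;
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // second-order working-set selection
    double Gmax = -std::numeric_limits<double>::infinity();
    double Gmax2 = -std::numeric_limits<double>::infinity();
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      if (up && -y[t] * G[t] >= Gmax) { Gmax = -y[t] * G[t]; i = t; }
    }
    if (i < 0) break;
    double obj_min = 0.0;
    for (int t = 0; t < n; ++t) {
      bool lo = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
      if (!lo) continue;
      double v = y[t] * G[t];
      if (v > Gmax2) Gmax2 = v;
      double grad_diff = Gmax + v;
      if (grad_diff > 0) {
        double quad = K(i, i) + K(t, t) - 2.0 * K(i, t);
        if (quad <= 0) quad = TAU;
        double obj = -(grad_diff * grad_diff) / quad;
        if (obj <= obj_min) { obj_min = obj; j = t; }
      }
    }
    if (j < 0 || Gmax + Gmax2 < eps) break;

    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = TAU;
    double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
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

    double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    if (dai != 0.0 || daj != 0.0) {
      for (int t = 0; t < n; ++t)
        G[t] += y[t] * (K(t, i) * y[i] * dai + K(t, j) * y[j] * daj);
    }
  }

  // rho: average y_i G_i over free SVs; else midpoint of the bounds.
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  double sum_free = 0; int n_free = 0;
  for (int t = 0; t < n; ++t) {
    double v = y[t] * G[t];
    if (alpha[t] > 0 && alpha[t] < C) { sum_free += v; ++n_free; }
    else {
      bool up = (y[t] == 1 && alpha[t] <= 0) || (y[t] == -1 && alpha[t] >= C);
      if (up) ub = std::min(ub, v); else lb = std::max(lb, v);
    }
  }
  double rho = n_free > 0 ? sum_free / n_free
                          : (std::isfinite(ub) && std::isfinite(lb) ? (ub + lb) / 2 : 0.0);
  SmoResult res; res.alpha = alpha; res.rho = rho; res.iter = iter;
  return res;
}

// [[Rcpp::export(name = ".svm_fit_cpp")]]
List svm_fit_cpp(const arma::mat& K, const arma::ivec& y, double C,
                 double eps = 1e-3, int max_iter = 20000) {
  SmoResult r = smo_solve(K, y, C, eps, max_iter);
  arma::vec coef = r.alpha % arma::conv_to<arma::vec>::from(y);
  arma::vec f = K * coef - r.rho;
  return List::create(_["alpha"] = r.alpha, _["rho"] = r.rho,
                      _["coef"] = coef, _["decision"] = f,
                      _["iterations"] = r.iter);
}

// Leave-one-out accuracy on a precomputed kernel: for each sample, fit on
// the rest (warm-started from the full-data solution) and predict the
// held-out one.  Returns the fraction correct.
// [[Rcpp::export(name = ".svm_loo_acc_cpp")]]
double svm_loo_acc_cpp(const arma::mat& K, const arma::ivec& y, double C,
                       double eps = 1e-3, int max_iter = 20000) {
  const int n = K.n_rows;
  SmoResult full = smo_solve(K, y, C, eps, max_iter);
  int correct = 0;
  arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
  for (int h = 0; h < n; ++h) {
    arma::uvec keep = arma::find(all != (unsigned)h);
    arma::mat Ks = K.submat(keep, keep);
    arma::ivec ys = y.elem(keep);
    arma::vec a0 = full.alpha.elem(keep);
    SmoResult r = smo_solve(Ks, ys, C, eps, max_iter, &a0);
    arma::vec coef = r.alpha % arma::conv_to<arma::vec>::from(ys);
    arma::vec krow(n - 1);
    for (int t = 0; t < n - 1; ++t) krow[t] = K(h, keep[t]);
    double f = arma::dot(krow, coef) - r.rho;
    int pred = f > 0 ? 1 : -1;
    if (pred == y[h]) ++correct;
  }
  return (double)correct / n;
}
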