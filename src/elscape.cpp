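#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gradient-ascent fit of the pairwise maximum-entropy model by exact moment
// matching: gradient = empirical moments - model moments, where model moments
// are computed by full enumeration over the 2^C states in S (rows of +-1).
// Stops when the largest absolute parameter update falls below tol.
// [[Rcpp::export]]
List cpp_fit_exact(const NumericMatrix& S, const NumericVector& act_e,
                   const NumericMatrix& cooc_e, double lr, double tol,
                   int max_iter) {
  const int n_states = S.nrow(), C = S.ncol();
  NumericVector h(C);
  NumericMatrix J(C, C);
  std::vector<double> E(n_states), P(n_states);
  double max_upd = R_PosInf;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    // energies and Boltzmann probabilities
    double Emin = R_PosInf;
    for (int i = 0; i < n_states; ++i) {
      double e = 0.0;
      for (int m = 0; m < C; ++m) {
        double sm = S(i, m);
        e -= h[m] * sm;
        for (int n = m + 1; n < C; ++n) e -= J(m, n) * sm * S(i, n);
      }
      E[i] = e;
      if (e < Emin) Emin = e;
    }
    double Z = 0.0;
    for (int i = 0; i < n_states; ++i) { P[i] = std::exp(-(E[i] - Emin)); Z += P[i]; }
    for (int i = 0; i < n_states; ++i) P[i] /= Z;
    // model moments
    max_upd = 0.0;
    for (int m = 0; m < C; ++m) {
      double am = 0.0;
      for (int i = 0; i < n_states; ++i) am += S(i, m) * P[i];
      double upd = lr * (act_e[m] - am);
      h[m] += upd;
      if (std::fabs(upd) > max_upd) max_upd = std::fabs(upd);
    }
    for (int m = 0; m < C; ++m) {
      for (int n = m + 1; n < C; ++n) {
        double cmn = 0.0;
        for (int i = 0; i < n_states; ++i) cmn += S(i, m) * S(i, n) * P[i];
        double upd = lr * (cooc_e(m, n) - cmn);
        J(m, n) += upd;
        J(n, m) = J(m, n);
        if (std::fabs(upd) > max_upd) max_upd = std::fabs(upd);
      }
    }
    if (max_upd < tol) { ++iter; break; }
  }
  return List::create(_["h"] = h, _["J"] = J, _["iterations"] = iter,
                      _["final_update"] = max_upd,
                      _["converged"] = max_upd < tol);
}

// Pseudo-likelihood gradient ascent on weighted unique states.  S holds the
// distinct observed spin vectors (rows, +-1), w their relative frequencies
// (summing to 1).  The objective is the mean per-sample log pseudo-likelihood
// sum_m log P(sigma_m | rest); full-batch updates with fixed learning rate.
// [[Rcpp::export]]
List cpp_fit_pl(const NumericMatrix& S, const NumericVector& w, double lr,
                double tol, int max_iter) {
  const int n_states = S.nrow(), C = S.ncol();
  NumericVector h(C);
  NumericMatrix J(C, C);
  NumericVector gh(C);
  NumericMatrix gJ(C, C);
  NumericMatrix th(n_states, C);  // tanh(h_m + sum_n J_mn s_n) per state
  double max_upd = R_PosInf;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    for (int i = 0; i < n_states; ++i)
      for (int m = 0; m < C; ++m) {
        double t = h[m];
        for (int n = 0; n < C; ++n) if (n != m) t += J(m, n) * S(i, n);
        th(i, m) = std::tanh(t);
      }
    std::fill(gh.begin(), gh.end(), 0.0);
    std::fill(gJ.begin(), gJ.end(), 0.0);
    for (int i = 0; i < n_states; ++i) {
      for (int m = 0; m < C; ++m) {
        double res = w[i] * (S(i, m) - th(i, m));
        gh[m] += res;
        for (int n = m + 1; n < C; ++n)
          gJ(m, n) += res * S(i, n) + w[i] * (S(i, n) - th(i, n)) * S(i, m);
      }
    }
    max_upd = 0.0;
    for (int m = 0; m < C; ++m) {
      double upd = lr * gh[m];
      h[m] += upd;
      if (std::fabs(upd) > max_upd) max_upd = std::fabs(upd);
      for (int n = m + 1; n < C; ++n) {
        double updJ = lr * gJ(m, n);
        J(m, n) += updJ;
        J(n, m) = J(m, n);
        if (std::fabs(updJ) > max_upd) max_upd = std::fabs(updJ);
      }
    }
    if (max_upd < tol) { ++iter; break; }
  }
  return List::create(_["h"] = h, _["J"] = J, _["iterations"] = iter,
                      _["final_update"] = max_upd,
                      _["converged"] = max_upd < tol);
}

// Metropolis random walk on the C-dimensional hypercube: propose a uniformly
// chosen Hamming-1 neighbour; move if its energy is lower, otherwise move
// with probability exp(E_current - E_proposed).  States are 0-based codes;
// uses R's RNG so set.seed() on the R side makes runs reproducible.
// [[Rcpp::export]]
IntegerVector cpp_random_walk(const NumericVector& E, int C, int n_steps,
                              int start) {
  IntegerVector traj(n_steps);
  int cur = start;
  for (int t = 0; t < n_steps; ++t) {
    int b = (int)std::floor(unif_rand() * C);
    if (b >= C) b = C - 1;
    int prop = cur ^ (1 << b);
    double dE = E[prop] - E[cur];
    if (dE < 0.0 || unif_rand() < std::exp(-dE)) cur = prop;
    traj[t] = cur;
  }
  return traj;
}

// Sequential minimal optimization for the soft-margin kernel SVM dual with
// per-sample box constraints Cbox (class-balanced weighting).  Deterministic:
// first KKT violator paired with the max-|E_i - E_j| partner.
// [[Rcpp::export]]
List cpp_smo(const NumericMatrix& K, const NumericVector& y,
             const NumericVector& Cbox, double tol, int max_passes) {
  const int n = K.nrow();
  NumericVector alpha(n);
  double b = 0.0;
  std::vector<double> Err(n);
  for (int i = 0; i < n; ++i) Err[i] = -y[i];  // f(x_i)=0 initially
  for (int sweep = 0; sweep < max_passes; ++sweep) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      double ri = Err[i] * y[i];
      if ((ri < -tol && alpha[i] < Cbox[i]) || (ri > tol && alpha[i] > 0)) {
        // partner: largest |E_i - E_j|
        int j = -1;
        double best = -1.0;
        for (int jj = 0; jj < n; ++jj) {
          if (jj == i) continue;
          double d = std::fabs(Err[i] - Err[jj]);
          if (d > best) { best = d; j = jj; }
        }
        if (j < 0) continue;
        double ai_old = alpha[i], aj_old = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          double g = aj_old - ai_old;
          L = std::max(0.0, g);
          H = std::min(Cbox[j], Cbox[i] + g);
        } else {
          double g = ai_old + aj_old;
          L = std::max(0.0, g - Cbox[i]);
          H = std::min(Cbox[j], g);
        }
        if (H - L < 1e-12) continue;
        double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
        if (eta >= 0) continue;
        double aj = aj_old - y[j] * (Err[i] - Err[j]) / eta;
        if (aj > H) aj = H;
        if (aj < L) aj = L;
        if (std::fabs(aj - aj_old) < 1e-7) continue;
        double ai = ai_old + y[i] * y[j] * (aj_old - aj);
        alpha[i] = ai;
        alpha[j] = aj;
        double b1 = b - Err[i] - y[i] * (ai - ai_old) * K(i, i) -
                    y[j] * (aj - aj_old) * K(i, j);
        double b2 = b - Err[j] - y[i] * (ai - ai_old) * K(i, j) -
                    y[j] * (aj - aj_old) * K(j, j);
        double b_new;
        if (ai > 0 && ai < Cbox[i]) b_new = b1;
        else if (aj > 0 && aj < Cbox[j]) b_new = b2;
        else b_new = 0.5 * (b1 + b2);
        double db = b_new - b;
        b = b_new;
        for (int t = 0; t < n; ++t)
          Err[t] += y[i] * (ai - ai_old) * K(t, i) +
                    y[j] * (aj - aj_old) * K(t, j) + db;
        ++changed;
      }
    }
    if (changed == 0) break;  // one clean pass: KKT satisfied within tol
  }
  return List::create(_["alpha"] = alpha, _["b"] = b);
}
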