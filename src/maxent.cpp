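#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// L1-penalized maximum-entropy (Gibbs) density over background cells.
//
// Maximizes  L(lambda) = lambda . fbar - log(Z/n) - sum_j beta_j |lambda_j|
// where Z = sum_i exp(lambda . f_i) over the n background rows and fbar is
// the presence mean of each feature. Cyclic coordinate descent: Newton step
// with soft-thresholding, then backtracking halvings so the penalized
// objective never decreases. At a beta = 0 optimum the background expectation
// of every feature equals its presence mean (KKT); with beta_j > 0 the
// mismatch is bounded by beta_j.

// [[Rcpp::export]]
List cpp_maxent_cd(NumericMatrix F, NumericVector fbar, NumericVector beta,
                   int max_sweeps, double tol, double obj_tol,
                   Nullable<NumericVector> lambda0 = R_NilValue) {
  int n = F.nrow(), d = F.ncol();
  std::vector<double> lambda(d, 0.0), eta(n, 0.0), w(n, 1.0);
  double Z = n;
  double obj = 0.0; // lambda = 0: fbar term 0, log(Z/n) = 0, penalty 0
  if (lambda0.isNotNull()) { // warm start
    NumericVector l0(lambda0);
    double emax = -1e300;
    for (int i = 0; i < n; ++i) {
      double e = 0.0;
      for (int j = 0; j < d; ++j) e += l0[j] * F(i, j);
      eta[i] = e;
      emax = std::max(emax, e);
    }
    Z = 0.0;
    for (int i = 0; i < n; ++i) {
      eta[i] -= emax;
      w[i] = std::exp(eta[i]);
      Z += w[i];
    }
    obj = -std::log(Z / n) - emax;
    for (int j = 0; j < d; ++j) {
      lambda[j] = l0[j];
      obj += l0[j] * fbar[j] - beta[j] * std::fabs(l0[j]);
    }
  }
  std::vector<double> trace, scratch(n);
  bool converged = false;
  int sweeps_done = 0;

  // active-set strategy: most sweeps update only features with nonzero
  // weight; every 10th sweep (and the first few) scans all features, and
  // convergence is only declared on a full scan
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool full_scan = (sweep < 3) || (sweep % 10 == 0);
    double max_delta = 0.0;
    double obj_sweep_start = obj;
    for (int j = 0; j < d; ++j) {
      if (!full_scan && lambda[j] == 0.0) continue;
      double Ej = 0.0, E2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double pf = w[i] * F(i, j);
        Ej += pf;
        E2 += pf * F(i, j);
      }
      Ej /= Z;
      E2 /= Z;
      double var = std::max(E2 - Ej * Ej, 1e-12);
      double g = fbar[j] - Ej;
      double z = lambda[j] + g / var;
      double thr = beta[j] / var;
      double lam_new = (z > thr) ? z - thr : ((z < -thr) ? z + thr : 0.0);
      double delta = lam_new - lambda[j];
      if (std::fabs(delta) < 1e-13) continue;
      // backtracking so the penalized objective is non-decreasing
      bool ok = false;
      double obj_new = obj, Znew = Z;
      for (int h = 0; h < 40; ++h) {
        Znew = 0.0;
        for (int i = 0; i < n; ++i) {
          scratch[i] = std::exp(delta * F(i, j));
          Znew += w[i] * scratch[i];
        }
        obj_new = obj + delta * fbar[j] - std::log(Znew / Z)
                  - beta[j] * (std::fabs(lambda[j] + delta) - std::fabs(lambda[j]));
        if (obj_new >= obj - 1e-12) { ok = true; break; }
        delta *= 0.5;
      }
      if (!ok) continue;
      for (int i = 0; i < n; ++i) {
        eta[i] += delta * F(i, j);
        w[i] *= scratch[i];
      }
      Z = Znew;
      lambda[j] += delta;
      obj = obj_new;
      max_delta = std::max(max_delta, std::fabs(delta));
    }
    // re-centre eta to avoid overflow
    double emax = eta[0];
    for (int i = 1; i < n; ++i) emax = std::max(emax, eta[i]);
    if (emax > 30.0 || emax < -30.0) {
      Z = 0.0;
      for (int i = 0; i < n; ++i) {
        eta[i] -= emax;
        w[i] = std::exp(eta[i]);
        Z += w[i];
      }
    }
    trace.push_back(obj);
    sweeps_done = sweep + 1;
    // stop on a stalled full scan: tiny coordinate moves or negligible gain
    if (full_scan && sweep >= 3 &&
        (max_delta < tol ||
         obj - obj_sweep_start <= obj_tol * (1.0 + std::fabs(obj)))) {
      converged = true;
      break;
    }
  }

  NumericVector p(n);
  for (int i = 0; i < n; ++i) p[i] = w[i] / Z;
  return List::create(_["lambda"] = wrap(lambda), _["p"] = p,
                      _["objective"] = wrap(trace),
                      _["converged"] = converged,
                      _["sweeps"] = sweeps_done);
}
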