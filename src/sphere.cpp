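// Weighted projection of a row of the Cholesky factor onto the unit sphere:
//   min sum_l w_l (b_l - bt_l)^2   s.t.  ||b|| = 1,
// solved through the Lagrangian stationarity b_l = w_l bt_l / (w_l + lam)
// with lam the root of ||b(lam)|| = 1 on (-min w, Inf).  The "hard case"
// (bt zero on every minimum-weight coordinate and the remaining norm short
// of 1) places the residual mass on the first minimum-weight coordinate.

#include "proxlvm_common.h"

using namespace arma;

static double sphere_norm2(const vec& bt, const vec& w, double lam) {
  double s = 0.0;
  for (uword l = 0; l < bt.n_elem; ++l) {
    double b = w(l) * bt(l) / (w(l) + lam);
    s += b * b;
  }
  return s;
}

vec plvm_prox_sphere(const vec& bt, const vec& w, bool& degenerate) {
  const uword K = bt.n_elem;
  degenerate = false;
  vec b(K, fill::zeros);
  if (norm(bt, "inf") < 1e-300) {          // no information: deterministic unit vector
    degenerate = true;
    b(0) = 1.0;
    return b;
  }
  if (K == 1) {
    b(0) = (bt(0) >= 0.0) ? 1.0 : -1.0;
    return b;
  }
  double wmin = w.min();
  // detect the hard case: bt == 0 on all minimum-weight coordinates
  bool hard_possible = true;
  for (uword l = 0; l < K; ++l)
    if (w(l) < wmin * (1.0 + 1e-12) && std::abs(bt(l)) > 0.0) { hard_possible = false; break; }

  double lo = -wmin;                        // open lower end
  if (hard_possible) {
    // limit of the norm as lam -> -wmin from above, over coords with w > wmin
    double s = 0.0;
    for (uword l = 0; l < K; ++l) {
      if (w(l) > wmin * (1.0 + 1e-12)) {
        double v = w(l) * bt(l) / (w(l) - wmin);
        s += v * v;
      }
    }
    if (s < 1.0) {                          // hard case: lam* = -wmin
      for (uword l = 0; l < K; ++l)
        b(l) = (w(l) > wmin * (1.0 + 1e-12)) ? w(l) * bt(l) / (w(l) - wmin) : 0.0;
      double resid = std::sqrt(std::max(0.0, 1.0 - s));
      for (uword l = 0; l < K; ++l)
        if (w(l) < wmin * (1.0 + 1e-12)) { b(l) = resid; break; }
      double nb = norm(b);
      if (nb > 0) b /= nb;
      return b;
    }
  }
  // bracket the root of ||b(lam)||^2 - 1 = 0 (strictly decreasing in lam)
  double eps0 = std::max(1e-14, 1e-12 * wmin);
  double llo = lo + eps0;
  while (sphere_norm2(bt, w, llo) < 1.0) {  // pathological fp case: shrink eps
    eps0 *= 0.5;
    if (eps0 < 1e-300) break;
    llo = lo + eps0;
  }
  double lhi = std::max(1.0, wmin);
  while (sphere_norm2(bt, w, lhi) > 1.0) lhi *= 2.0;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (llo + lhi);
    if (sphere_norm2(bt, w, mid) > 1.0) llo = mid; else lhi = mid;
    if (lhi - llo < 1e-15 * (1.0 + std::abs(lhi))) break;
  }
  double lam = 0.5 * (llo + lhi);
  for (uword l = 0; l < K; ++l) b(l) = w(l) * bt(l) / (w(l) + lam);
  double nb = norm(b);
  if (nb > 0) b /= nb;                      // exact unit norm
  return b;
}

// [[Rcpp::export(name = ".prox_sphere")]]
Rcpp::List prox_sphere_rcpp(const arma::vec& bt, const arma::vec& w) {
  bool degen = false;
  vec b = plvm_prox_sphere(bt, w, degen);
  return Rcpp::List::create(Rcpp::Named("b") = b,
                            Rcpp::Named("degenerate") = degen);
}
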