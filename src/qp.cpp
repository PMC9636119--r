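// Primal active-set solver for the strictly convex quadratic program
//   min (x - target)' diag(w) (x - target)
//   s.t. Aeq x = beq,  Ain x >= bin,
// i.e. a projection onto a polyhedron under a diagonal metric.  Written for
// the small per-item projections arising in restricted latent class
// estimation (dimension 2^K, a few dozen rows), where no installed package
// provides a QP solver.  Requires a feasible starting point.

#include "proxlvm_common.h"

using namespace arma;

// Solve the equality-constrained subproblem
//   min (x-t)' D (x-t)  s.t.  C x = b
// via  x = t - (1/2) Dinv C' lam,  lam = 2 (C Dinv C')^{-1} (C t - b).
// Returns false if the KKT system is (numerically) singular.
static bool eqp_solve(const vec& w, const vec& t, const mat& C, const vec& b,
                      vec& x, vec& lam) {
  if (C.n_rows == 0) { x = t; lam.reset(); return true; }
  mat Dinv_Ct = C.t();
  Dinv_Ct.each_col() /= w;
  mat S = C * Dinv_Ct;                 // C Dinv C'
  vec rhs = 2.0 * (C * t - b);
  bool ok = solve(lam, S, rhs, solve_opts::no_approx);
  if (!ok) {
    // dependent active rows: fall back to a least-squares multiplier
    lam = pinv(S, 1e-10) * rhs;
  }
  x = t - 0.5 * (Dinv_Ct * lam);
  return true;
}

vec plvm_qp_active_set(const vec& w, const vec& target,
                       const mat& Aeq, const vec& beq,
                       const mat& Ain, const vec& bin,
                       const vec& x0, uvec& warm, bool use_warm) {
  const uword p = target.n_elem;
  const uword ne = Aeq.n_rows, ni = Ain.n_rows;
  vec x = x0;
  const double tol = 1e-10;

  std::vector<uword> W;                 // working set of inequality rows
  if (use_warm) {
    for (uword idx = 0; idx < warm.n_elem; ++idx) {
      uword i = warm(idx);
      if (i < ni && std::abs(dot(Ain.row(i), x) - bin(i)) < 1e-8) W.push_back(i);
    }
  }

  for (int iter = 0; iter < 500; ++iter) {
    uword nw = W.size();
    mat C(ne + nw, p);
    vec b(ne + nw);
    if (ne > 0) { C.rows(0, ne - 1) = Aeq; b.subvec(0, ne - 1) = beq; }
    for (uword s = 0; s < nw; ++s) { C.row(ne + s) = Ain.row(W[s]); b(ne + s) = bin(W[s]); }

    vec xs, lam;
    eqp_solve(w, target, C, b, xs, lam);
    vec pdir = xs - x;

    if (norm(pdir, "inf") < tol * (1.0 + norm(x, "inf"))) {
      // at the subproblem optimum: check multipliers of working inequalities.
      // KKT: grad f = -C' lam, and for Ain x >= bin rows the multiplier of
      // the >= constraint is -lam; optimality needs -lam >= 0, i.e. lam <= 0.
      if (nw == 0) return xs;
      uword worst = 0; double worst_lam = tol;
      bool drop = false;
      for (uword s = 0; s < nw; ++s) {
        double l = lam(ne + s);
        if (l > worst_lam) { worst_lam = l; worst = s; drop = true; }
      }
      if (!drop) {
        warm = conv_to<uvec>::from(W);
        return xs;
      }
      W.erase(W.begin() + worst);
      continue;
    }

    // step to the nearest blocking constraint
    double alpha = 1.0; sword block = -1;
    for (uword i = 0; i < ni; ++i) {
      bool inW = false;
      for (uword s = 0; s < W.size(); ++s) if (W[s] == i) { inW = true; break; }
      if (inW) continue;
      double ap = dot(Ain.row(i), pdir);
      if (ap < -tol) {
        double ai = (bin(i) - dot(Ain.row(i), x)) / ap;
        if (ai < alpha) { alpha = ai; block = (sword)i; }
      }
    }
    if (alpha < 0.0) alpha = 0.0;
    x += alpha * pdir;
    if (block >= 0) W.push_back((uword)block); else x = xs;
  }
  warm = conv_to<uvec>::from(W);
  return x;  // iteration guard; practically unreachable for these problems
}

// [[Rcpp::export(name = ".qp_active_set")]]
arma::vec qp_active_set_rcpp(const arma::vec& weights, const arma::vec& target,
                             const arma::mat& Aeq, const arma::vec& beq,
                             const arma::mat& Ain, const arma::vec& bin,
                             const arma::vec& x0) {
  uvec warm;
  return plvm_qp_active_set(weights, target, Aeq, beq, Ain, bin, x0, warm, false);
}
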