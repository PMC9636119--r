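// Quasi-Newton stochastic proximal engine for logistic item factor analysis.
// One iteration = one Gibbs/ARS sweep over the latent factor matrix, then a
// diagonally scaled proximal gradient update of (d, A, B) with the running
// truncated-diagonal curvature estimate.  Variants: USP (full algorithm),
// USP-PPG (c1 = c2, no second-order information), USP-RM1 (no averaging),
// USP-RM2 (no averaging, 1/t steps), StEM (full complete-data maximization
// by iterated proximal Newton updates).
//
// Free-parameter packing: [d_1..d_J | a_jk (row-major, q_jk = 1 only) |
// b_kl (k = 1..K, l = 1..k)].

#include "proxlvm_common.h"

using namespace arma;

namespace {

struct Layout {
  uword J, K, p, na;
  std::vector<int> amap;   // J*K row-major -> packed index or -1
  std::vector<std::pair<int,int>> bidx; // packed order of (k,l)

  Layout(const umat& Q) {
    J = Q.n_rows; K = Q.n_cols;
    amap.assign(J * K, -1);
    uword pos = J;
    for (uword j = 0; j < J; ++j)
      for (uword k = 0; k < K; ++k)
        if (Q(j, k) == 1) amap[j * K + k] = (int)pos++;
    na = pos - J;
    for (uword k = 0; k < K; ++k)
      for (uword l = 0; l <= k; ++l) bidx.push_back({(int)k, (int)l});
    p = pos + bidx.size();
  }

  vec pack(const vec& d, const mat& A, const mat& B) const {
    vec b(p);
    b.subvec(0, J - 1) = d;
    for (uword j = 0; j < J; ++j)
      for (uword k = 0; k < K; ++k)
        if (amap[j * K + k] >= 0) b(amap[j * K + k]) = A(j, k);
    for (uword s = 0; s < bidx.size(); ++s)
      b(J + na + s) = B(bidx[s].first, bidx[s].second);
    return b;
  }

  void unpack(const vec& b, vec& d, mat& A, mat& B) const {
    d = b.subvec(0, J - 1);
    A.zeros(J, K);
    for (uword j = 0; j < J; ++j)
      for (uword k = 0; k < K; ++k)
        if (amap[j * K + k] >= 0) A(j, k) = b(amap[j * K + k]);
    B.zeros(K, K);
    for (uword s = 0; s < bidx.size(); ++s)
      B(bidx[s].first, bidx[s].second) = b(J + na + s);
  }
};

// gradient and diagonal Hessian of the complete-data objective
// H = -log f(y, xi | beta) + lambda1 * sum a^2 (packed layout)
void grad_hess(const Layout& L, const mat& EtaT, const mat& YT, const mat& Xi,
               const mat& A, const mat& B, double lambda1,
               vec& grad, vec& hess) {
  const uword N = Xi.n_rows, K = L.K;
  mat P = EtaT;
  P.transform([](double x) { return plvm_sigmoid(x); });
  mat E = P - YT;
  mat W = P % (1.0 - P);
  vec gd = sum(E, 1);
  vec hd = sum(W, 1);
  mat Ga = E * Xi;
  mat Ha = W * (Xi % Xi);
  if (lambda1 > 0.0) {
    Ga += 2.0 * lambda1 * A;
    Ha += 2.0 * lambda1;
  }
  mat S = Xi.t() * Xi;
  mat Sigma = B * B.t();
  mat Pm = inv_sympd(Sigma);
  mat Rm = Pm * S * Pm;
  mat RB = Rm * B;

  grad.set_size(L.p); hess.set_size(L.p);
  grad.subvec(0, L.J - 1) = gd;
  hess.subvec(0, L.J - 1) = hd;
  for (uword j = 0; j < L.J; ++j)
    for (uword k = 0; k < K; ++k)
      if (L.amap[j * K + k] >= 0) {
        grad(L.amap[j * K + k]) = Ga(j, k);
        hess(L.amap[j * K + k]) = Ha(j, k);
      }
  for (uword s = 0; s < L.bidx.size(); ++s) {
    int k = L.bidx[s].first, l = L.bidx[s].second;
    vec c = B.col(l);
    vec Rc = Rm * c, Pc = Pm * c;
    double g = -RB(k, l);
    double T1 = 2.0 * dot(c, Rm.col(k)) * dot(c, Pm.col(k))
              + dot(c, Rc) * Pm(k, k) + Rm(k, k) * dot(c, Pc);
    double hh = T1 - Rm(k, k);
    if (k == l) {
      g += (double)N / B(k, k);
      hh += -(double)N / (B(k, k) * B(k, k));
    }
    grad(L.J + L.na + s) = g;
    hess(L.J + L.na + s) = hh;
  }
}

// scaled proximal map for the IFA parameter blocks, applied in place to bt:
// identity on d, soft-thresholding (penalized case) on free loadings,
// weighted sphere projection on each Cholesky row.
void ifa_prox(const Layout& L, vec& bt, const vec& dw, double gamma,
              int penalty, double lambda2) {
  if (penalty > 0 && lambda2 > 0.0) {
    for (uword i = L.J; i < L.J + L.na; ++i) {
      double kap = lambda2 * gamma / dw(i);
      double v = bt(i);
      bt(i) = (v > kap) ? v - kap : ((v < -kap) ? v + kap : 0.0);
    }
  }
  uword off = L.J + L.na, s = 0;
  for (uword k = 0; k < L.K; ++k) {
    uword len = k + 1;
    vec rowt = bt.subvec(off + s, off + s + len - 1);
    vec roww = dw.subvec(off + s, off + s + len - 1);
    bool degen = false;
    vec pb = plvm_prox_sphere(rowt, roww, degen);
    bt.subvec(off + s, off + s + len - 1) = pb;
    s += len;
  }
}

} // namespace

// [[Rcpp::export(name = ".ifa_grad_hess")]]
Rcpp::List ifa_grad_hess_rcpp(const arma::mat& Y, const arma::mat& Xi,
                              const arma::vec& d, const arma::mat& A,
                              const arma::mat& B, const arma::umat& Q,
                              double lambda1) {
  Layout L(Q);
  mat YT = Y.t();
  mat EtaT = A * Xi.t();
  EtaT.each_col() += d;
  vec grad, hess;
  grad_hess(L, EtaT, YT, Xi, A, B, lambda1, grad, hess);
  return Rcpp::List::create(Rcpp::Named("grad") = grad,
                            Rcpp::Named("hess") = hess);
}

// [[Rcpp::export(name = ".ifa_usp")]]
Rcpp::List ifa_usp_rcpp(const arma::mat& Y, const arma::umat& Q,
                        const arma::vec& d0, const arma::mat& A0,
                        const arma::mat& B0,
                        int penalty, double lambda1, double lambda2,
                        int variant, int max_iter, int burn_in,
                        double mu, double eps, double c1, double c2,
                        double threshold, int window,
                        bool keep_history, int thin,
                        double stem_tol, int stem_max_inner, int gibbs_sweeps,
                        double curv_clamp) {
  const uword N = Y.n_rows, K = A0.n_cols;
  Layout L(Q);
  mat YT = Y.t();

  const bool rm2 = (variant == 3);
  const bool averaging = (variant == 0 || variant == 1 || variant == 4);
  const bool stem = (variant == 4);

  vec d = d0; mat A = A0, B = B0;
  vec beta = L.pack(d, A, B);
  vec delta1(L.p, fill::zeros), delta2(L.p, fill::zeros), d_avg(L.p, fill::zeros);
  vec avg(L.p, fill::zeros), avg_prev(L.p, fill::zeros);
  uword navg = 0;

  mat Xi(N, K, fill::zeros);
  mat ModeCache(N, K, fill::zeros);
  mat Sigma = B * B.t();
  mat Omega = inv_sympd(Sigma);
  mat EtaT = A * Xi.t();
  EtaT.each_col() += d;

  std::vector<double> diffs;
  diffs.reserve(std::min(max_iter, 200000));
  std::vector<double> hist;
  int n_iter = max_iter;
  bool stopped = false;
  vec grad(L.p), hess(L.p);

  GetRNGstate();
  for (int t = 1; t <= max_iter; ++t) {
    // stochastic step
    std::vector<std::vector<int>> supp(K);
    for (uword k = 0; k < K; ++k)
      for (uword j = 0; j < L.J; ++j)
        if (A(j, k) != 0.0) supp[k].push_back((int)j);
    for (int s = 0; s < gibbs_sweeps; ++s)
      plvm_ifa_gibbs_sweep(Xi, EtaT, YT, A, Omega, supp, ModeCache);

    vec beta_old = beta;
    if (!stem) {
      // proximal step with quasi-Newton diagonal scaling
      grad_hess(L, EtaT, YT, Xi, A, B, (penalty == 2) ? lambda1 : 0.0, grad, hess);
      if (c1 < 0.0 && t == 1) {
        vec hp = hess(find(hess > 0.0));
        c1 = (hp.n_elem > 0) ? 0.25 * median(hp) : 1e-2;
        if (c2 < c1) c2 = c1;
      }
      double gam = plvm_step(t, mu, eps, rm2);
      double gsc = std::min(gam, 1.0);     // the averaging recursions need gamma <= 1
      delta1 = (1.0 - gsc) * delta1 + gsc * (hess - square(grad));
      delta2 = (1.0 - gsc) * delta2 + gsc * grad;
      vec dtil = delta1 + square(delta2);
      if (curv_clamp > 0.0)
        for (uword i = 0; i < dtil.n_elem; ++i)
          if (hess(i) > 0.0)
            dtil(i) = plvm_trunc(dtil(i), curv_clamp * hess(i), hess(i));
      dtil.transform([&](double x) { return plvm_trunc(x, c1, c2); });
      d_avg = ((double)(t - 1) / t) * d_avg + (1.0 / t) * dtil;
      beta -= gam * (grad / d_avg);
      ifa_prox(L, beta, d_avg, gam, penalty, lambda2);
      if (!beta.is_finite())
        Rcpp::stop("non-finite parameter update at iteration %d", t);
    } else {
      // StEM: maximize the complete-data objective by iterated proximal
      // Newton updates (unit step, truncated diagonal curvature)
      double damp = 1.0, prev = datum::inf, best = datum::inf;
      int stall = 0;
      for (int it = 0; it < stem_max_inner; ++it) {
        grad_hess(L, EtaT, YT, Xi, A, B, (penalty == 2) ? lambda1 : 0.0, grad, hess);
        if (c1 < 0.0) {   // auto scale from the first complete-data curvature
          vec hp = hess(find(hess > 0.0));
          c1 = (hp.n_elem > 0) ? 0.25 * median(hp) : 1e-2;
          if (c2 < c1) c2 = c1;
        }
        vec Din = hess;
        Din.transform([&](double x) { return plvm_trunc(x, c1, c2); });
        vec bnew = beta - damp * (grad / Din);
        ifa_prox(L, bnew, Din, damp, penalty, lambda2);
        double dd = norm(bnew - beta, "inf");
        beta = bnew;
        L.unpack(beta, d, A, B);
        EtaT = A * Xi.t();
        EtaT.each_col() += d;
        if (dd < stem_tol) break;
        // halve the step on divergence, or when the update size stalls
        // (the projected diagonal-Newton map can orbit on curved sets)
        if (dd > 10.0 * prev && dd > 1.0 && damp > 1.0 / 64.0) damp *= 0.5;
        if (dd < 0.9 * best) { best = dd; stall = 0; }
        else if (++stall >= 10 && damp > 1.0 / 64.0) { damp *= 0.5; stall = 0; }
        prev = dd;
      }
      if (!beta.is_finite())
        Rcpp::stop("non-finite StEM update at iteration %d", t);
    }

    L.unpack(beta, d, A, B);
    Sigma = B * B.t();
    Omega = inv_sympd(Sigma);
    if (!stem) {
      EtaT = A * Xi.t();
      EtaT.each_col() += d;
    }

    double raw_diff = norm(beta - beta_old, "inf");
    double diff = raw_diff;

    if (averaging && t > burn_in) {
      ++navg;
      avg_prev = avg;
      avg += (beta - avg) / (double)navg;
      // the estimator is the trajectory average: monitor its movement
      if (navg > 1) diff = norm(avg - avg_prev, "inf");
    }
    diffs.push_back(diff);
    if (keep_history && (t % thin == 0))
      for (uword i = 0; i < L.p; ++i) hist.push_back(beta(i));

    if (t >= burn_in + window && (int)diffs.size() >= window) {
      bool ok = true;
      for (int s2 = 0; s2 < window; ++s2)
        if (diffs[diffs.size() - 1 - s2] >= threshold) { ok = false; break; }
      if (ok) { n_iter = t; stopped = true; break; }
    }
  }
  PutRNGstate();
  if (!stopped) n_iter = max_iter;

  vec result = (averaging && navg > 0) ? avg : beta;
  vec rd; mat rA, rB;
  L.unpack(result, rd, rA, rB);
  vec ld; mat lA, lB;
  L.unpack(beta, ld, lA, lB);

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("d") = rd, Rcpp::Named("A") = rA, Rcpp::Named("B") = rB,
    Rcpp::Named("beta") = result,
    Rcpp::Named("last_d") = ld, Rcpp::Named("last_A") = lA,
    Rcpp::Named("last_B") = lB,
    Rcpp::Named("d_avg") = d_avg, Rcpp::Named("delta1") = delta1,
    Rcpp::Named("delta2") = delta2,
    Rcpp::Named("n_iter") = n_iter, Rcpp::Named("stopped") = stopped,
    Rcpp::Named("diffs") = diffs,
    Rcpp::Named("xi") = Xi);
  if (keep_history) {
    uword nrow = hist.size() / L.p;
    mat H(nrow, L.p);
    for (uword r = 0; r < nrow; ++r)
      for (uword i = 0; i < L.p; ++i) H(r, i) = hist[r * L.p + i];
    out["history"] = H;
  }
  return out;
}
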