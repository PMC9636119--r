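// Stochastic proximal engine for the restricted latent class model.
// The stochastic step samples each person's attribute profile exactly from
// its categorical posterior; the proximal step projects each item's theta
// block onto the monotonicity polyhedron (capable profiles equal, capable
// value >= every other value >= the zero-profile value) by an active-set
// QP under the diagonal quasi-Newton metric.  The structural log-odds nu
// (baseline nu_0 = 0 excluded from the parameter vector) are unconstrained.
//
// Packing: [theta column-major (J x M, M = 2^K) | nu_alpha, alpha != 0].

#include "proxlvm_common.h"

using namespace arma;

namespace {

struct QpSet {
  std::vector<mat> Aeq, Ain;
  std::vector<vec> beq, bin;
};

void softmax_inplace(vec& x) {
  double m = x.max();
  x = exp(x - m);
  x /= accu(x);
}

} // namespace

// [[Rcpp::export(name = ".rlca_usp")]]
Rcpp::List rlca_usp_rcpp(const arma::mat& Y, const arma::mat& theta0,
                         const arma::vec& nu0,
                         const Rcpp::List& qp_eq, const Rcpp::List& qp_in,
                         int variant, int max_iter, int burn_in,
                         double mu, double eps, double c1, double c2,
                         double threshold, int window,
                         bool keep_history, int thin,
                         double stem_tol, int stem_max_inner, double curv_clamp) {
  const uword N = Y.n_rows, J = theta0.n_rows, M = theta0.n_cols;
  const uword p = J * M + (M - 1);
  mat YT = Y.t();

  const bool rm2 = (variant == 3);
  const bool averaging = (variant == 0 || variant == 1 || variant == 4);
  const bool stem = (variant == 4);

  QpSet qp;
  for (uword j = 0; j < J; ++j) {
    qp.Aeq.push_back(Rcpp::as<mat>(qp_eq[j]));
    qp.Ain.push_back(Rcpp::as<mat>(qp_in[j]));
    qp.beq.push_back(vec(qp.Aeq[j].n_rows, fill::zeros));
    qp.bin.push_back(vec(qp.Ain[j].n_rows, fill::zeros));
  }
  std::vector<uvec> warm(J);
  std::vector<bool> has_warm(J, false);

  mat theta = theta0;
  vec nu = nu0;                       // length M-1 (free entries)
  vec delta1(p, fill::zeros), delta2(p, fill::zeros), d_avg(p, fill::zeros);
  vec avg(p, fill::zeros), avg_prev(p, fill::zeros);
  uword navg = 0;

  auto pack = [&](const mat& th, const vec& nv) {
    vec b(p);
    std::memcpy(b.memptr(), th.memptr(), J * M * sizeof(double));
    b.subvec(J * M, p - 1) = nv;
    return b;
  };

  vec beta = pack(theta, nu);
  std::vector<double> diffs;
  std::vector<double> hist;
  int n_iter = max_iter;
  bool stopped = false;

  uvec z(N);
  vec nfull(M);
  vec grad(p), hess(p);

  GetRNGstate();
  for (int t = 1; t <= max_iter; ++t) {
    // ---- stochastic step: exact posterior draw of each profile ----
    vec colK(M);
    for (uword a = 0; a < M; ++a) {
      double s = 0.0;
      for (uword j = 0; j < J; ++j) s += plvm_log1pexp(theta(j, a));
      colK(a) = s;
    }
    vec nuFull(M); nuFull(0) = 0.0;
    nuFull.subvec(1, M - 1) = nu;
    mat Lp = Y * theta;               // N x M
    Lp.each_row() += (nuFull - colK).t();
    vec nalpha(M, fill::zeros);
    mat S(J, M, fill::zeros);
    for (uword i = 0; i < N; ++i) {
      rowvec lp = Lp.row(i);
      double mx = lp.max();
      double tot = 0.0;
      double w[4096];
      for (uword a = 0; a < M; ++a) { w[a] = std::exp(lp(a) - mx); tot += w[a]; }
      double u = unif_rand() * tot, acc = 0.0;
      uword zi = M - 1;
      for (uword a = 0; a < M; ++a) { acc += w[a]; if (u <= acc) { zi = a; break; } }
      z(i) = zi;
      nalpha(zi) += 1.0;
      S.col(zi) += YT.col(i);
    }

    vec beta_old = beta;

    // complete-data gradient and diagonal Hessian at current beta
    auto fill_grad_hess = [&](const mat& th, const vec& nv) {
      mat Pth = th;
      Pth.transform([](double x) { return plvm_sigmoid(x); });
      mat Wth = Pth % (1.0 - Pth);
      for (uword a = 0; a < M; ++a) {
        for (uword j = 0; j < J; ++j) {
          grad(j + J * a) = nalpha(a) * Pth(j, a) - S(j, a);
          hess(j + J * a) = nalpha(a) * Wth(j, a);
        }
      }
      vec pi = nv; pi.insert_rows(0, 1); pi(0) = 0.0;
      softmax_inplace(pi);
      for (uword a = 1; a < M; ++a) {
        grad(J * M + a - 1) = (double)N * pi(a) - nalpha(a);
        hess(J * M + a - 1) = (double)N * pi(a) * (1.0 - pi(a));
      }
    };

    auto apply_prox = [&](vec& bt, const vec& dw) {
      for (uword j = 0; j < J; ++j) {
        vec targ(M), wts(M);
        for (uword a = 0; a < M; ++a) { targ(a) = bt(j + J * a); wts(a) = dw(j + J * a); }
        double x0v = dot(wts, targ) / accu(wts);
        vec x0(M); x0.fill(x0v);
        vec sol = plvm_qp_active_set(wts, targ, qp.Aeq[j], qp.beq[j],
                                     qp.Ain[j], qp.bin[j], x0, warm[j], has_warm[j]);
        has_warm[j] = true;
        for (uword a = 0; a < M; ++a) bt(j + J * a) = sol(a);
      }
    };

    if (!stem) {
      fill_grad_hess(theta, nu);
      if (c1 < 0.0 && t == 1) {
        vec hp = hess(find(hess > 0.0));
        c1 = (hp.n_elem > 0) ? 0.25 * median(hp) : 1e-2;
        if (c2 < c1) c2 = c1;
      }
      double gam = plvm_step(t, mu, eps, rm2);
      double gsc = std::min(gam, 1.0);
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
      apply_prox(beta, d_avg);
      if (!beta.is_finite())
        Rcpp::stop("non-finite parameter update at iteration %d", t);
    } else {
      double damp = 1.0, prev = datum::inf, best = datum::inf;
      int stall = 0;
      for (int it = 0; it < stem_max_inner; ++it) {
        std::memcpy(theta.memptr(), beta.memptr(), J * M * sizeof(double));
        nu = beta.subvec(J * M, p - 1);
        fill_grad_hess(theta, nu);
        if (c1 < 0.0) {   // auto scale from the first complete-data curvature
          vec hp = hess(find(hess > 0.0));
          c1 = (hp.n_elem > 0) ? 0.25 * median(hp) : 1e-2;
          if (c2 < c1) c2 = c1;
        }
        vec Din = hess;
        Din.transform([&](double x) { return plvm_trunc(x, c1, c2); });
        vec bnew = beta - damp * (grad / Din);
        apply_prox(bnew, Din);
        double dd = norm(bnew - beta, "inf");
        beta = bnew;
        if (dd < stem_tol) break;
        // halve the step on divergence, or when the update size stalls
        // (the projected diagonal-Newton map can orbit on curved sets)
        if (dd > 10.0 * prev && dd > 1.0 && damp > 1.0 / 64.0) damp *= 0.5;
        if (dd < 0.9 * best) { best = dd; stall = 0; }
        else if (++stall >= 10 && damp > 1.0 / 64.0) { damp *= 0.5; stall = 0; }
        prev = dd;
      }
    }

    std::memcpy(theta.memptr(), beta.memptr(), J * M * sizeof(double));
    nu = beta.subvec(J * M, p - 1);

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
      for (uword i = 0; i < p; ++i) hist.push_back(beta(i));
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
  mat rtheta(J, M);
  std::memcpy(rtheta.memptr(), result.memptr(), J * M * sizeof(double));
  vec rnu = result.subvec(J * M, p - 1);

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("theta") = rtheta, Rcpp::Named("nu") = rnu,
    Rcpp::Named("last_theta") = theta, Rcpp::Named("last_nu") = nu,
    Rcpp::Named("d_avg") = d_avg, Rcpp::Named("delta1") = delta1,
    Rcpp::Named("delta2") = delta2,
    Rcpp::Named("n_iter") = n_iter, Rcpp::Named("stopped") = stopped,
    Rcpp::Named("diffs") = diffs,
    Rcpp::Named("z") = z);
  if (keep_history) {
    uword nrow = hist.size() / p;
    mat H(nrow, p);
    for (uword r = 0; r < nrow; ++r)
      for (uword i = 0; i < p; ++i) H(r, i) = hist[r * p + i];
    out["history"] = H;
  }
  return out;
}
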