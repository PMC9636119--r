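// Adaptive rejection sampling (Gilks-Wild) for the univariate full
// conditionals of the latent factors in logistic item factor analysis.
// Each conditional is log-concave: a Gaussian prior conditional times a
// product of Bernoulli-logistic likelihood terms over the items loading on
// the factor.  The sampler builds a piecewise-linear upper hull from
// tangents at a small set of abscissae (initialized around the conditional
// mode, located by safeguarded Newton), samples from the induced piecewise
// exponential envelope, and uses the chord lower hull as a squeeze.  On
// numerical failure it falls back to stepping-out slice sampling, which is
// also exact for the (unimodal) conditional.

#include "proxlvm_common.h"

using namespace arma;

namespace {

struct CondCtx {
  int nj;                 // items in the factor's support
  const double* base;     // eta minus this coordinate's contribution
  const double* yv;       // binary responses
  const double* av;       // loadings on this factor
  double m, v;            // prior conditional mean and variance
};

// log density (up to constant), first and second derivative
inline double cond_eval(const CondCtx& c, double x, double& hp, double& hpp) {
  double dm = x - c.m;
  double h = -0.5 * dm * dm / c.v;
  hp = -dm / c.v;
  hpp = -1.0 / c.v;
  for (int j = 0; j < c.nj; ++j) {
    double a = c.av[j];
    double eta = c.base[j] + a * x;
    double e, l1pe, p;
    if (eta >= 0.0) {
      e = std::exp(-eta); l1pe = eta + std::log1p(e); p = 1.0 / (1.0 + e);
    } else {
      e = std::exp(eta);  l1pe = std::log1p(e);      p = e / (1.0 + e);
    }
    h += c.yv[j] * eta - l1pe;
    hp += a * (c.yv[j] - p);
    hpp -= a * a * p * (1.0 - p);
  }
  return h;
}

constexpr int MAXP = 12;

struct Hull {
  double x[MAXP], h[MAXP], hp[MAXP];
  double z[MAXP + 1];        // z[0] = -Inf, z[n] = +Inf
  double lm[MAXP];           // segment log masses (normalized by hmax)
  double hmax;
  int n;

  void insert(double xi, double hi, double hpi) {
    if (n >= MAXP) return;
    int pos = 0;
    while (pos < n && x[pos] < xi) ++pos;
    for (int s = n; s > pos; --s) { x[s] = x[s-1]; h[s] = h[s-1]; hp[s] = hp[s-1]; }
    x[pos] = xi; h[pos] = hi; hp[pos] = hpi; ++n;
  }

  // recompute tangent intersections and segment masses
  bool refresh() {
    z[0] = -datum::inf; z[n] = datum::inf;
    for (int i = 0; i < n - 1; ++i) {
      double dh = hp[i] - hp[i+1];
      if (std::abs(dh) < 1e-12 * (1.0 + std::abs(hp[i]))) {
        z[i+1] = 0.5 * (x[i] + x[i+1]);
      } else {
        z[i+1] = (h[i+1] - h[i] - x[i+1]*hp[i+1] + x[i]*hp[i]) / dh;
        if (z[i+1] < x[i]) z[i+1] = x[i];
        if (z[i+1] > x[i+1]) z[i+1] = x[i+1];
      }
    }
    hmax = h[0];
    for (int i = 1; i < n; ++i) if (h[i] > hmax) hmax = h[i];
    for (int i = 0; i < n; ++i) {
      double s = hp[i], hi = h[i] - hmax;
      double lmass;
      if (i == 0 && !std::isfinite(z[0])) {
        if (s <= 0.0) return false;
        lmass = hi + s * (z[1] - x[0]) - std::log(s);
      } else if (i == n - 1 && !std::isfinite(z[n])) {
        if (s >= 0.0) return false;
        lmass = hi + s * (z[n-1] - x[i]) - std::log(-s);
      } else {
        double u1 = s * (z[i] - x[i]), u2 = s * (z[i+1] - x[i]);
        double dz = z[i+1] - z[i];
        if (dz <= 0.0) { lmass = -datum::inf; }
        else if (std::abs(s) * dz < 1e-10) {
          lmass = hi + 0.5 * (u1 + u2) + std::log(dz);
        } else if (s > 0.0) {
          lmass = hi + u2 + std::log1p(-std::exp(u1 - u2)) - std::log(s);
        } else {
          lmass = hi + u1 + std::log1p(-std::exp(u2 - u1)) - std::log(-s);
        }
      }
      lm[i] = lmass;
    }
    return true;
  }

  // sample from the piecewise exponential envelope; returns x and the
  // envelope log value at x (relative to the true scale, i.e. + hmax)
  bool sample(double& xs, double& env) {
    double tot = 0.0, mmax = lm[0];
    for (int i = 1; i < n; ++i) if (lm[i] > mmax) mmax = lm[i];
    if (!std::isfinite(mmax)) return false;
    double w[MAXP];
    for (int i = 0; i < n; ++i) { w[i] = std::exp(lm[i] - mmax); tot += w[i]; }
    double u = unif_rand() * tot, acc = 0.0;
    int seg = n - 1;
    for (int i = 0; i < n; ++i) { acc += w[i]; if (u <= acc) { seg = i; break; } }
    double s = hp[seg], r = unif_rand();
    double zl = z[seg], zr = z[seg + 1];
    if (!std::isfinite(zl)) {                     // s > 0
      xs = zr + std::log(r) / s;
    } else if (!std::isfinite(zr)) {              // s < 0
      xs = zl + std::log1p(-r) / s;
    } else if (std::abs(s) * (zr - zl) < 1e-10) {
      xs = zl + r * (zr - zl);
    } else {
      double u1 = s * (zl - x[seg]), u2 = s * (zr - x[seg]);
      double mm = std::max(u1, u2);
      xs = x[seg] + (mm + std::log((1.0 - r) * std::exp(u1 - mm) + r * std::exp(u2 - mm))) / s;
    }
    if (!std::isfinite(xs)) return false;
    env = h[seg] + s * (xs - x[seg]);
    return true;
  }

  // chord lower bound (squeeze); -Inf outside the abscissae
  double squeeze(double xs) const {
    if (xs < x[0] || xs > x[n-1]) return -datum::inf;
    for (int i = 0; i < n - 1; ++i) {
      if (xs <= x[i+1]) {
        double t = (xs - x[i]) / (x[i+1] - x[i]);
        return h[i] + t * (h[i+1] - h[i]);
      }
    }
    return -datum::inf;
  }
};

// stepping-out slice sampler fallback (exact for unimodal targets)
double slice_draw(const CondCtx& c, double xcur, double width) {
  double hp, hpp;
  double h0 = cond_eval(c, xcur, hp, hpp);
  double ly = h0 - exp_rand();
  double L = xcur - width * unif_rand(), Rr = L + width;
  for (int i = 0; i < 100 && cond_eval(c, L, hp, hpp) > ly; ++i) L -= width;
  for (int i = 0; i < 100 && cond_eval(c, Rr, hp, hpp) > ly; ++i) Rr += width;
  for (int i = 0; i < 200; ++i) {
    double xs = L + unif_rand() * (Rr - L);
    if (cond_eval(c, xs, hp, hpp) >= ly) return xs;
    if (xs < xcur) L = xs; else Rr = xs;
  }
  return xcur;
}

// one exact draw from the conditional; mode_cache is updated in place
double ars_draw(const CondCtx& c, double& mode_cache, double xcur) {
  double x0 = mode_cache, hp0, hpp0;
  double h0 = cond_eval(c, x0, hp0, hpp0);
  for (int it = 0; it < 10; ++it) {
    double sd = 1.0 / std::sqrt(-hpp0);
    double step = hp0 / (-hpp0);
    if (std::abs(step) < 1e-7 * sd) break;
    if (step > 8.0 * sd) step = 8.0 * sd;
    if (step < -8.0 * sd) step = -8.0 * sd;
    x0 += step;
    h0 = cond_eval(c, x0, hp0, hpp0);
  }
  mode_cache = x0;
  double sd = 1.0 / std::sqrt(-hpp0);

  Hull hull; hull.n = 0;
  hull.insert(x0, h0, hp0);
  {
    double hpl, hppl, hl, w = sd;
    int tries = 0;
    double xl = x0 - w;
    hl = cond_eval(c, xl, hpl, hppl);
    while (hpl <= 0.0 && tries++ < 60) { w *= 2.0; xl = x0 - w; hl = cond_eval(c, xl, hpl, hppl); }
    hull.insert(xl, hl, hpl);
    double xr = x0 + (w = sd);
    tries = 0;
    double hpr, hppr, hr = cond_eval(c, xr, hpr, hppr);
    while (hpr >= 0.0 && tries++ < 60) { w *= 2.0; xr = x0 + w; hr = cond_eval(c, xr, hpr, hppr); }
    hull.insert(xr, hr, hpr);
  }

  for (int iter = 0; iter < 100; ++iter) {
    if (!hull.refresh()) break;
    double xs, env;
    if (!hull.sample(xs, env)) break;
    double lu = std::log(unif_rand());
    double sq = hull.squeeze(xs);
    if (lu <= sq - env) return xs;
    double hps, hpps;
    double hs = cond_eval(c, xs, hps, hpps);
    if (lu <= hs - env) return xs;
    hull.insert(xs, hs, hps);
  }
  return slice_draw(c, xcur, sd);
}

} // namespace

void plvm_ifa_gibbs_sweep(mat& Xi, mat& EtaT, const mat& YT, const mat& A,
                          const mat& Omega,
                          const std::vector<std::vector<int>>& supp,
                          mat& ModeCache) {
  const uword N = Xi.n_rows, K = Xi.n_cols;
  std::vector<double> base, yv, av;
  for (uword k = 0; k < K; ++k) {
    const double v = 1.0 / Omega(k, k);
    const std::vector<int>& sk = supp[k];
    const int nj = (int)sk.size();
    base.resize(std::max(nj, 1)); yv.resize(std::max(nj, 1)); av.resize(std::max(nj, 1));
    for (int s = 0; s < nj; ++s) av[s] = A(sk[s], k);
    for (uword i = 0; i < N; ++i) {
      double m = 0.0;
      for (uword k2 = 0; k2 < K; ++k2)
        if (k2 != k) m -= v * Omega(k, k2) * Xi(i, k2);
      double xcur = Xi(i, k), xnew;
      if (nj == 0) {
        xnew = m + std::sqrt(v) * norm_rand();
      } else {
        for (int s = 0; s < nj; ++s) {
          base[s] = EtaT(sk[s], i) - av[s] * xcur;
          yv[s] = YT(sk[s], i);
        }
        CondCtx ctx{nj, base.data(), yv.data(), av.data(), m, v};
        double mc = ModeCache(i, k);
        xnew = ars_draw(ctx, mc, xcur);
        ModeCache(i, k) = mc;
        for (int s = 0; s < nj; ++s) EtaT(sk[s], i) += av[s] * (xnew - xcur);
      }
      Xi(i, k) = xnew;
    }
  }
}

// [[Rcpp::export(name = ".ifa_gibbs")]]
arma::mat ifa_gibbs_rcpp(const arma::mat& Y, const arma::vec& d, const arma::mat& A,
                         const arma::mat& B, const arma::mat& Xi0, int n_sweeps) {
  mat YT = Y.t();
  mat Xi = Xi0;
  mat Sigma = B * B.t();
  mat Omega = inv_sympd(Sigma);
  mat EtaT = A * Xi.t();
  EtaT.each_col() += d;
  const uword K = A.n_cols;
  std::vector<std::vector<int>> supp(K);
  for (uword k = 0; k < K; ++k)
    for (uword j = 0; j < A.n_rows; ++j)
      if (A(j, k) != 0.0) supp[k].push_back((int)j);
  mat ModeCache(Xi.n_rows, K, fill::zeros);
  GetRNGstate();
  for (int s = 0; s < n_sweeps; ++s)
    plvm_ifa_gibbs_sweep(Xi, EtaT, YT, A, Omega, supp, ModeCache);
  PutRNGstate();
  return Xi;
}
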