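#ifndef PROXLVM_COMMON_H
#define PROXLVM_COMMON_H

#include <RcppArmadillo.h>

// log(1 + exp(x)) without overflow
static inline double plvm_log1pexp(double x) {
  if (x > 35.0) return x + std::exp(-x);
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double plvm_sigmoid(double x) {
  if (x >= 0.0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// clamp to [c1, c2]
static inline double plvm_trunc(double x, double c1, double c2) {
  if (x < c1) return c1;
  if (x > c2) return c2;
  return x;
}

// step size mu * t^(-1/2-eps), or mu/t in Robbins-Monro mode
static inline double plvm_step(int t, double mu, double eps, bool rm2) {
  if (rm2) return mu / (double)t;
  return mu * std::pow((double)t, -0.5 - eps);
}

arma::vec plvm_qp_active_set(const arma::vec& w, const arma::vec& target,
                             const arma::mat& Aeq, const arma::vec& beq,
                             const arma::mat& Ain, const arma::vec& bin,
                             const arma::vec& x0, arma::uvec& warm,
                             bool use_warm);

arma::vec plvm_prox_sphere(const arma::vec& bt, const arma::vec& w, bool& degenerate);

void plvm_ifa_gibbs_sweep(arma::mat& Xi, arma::mat& EtaT, const arma::mat& YT,
                          const arma::mat& A, const arma::mat& Omega,
                          const std::vector<std::vector<int>>& supp,
                          arma::mat& ModeCache);

#endif
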