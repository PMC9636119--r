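# Toy models for the generic engine ------------------------------------------

# degenerate no-latent Gaussian model: y_i ~ N(beta, 1).  The stochastic
# gradient is deterministic; the complete-data MLE is the sample mean.
gaussian_toy_model <- function() {
  usp_model(
    sample_latent = function(y, beta, xi, t) NULL,
    grad = function(y, xi, beta) length(y) * beta - sum(y),
    diag_hess = function(y, xi, beta) length(y),
    prox = function(bt, w, g) bt,
    n_params = 1L,
    full_maximize = function(y, xi, beta) mean(y))
}

# conjugate latent-Gaussian toy: xi_i ~ N(beta, 1), y_i | xi_i ~ N(xi_i, 1).
# Exact posterior sampling gives a genuinely stochastic gradient; the
# marginal MLE is again the sample mean (y_i ~ N(beta, 2)).
latent_gaussian_toy_model <- function() {
  usp_model(
    sample_latent = function(y, beta, xi, t) {
      rnorm(length(y), (y + beta) / 2, sqrt(0.5))
    },
    grad = function(y, xi, beta) length(y) * beta - sum(xi),
    diag_hess = function(y, xi, beta) length(y),
    prox = function(bt, w, g) bt,
    n_params = 1L)
}

# small random RLCA instance for oracle tests
small_rlca_instance <- function(seed, N = 40, J = 5, K = 2) {
  set.seed(seed)
  Q <- matrix(rbinom(J * K, 1, 0.6), J, K)
  Q[rowSums(Q) == 0, 1] <- 1L
  M <- 2^K
  theta <- matrix(rnorm(J * M), J, M)
  nu <- c(0, rnorm(M - 1, 0, 0.5))
  Y <- matrix(rbinom(N * J, 1, 0.5), N, J)
  list(Q = Q, theta = theta, nu = nu, Y = Y, J = J, K = K, M = M, N = N)
}

# brute-force oracle for the per-item monotone projection, via the
# reparameterized form: shared capable value c, the other values clipped
# into [theta_0, c], then 2-D minimization over (theta_0, c = theta_0 + s)
rlca_prox_oracle <- function(bt, w, cs) {
  M <- length(bt)
  cap <- cs$capable; inc <- cs$incapable
  if (length(inc) == 0L) return(rep(sum(w * bt) / sum(w), M))
  others <- setdiff(inc, 1L)
  obj <- function(par) {
    t0 <- par[1]; cc <- par[1] + abs(par[2])
    v <- numeric(M)
    v[cap] <- cc
    v[1L] <- t0
    if (length(others)) v[others] <- pmin(pmax(bt[others], t0), cc)
    sum(w * (v - bt)^2)
  }
  best <- NULL
  for (t0g in quantile(bt, c(0.05, 0.25, 0.5))) for (sg in c(0.01, 1, 3)) {
    o <- optim(c(t0g, sg), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  t0 <- best$par[1]; cc <- t0 + abs(best$par[2])
  v <- numeric(M)
  v[cap] <- cc; v[1L] <- t0
  if (length(others)) v[others] <- pmin(pmax(bt[others], t0), cc)
  v
}
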