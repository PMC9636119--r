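log1pexp <- function(x) {
  out <- x
  lo <- x <= 35
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 35
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

# free-parameter layout shared with the compiled engine:
# [d_1..d_J | a_jk (row-major over items, q_jk = 1 only) | b_kl, l <= k]
ifa_layout <- function(Q) {
  J <- nrow(Q); K <- ncol(Q)
  amap <- matrix(NA_integer_, J, K)
  pos <- J
  for (j in seq_len(J)) for (k in seq_len(K)) if (Q[j, k] == 1) {
    pos <- pos + 1L
    amap[j, k] <- pos
  }
  na <- pos - J
  bpairs <- do.call(rbind, lapply(seq_len(K), function(k) cbind(k, seq_len(k))))
  sphere_rows <- split(J + na + seq_len(nrow(bpairs)), bpairs[, 1])
  list(J = J, K = K, na = na, amap = amap, bpairs = bpairs,
       p = pos + nrow(bpairs),
       blocks = list(d = seq_len(J), a = J + seq_len(na),
                     b = J + na + seq_len(nrow(bpairs))),
       sphere_rows = sphere_rows)
}

ifa_pack <- function(layout, d, A, B) {
  beta <- numeric(layout$p)
  beta[layout$blocks$d] <- d
  for (j in seq_len(layout$J)) for (k in seq_len(layout$K))
    if (!is.na(layout$amap[j, k])) beta[layout$amap[j, k]] <- A[j, k]
  beta[layout$blocks$b] <- B[layout$bpairs]
  beta
}

ifa_unpack <- function(layout, beta) {
  d <- beta[layout$blocks$d]
  A <- matrix(0, layout$J, layout$K)
  for (j in seq_len(layout$J)) for (k in seq_len(layout$K))
    if (!is.na(layout$amap[j, k])) A[j, k] <- beta[layout$amap[j, k]]
  B <- matrix(0, layout$K, layout$K)
  B[layout$bpairs] <- beta[layout$blocks$b]
  list(d = d, A = A, B = B)
}

#' Item response probability of the logistic item factor model
#'
#' \eqn{P(Y_{ij} = 1 | \xi_i) = \mathrm{logistic}(d_j + a_j^\top \xi_i)},
#' evaluated stably for extreme linear predictors.
#'
#' @param d_j item intercept.
#' @param a_j loading vector.
#' @param xi factor value vector (or matrix with one row per person).
#' @return Probability in (0, 1), vectorized over rows of `xi`.
#' @examples
#' item_response_prob(0, 0, 0)       # 0.5
#' item_response_prob(log(3), 0, 0)  # 0.75
#' @export
item_response_prob <- function(d_j, a_j, xi) {
  if (is.matrix(xi)) eta <- d_j + as.numeric(xi %*% a_j)
  else eta <- d_j + sum(a_j * xi)
  1 / (1 + exp(-eta))
}

#' Complete-data negative log-likelihood of the item factor model
#'
#' \eqn{H(\xi, \beta) = -\log f(y, \xi | \beta) + R_1(\beta)}: the Bernoulli
#' terms plus the Gaussian prior density of the factors under
#' \eqn{\Sigma = BB^\top}, plus the optional smooth ridge part
#' \eqn{\lambda_1 \sum a_{jk}^2} of an elastic-net penalty.
#'
#' @param xi N x K latent factor matrix.
#' @param d,A,B model parameters (intercepts, loadings, Cholesky factor).
#' @param Y N x J binary response matrix.
#' @param lambda1 smooth ridge weight (0 for none).
#' @return Scalar value of \eqn{H}.
#' @export
ifa_complete_negloglik <- function(xi, d, A, B, Y, lambda1 = 0) {
  N <- nrow(Y); K <- ncol(B)
  Eta <- sweep(xi %*% t(A), 2, d, "+")
  bern <- sum(Y * Eta - log1pexp(Eta))
  dtB <- det(B)
  if (abs(dtB) < 1e-12) stop("rank-deficient Cholesky factor")
  Sigma <- B %*% t(B)
  quad <- sum(xi * t(solve(Sigma, t(xi))))
  gauss <- -N * K / 2 * log(2 * pi) - N * log(abs(dtB)) - quad / 2
  -(bern + gauss) + lambda1 * sum(A^2)
}

#' Gradient and diagonal Hessian of the complete-data objective
#'
#' Analytic first and (diagonal) second derivatives of
#' [ifa_complete_negloglik()] with respect to the free parameters in the
#' packed layout (intercepts, free loadings, lower-triangular Cholesky
#' entries).
#'
#' @inheritParams ifa_complete_negloglik
#' @param Q binary design matrix (defaults to all ones: every loading free).
#' @return List with `grad`, `hess` (length-p vectors) and `blocks`.
#' @export
ifa_grad_diag_hess <- function(xi, d, A, B, Y, Q = NULL, lambda1 = 0) {
  if (is.null(Q)) Q <- matrix(1L, nrow(A), ncol(A))
  layout <- ifa_layout(Q)
  res <- .ifa_grad_hess(Y, xi, d, A, B, Q, lambda1)
  list(grad = as.numeric(res$grad), hess = as.numeric(res$hess),
       blocks = layout$blocks)
}

#' Gibbs sampling of the latent factors by adaptive rejection sampling
#'
#' Performs full Gibbs scans over the latent factor matrix; each coordinate
#' is drawn from its univariate full conditional (log-concave: logistic
#' likelihood times Gaussian prior conditional) by adaptive rejection
#' sampling.  Persons are conditionally independent given the data and are
#' updated independently.
#'
#' @inheritParams ifa_complete_negloglik
#' @param xi N x K matrix of current latent values (the chain state).
#' @param n_sweeps number of full scans.
#' @return The updated N x K latent matrix.
#' @export
ifa_gibbs_xi <- function(Y, d, A, B, xi, n_sweeps = 1L) {
  stopifnot(nrow(xi) == nrow(Y), ncol(xi) == ncol(A))
  .ifa_gibbs(Y, as.numeric(d), A, B, xi, as.integer(n_sweeps))
}

#' Marginal log-likelihood by tensor-product Gauss-Hermite quadrature
#'
#' Evaluates the marginal likelihood of the logistic item factor model by
#' adapting the Gauss-Hermite grid to the factor covariance through the
#' transform \eqn{x = \sqrt 2\, B z}.  Intended as a reference for low
#' dimensions (`K <= 3`).
#'
#' @inheritParams ifa_complete_negloglik
#' @param n_quad quadrature points per dimension.
#' @return The marginal log-likelihood value.
#' @export
ifa_marginal_loglik <- function(d, A, B, Y, n_quad = 31L) {
  K <- ncol(B)
  if (K > 3) stop("quadrature reference supports K <= 3 only")
  gh <- pracma::gaussHermite(n_quad)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_quad)), K)))
  Z <- matrix(gh$x[grid], ncol = K)
  logw <- rowSums(matrix(log(gh$w)[grid], ncol = K)) - K / 2 * log(pi)
  X <- sqrt(2) * Z %*% t(B)                    # R x K node locations
  EtaN <- sweep(X %*% t(A), 2, d, "+")         # R x J
  Cr <- rowSums(log1pexp(EtaN))                # R
  L <- tcrossprod(Y, EtaN)                     # N x R  (sum_j y_ij eta_jr)
  L <- sweep(L, 2, logw - Cr, "+")
  mx <- apply(L, 1, max)
  sum(mx + log(rowSums(exp(L - mx))))
}

#' Gauss-Hermite quadrature EM reference solver for confirmatory IFA
#'
#' Bock-Aitkin EM on the confirmatory marginal maximum likelihood problem:
#' the E-step computes posterior node weights on a covariance-adapted
#' Gauss-Hermite grid, the M-step solves one weighted logistic regression
#' per item (Newton iterations restricted to the item's free loadings) and
#' updates the factor correlations by maximizing the expected Gaussian
#' log-likelihood over unit-diagonal covariance matrices.  Used as the
#' comparison standard (treated as the MML optimum) for the stochastic
#' algorithms at low `K`.
#'
#' @param Y N x J binary responses.
#' @param Q J x K binary design matrix (no all-zero rows).
#' @param n_quad quadrature points per dimension (default 31).
#' @param tol convergence tolerance on the marginal log-likelihood change.
#' @param max_iter EM iteration cap.
#' @param start optional list with `d`, `A`, `B`.
#' @return List with `d`, `A`, `B`, `Sigma`, `loglik`, `loglik_path`,
#'   `n_iter`, `converged`.
#' @export
ifa_em <- function(Y, Q, n_quad = 31L, tol = 1e-6, max_iter = 500L,
                   start = NULL) {
  J <- nrow(Q); K <- ncol(Q); N <- nrow(Y)
  if (K > 3) stop("EM reference supports K <= 3 only")
  if (any(rowSums(Q) == 0)) stop("Q has an all-zero row")
  gh <- pracma::gaussHermite(n_quad)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_quad)), K)))
  Z <- matrix(gh$x[grid], ncol = K)
  logw <- rowSums(matrix(log(gh$w)[grid], ncol = K)) - K / 2 * log(pi)

  if (is.null(start))
    start <- list(d = numeric(J), A = matrix(1, J, K) * Q, B = diag(K))
  d <- start$d; A <- start$A; B <- start$B
  Sigma <- B %*% t(B)

  loglik_path <- numeric(0)
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  repeat {
    it <- it + 1L
    X <- sqrt(2) * Z %*% t(B)                  # R x K
    EtaN <- sweep(X %*% t(A), 2, d, "+")
    Cr <- rowSums(log1pexp(EtaN))
    L <- sweep(tcrossprod(Y, EtaN), 2, logw - Cr, "+")
    mx <- apply(L, 1, max)
    W <- exp(L - mx)
    rs <- rowSums(W)
    ll <- sum(mx + log(rs))
    loglik_path <- c(loglik_path, ll)
    W <- W / rs                                # posterior node weights
    nr <- colSums(W)                           # expected count per node
    Sj <- crossprod(Y, W)                      # J x R expected successes

    # M-step: per-item weighted logistic regressions
    for (j in seq_len(J)) {
      free <- which(Q[j, ] == 1)
      Xj <- rbind(1, t(X[, free, drop = FALSE]))   # (1+|free|) x R
      par <- c(d[j], A[j, free])
      for (nit in 1:50) {
        eta <- as.numeric(crossprod(Xj, par))
        pj <- 1 / (1 + exp(-eta))
        g <- Xj %*% (nr * pj - Sj[j, ])
        Hm <- Xj %*% (t(Xj) * (nr * pj * (1 - pj)))
        step <- solve(Hm + diag(1e-10, nrow(Hm)), g)
        par <- par - step
        if (max(abs(step)) < 1e-10) break
      }
      d[j] <- par[1]
      A[j, free] <- par[-1]
    }

    # M-step: unit-diagonal covariance from expected second moments
    M2 <- crossprod(X, X * nr) / N
    if (K == 1) {
      Sigma <- matrix(1, 1, 1)
    } else if (K == 2) {
      f <- function(s) {
        S <- matrix(c(1, s, s, 1), 2, 2)
        determinant(S)$modulus + sum(diag(solve(S, M2)))
      }
      s12 <- optimize(f, c(-0.999, 0.999))$minimum
      Sigma <- matrix(c(1, s12, s12, 1), 2, 2)
    } else {
      obj <- function(rho) {
        S <- diag(K)
        S[lower.tri(S)] <- rho
        S <- S + t(S) - diag(K)
        ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < 1e-8) return(1e10)
        determinant(S)$modulus + sum(diag(solve(S, M2)))
      }
      rho0 <- Sigma[lower.tri(Sigma)]
      opt <- stats::optim(rho0, obj, method = "Nelder-Mead")
      S <- diag(K)
      S[lower.tri(S)] <- opt$par
      Sigma <- S + t(S) - diag(K)
    }
    B <- t(chol(Sigma))

    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    ll_old <- ll
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations", max_iter))
  list(d = d, A = A, B = B, Sigma = Sigma, loglik = ll,
       loglik_path = loglik_path, n_iter = it, converged = converged)
}

#' Spectral starting values for exploratory item factor analysis
#'
#' Deterministic data-driven starting values: the top-K singular vectors of
#' the centered response matrix, scaled to the logit metric, rotated toward
#' a sparse pattern by promax, with the implied factor correlation matrix.
#' A good starting point matters because the regularized exploratory
#' objective is non-convex with rotated local optima; spectral and
#' joint-likelihood starts are the standard remedies.
#'
#' @param Y N x J binary response matrix.
#' @param K number of factors.
#' @return List with `d`, `A`, `B` suitable as `start` for [fit_ifa()].
#' @export
ifa_spectral_start <- function(Y, K) {
  N <- nrow(Y)
  d0 <- qlogis(pmin(pmax(colMeans(Y), 0.02), 0.98))
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sv <- svd(Yc, nu = 0, nv = K)
  A0 <- 4 * sv$v %*% diag(sv$d[seq_len(K)], K, K) / sqrt(N)
  Phi <- diag(K)
  if (K > 1) {
    rot <- tryCatch({
      pm <- stats::promax(A0)
      R <- crossprod(pm$rotmat)
      Phi2 <- solve(R)
      sc <- 1 / sqrt(diag(Phi2))
      Phi2 <- diag(sc, K, K) %*% Phi2 %*% diag(sc, K, K)
      list(A = unclass(pm$loadings), Phi = Phi2)
    }, error = function(e) NULL)
    if (!is.null(rot)) { A0 <- rot$A; Phi <- rot$Phi }
  }
  sgn <- sign(colSums(A0)); sgn[sgn == 0] <- 1
  A0 <- sweep(A0, 2, sgn, "*")
  Phi <- diag(sgn, K, K) %*% Phi %*% diag(sgn, K, K)
  ev <- eigen(Phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0.05) Phi <- 0.95 * Phi + 0.05 * diag(K)
  list(d = as.numeric(d0), A = A0, B = t(chol(Phi)))
}

#' Fit an item factor model by the stochastic proximal algorithm
#'
#' Front-end to the compiled engine.  `penalty = "none"` fits the
#' confirmatory model (zero constraints from `Q`, no penalty);
#' `"lasso"` and `"elastic_net"` fit the regularized exploratory model in
#' which every loading is free and the non-smooth part soft-thresholds the
#' loadings, while the Cholesky rows of the factor covariance are projected
#' onto the unit sphere in every iteration.
#'
#' @param Y N x J binary response matrix.
#' @param Q J x K binary design matrix; required for `penalty = "none"`,
#'   defaults to all ones otherwise.
#' @param K number of factors (needed only when `Q` is absent).
#' @param penalty `"none"`, `"lasso"`, or `"elastic_net"`.
#' @param lambda L1 weight for `"lasso"`.
#' @param lambda1,lambda2 ridge and L1 weights for `"elastic_net"`.
#' @param control a [usp_control()].
#' @param start optional list with `d`, `A`, `B`.  Confirmatory fits start
#'   at `d = 0`, loadings 1 on the design support, `B = I`; exploratory
#'   fits default to the spectral promax start [ifa_spectral_start()].
#' @param seed optional integer seed.
#' @return An object of class `ifa_fit`: averaged estimates `d`, `A`, `B`,
#'   the implied correlation matrix `Sigma` (rows of the averaged Cholesky
#'   factor renormalized to unit length), last iterates, the scaling
#'   diagnostics, and the iteration trace.
#' @export
fit_ifa <- function(Y, Q = NULL, K = NULL,
                    penalty = c("none", "lasso", "elastic_net"),
                    lambda = 0, lambda1 = 0, lambda2 = 0,
                    control = usp_control(), start = NULL, seed = NULL) {
  penalty <- match.arg(penalty)
  Y <- as.matrix(Y)
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  if (penalty == "none") {
    if (is.null(Q)) stop("confirmatory fit requires a Q matrix")
  } else if (is.null(Q)) {
    if (is.null(K)) stop("exploratory fit requires Q or K")
    Q <- matrix(1L, ncol(Y), K)
  }
  Q <- as.matrix(Q)
  storage.mode(Q) <- "integer"
  if (penalty == "none" && any(rowSums(Q) == 0))
    stop("Q has an all-zero row")
  J <- ncol(Y); K <- ncol(Q)
  if (penalty == "lasso") { lambda2 <- lambda; lambda1 <- 0 }
  pen_code <- match(penalty, c("none", "lasso", "elastic_net")) - 1L
  if (is.null(start)) {
    start <- if (penalty == "none")
      list(d = numeric(J), A = matrix(1, J, K) * Q, B = diag(K))
    else ifa_spectral_start(Y, K)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- .ifa_usp(Y, Q, as.numeric(start$d), start$A, start$B,
                  pen_code, lambda1, lambda2,
                  variant_code(control$variant), control$max_iter,
                  control$burn_in, control$mu, control$epsilon,
                  if (is.null(control$c1)) -1 else control$c1,
                  control$c2, control$stop_threshold,
                  control$stop_window, control$keep_history, control$thin,
                  control$stem_tol, control$stem_max_inner,
                  control$gibbs_sweeps, control$curv_clamp)
  Bavg <- res$B
  rn <- sqrt(rowSums(Bavg^2))
  Bn <- Bavg / rn
  structure(list(d = as.numeric(res$d), A = res$A, B = Bavg,
                 Sigma = Bn %*% t(Bn),
                 last = list(d = as.numeric(res$last_d), A = res$last_A,
                             B = res$last_B),
                 beta = as.numeric(res$beta),
                 d_avg = as.numeric(res$d_avg),
                 n_iter = res$n_iter, stopped = res$stopped,
                 diffs = as.numeric(res$diffs),
                 history = res$history,
                 xi = res$xi,
                 layout = ifa_layout(Q), Q = Q, penalty = penalty,
                 lambda1 = lambda1, lambda2 = lambda2,
                 control = control), class = "ifa_fit")
}

#' @export
print.ifa_fit <- function(x, ...) {
  cat(sprintf("ifa_fit (%s, %s): J = %d items, K = %d factors, %d iterations%s\n",
              x$penalty, x$control$variant, nrow(x$A), ncol(x$A), x$n_iter,
              if (x$stopped) " (stopped adaptively)" else ""))
  if (x$penalty != "none")
    cat(sprintf("  nonzero loadings: %d of %d\n", sum(x$A != 0), length(x$A)))
  cat(sprintf("  factor correlations: %s\n",
              paste(sprintf("%.3f", x$Sigma[lower.tri(x$Sigma)]),
                    collapse = " ")))
  invisible(x)
}

#' Assemble a generic-engine model interface for the item factor model
#'
#' Exposes the item factor back-end through the [usp_model()] contract so
#' that the pure-R engine [usp_run()] and [louis_hessian()] can operate on
#' it; the stochastic step, derivatives and proximal map call the same
#' compiled primitives as [fit_ifa()].
#'
#' @inheritParams fit_ifa
#' @param gibbs_sweeps Gibbs scans per stochastic step.
#' @return A [usp_model()] whose parameter vector follows the packed layout
#'   (`blocks` attached).
#' @export
ifa_usp_model <- function(Y, Q, penalty = c("none", "lasso", "elastic_net"),
                          lambda = 0, lambda1 = 0, lambda2 = 0,
                          gibbs_sweeps = 1L) {
  penalty <- match.arg(penalty)
  if (penalty == "lasso") { lambda2 <- lambda; lambda1 <- 0 }
  Q <- as.matrix(Q)
  storage.mode(Q) <- "integer"
  layout <- ifa_layout(Q)
  N <- nrow(Y)
  l1 <- if (penalty == "elastic_net") lambda1 else 0
  prox_fun <- function(beta_tilde, weights, gamma) {
    out <- beta_tilde
    if (penalty != "none" && lambda2 > 0) {
      idx <- layout$blocks$a
      out[idx] <- soft_threshold(out[idx], lambda2 * gamma / weights[idx])
    }
    for (idx in layout$sphere_rows)
      out[idx] <- prox_sphere_row(out[idx], weights[idx])
    out
  }
  usp_model(
    sample_latent = function(y, beta, xi, t) {
      par <- ifa_unpack(layout, beta)
      if (is.null(xi)) xi <- matrix(0, N, layout$K)
      ifa_gibbs_xi(y, par$d, par$A, par$B, xi, gibbs_sweeps)
    },
    grad = function(y, xi, beta) {
      par <- ifa_unpack(layout, beta)
      as.numeric(.ifa_grad_hess(y, xi, par$d, par$A, par$B, Q, l1)$grad)
    },
    diag_hess = function(y, xi, beta) {
      par <- ifa_unpack(layout, beta)
      as.numeric(.ifa_grad_hess(y, xi, par$d, par$A, par$B, Q, l1)$hess)
    },
    prox = prox_fun,
    n_params = layout$p,
    objective = function(y, xi, beta) {
      par <- ifa_unpack(layout, beta)
      ifa_complete_negloglik(xi, par$d, par$A, par$B, y, l1)
    },
    loglik_grad_full = function(y, xi, beta) {
      par <- ifa_unpack(layout, beta)
      -as.numeric(.ifa_grad_hess(y, xi, par$d, par$A, par$B, Q, 0)$grad)
    },
    blocks = layout$blocks)
}
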