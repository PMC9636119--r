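test_that("item response probability is the stable logistic", {
  expect_equal(item_response_prob(0, 0, 0), 0.5)
  expect_equal(item_response_prob(log(3), c(0, 0), c(1, 1)), 0.75)
  # extreme tail agrees with exp(eta) to 1% relative
  p <- item_response_prob(-30, 1, 0)
  expect_equal(p, exp(-30), tolerance = 0.01)
  expect_true(is.finite(item_response_prob(700, 0, 0)))
})

test_that("complete-data objective: closed form, additivity, naive oracle", {
  v <- ifa_complete_negloglik(matrix(0, 1, 1), 0, matrix(0, 1, 1),
                              matrix(1, 1, 1), matrix(1, 1, 1))
  expect_equal(v, log(2) + 0.5 * log(2 * pi))
  # doubling the data doubles the value
  set.seed(3)
  N <- 12; J <- 4; K <- 2
  Y <- matrix(rbinom(N * J, 1, 0.5), N, J)
  Xi <- matrix(rnorm(N * K), N, K)
  d <- rnorm(J); A <- matrix(runif(J * K), J, K)
  B <- t(chol(matrix(c(1, 0.3, 0.3, 1), 2, 2)))
  v1 <- ifa_complete_negloglik(Xi, d, A, B, Y)
  v2 <- ifa_complete_negloglik(rbind(Xi, Xi), d, A, B, rbind(Y, Y))
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  # naive double-loop oracle
  Sg <- B %*% t(B)
  acc <- 0
  for (i in 1:N) {
    for (j in 1:J) {
      eta <- d[j] + sum(A[j, ] * Xi[i, ])
      acc <- acc - (Y[i, j] * eta - log(1 + exp(eta)))
    }
    acc <- acc - (-K / 2 * log(2 * pi) - 0.5 * log(det(Sg)) -
                    0.5 * drop(Xi[i, ] %*% solve(Sg, Xi[i, ])))
  }
  expect_equal(v1, acc, tolerance = 1e-10)
})

test_that("analytic gradient and diagonal Hessian match finite differences", {
  set.seed(17)
  N <- 25; J <- 6; K <- 3
  Q <- matrix(rbinom(J * K, 1, 0.7), J, K); Q[rowSums(Q) == 0, 1] <- 1L
  A <- matrix(runif(J * K, 0.5, 1.5) * Q, J, K)
  d <- rnorm(J)
  S <- matrix(0.3, K, K); diag(S) <- 1
  B <- t(chol(S))
  Xi <- matrix(rnorm(N * K), N, K)
  Y <- matrix(rbinom(N * J, 1, 0.5), N, J)
  lam1 <- 0.7
  gh <- ifa_grad_diag_hess(Xi, d, A, B, Y, Q, lambda1 = lam1)
  lay <- proxlvm:::ifa_layout(Q)
  b0 <- proxlvm:::ifa_pack(lay, d, A, B)
  Hf <- function(beta) {
    pp <- proxlvm:::ifa_unpack(lay, beta)
    ifa_complete_negloglik(Xi, pp$d, pp$A, pp$B, Y, lambda1 = lam1)
  }
  grad_at <- function(beta) {
    pp <- proxlvm:::ifa_unpack(lay, beta)
    ifa_grad_diag_hess(Xi, pp$d, pp$A, pp$B, Y, Q, lambda1 = lam1)$grad
  }
  g_fd <- h_fd <- numeric(length(b0))
  for (i in seq_along(b0)) {
    e <- numeric(length(b0)); e[i] <- 1e-5
    g_fd[i] <- (Hf(b0 + e) - Hf(b0 - e)) / 2e-5
    # diagonal Hessian as central differences of the analytic gradient
    h_fd[i] <- (grad_at(b0 + e)[i] - grad_at(b0 - e)[i]) / 2e-5
  }
  expect_lt(max(abs(gh$grad - g_fd) / (1 + abs(g_fd))), 1e-6)
  expect_lt(max(abs(gh$hess - h_fd) / (1 + abs(h_fd))), 1e-4)
  # Bernoulli gradient vanishes when fitted probabilities equal the data
  Y1 <- matrix(1, 5, 2)
  gh1 <- ifa_grad_diag_hess(matrix(0, 5, 2), rep(40, 2),
                            matrix(0, 2, 2), diag(2), Y1)
  expect_lt(max(abs(gh1$grad[1:2])), 1e-10)
})

test_that("Gibbs/ARS sampling reproduces the prior when the likelihood is
           flat", {
  set.seed(19)
  S <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  B <- t(chol(S))
  xs <- ifa_gibbs_xi(matrix(0, 4000, 3), rep(0, 3), matrix(0, 3, 2), B,
                     matrix(0, 4000, 2), n_sweeps = 5)
  expect_lt(max(abs(colMeans(xs))), 3 * sqrt(1 / 4000) * 1.5)
  expect_lt(abs(cov(xs)[1, 2] - 0.6), 0.06)
  expect_lt(max(abs(diag(cov(xs)) - 1)), 0.1)
})

test_that("ARS draws match the quadrature-normalized posterior density on a
           one-item toy", {
  set.seed(23)
  d1 <- -0.5; a1 <- 1.5
  Y <- matrix(1, 1, 1)
  nd <- 2e4
  draws <- numeric(nd)
  xi <- matrix(0.3, 1, 1)
  for (r in seq_len(nd)) {
    xi <- ifa_gibbs_xi(Y, d1, matrix(a1, 1, 1), matrix(1, 1, 1), xi, 1)
    draws[r] <- xi[1, 1]
  }
  post <- function(x) plogis(d1 + a1 * x) * dnorm(x)
  Zc <- integrate(post, -Inf, Inf, rel.tol = 1e-12)$value
  br <- seq(-4.5, 5.5, by = 0.25)
  hp <- hist(pmin(pmax(draws, -4.4), 5.4), breaks = br, plot = FALSE)$counts / nd
  thp <- vapply(seq_len(length(br) - 1), function(i)
    integrate(post, br[i], br[i + 1], rel.tol = 1e-10)$value / Zc, 0)
  expect_lt(max(abs(hp - thp)), 0.02)
})

test_that("quadrature marginal likelihood: closed case, adaptive oracle,
           self-consistency", {
  Y1 <- matrix(rbinom(10, 1, 0.5), 10, 1)
  expect_equal(ifa_marginal_loglik(0, matrix(0, 1, 1), matrix(1, 1, 1),
                                   Y1, 21), 10 * log(0.5))
  set.seed(29)
  d1 <- 0.3; a1 <- 1.2
  Y <- matrix(rbinom(15, 1, 0.6), 15, 1)
  ql <- ifa_marginal_loglik(d1, matrix(a1, 1, 1), matrix(1, 1, 1), Y, 41)
  oracle <- sum(vapply(Y[, 1], function(y) {
    log(integrate(function(x) {
      p <- plogis(d1 + a1 * x)
      (if (y == 1) p else 1 - p) * dnorm(x)
    }, -Inf, Inf, rel.tol = 1e-12)$value)
  }, 0))
  expect_equal(ql, oracle, tolerance = 1e-8)
  # refinement 11 -> 21 -> 31 settles
  Y2 <- matrix(rbinom(60, 1, 0.5), 30, 2)
  A2 <- matrix(c(1.1, 0, 0.4, 0.9), 2, 2, byrow = TRUE)
  B2 <- t(chol(matrix(c(1, 0.4, 0.4, 1), 2, 2)))
  v <- vapply(c(11L, 21L, 31L), function(nq)
    ifa_marginal_loglik(c(0.2, -0.3), A2, B2, Y2, nq), 0)
  expect_lt(abs(v[3] - v[2]), 1e-6)
  expect_lt(abs(v[3] - v[2]), abs(v[2] - v[1]) + 1e-12)
  expect_error(ifa_marginal_loglik(rep(0, 2), matrix(0, 2, 4), diag(4),
                                   matrix(0, 2, 2), 5), "K <= 3")
})

test_that("EM reference ascends the likelihood and recovers truth at large N", {
  des <- study_design("I", seed = 5)
  set.seed(5)
  truth <- generate_ifa_params(des)
  set.seed(6)
  Y <- generate_ifa_data(truth, 8000)
  em <- ifa_em(Y, des$Q, n_quad = 21, tol = 1e-5, start = truth)
  expect_true(all(diff(em$loglik_path) > -1e-6))
  expect_lt(sqrt(mean((em$A[des$Q == 1] - truth$A[des$Q == 1])^2)), 0.1)
  expect_lt(sqrt(mean((em$d - truth$d)^2)), 0.1)
  expect_lt(abs(em$Sigma[1, 2] - 0.4), 0.1)
})

test_that("averaged stochastic gradients approach the marginal score
           (unbiasedness proxy on a K = 2 toy)", {
  set.seed(41)
  des <- study_design("I", seed = 41)
  truth <- generate_ifa_params(des)
  Y <- generate_ifa_data(truth, 150)
  Q <- des$Q
  lay <- proxlvm:::ifa_layout(Q)
  beta <- proxlvm:::ifa_pack(lay, truth$d, truth$A, truth$B)
  # average complete-data gradients over many Gibbs refreshes at fixed beta
  xi <- matrix(0, 150, 2)
  G <- numeric(lay$p)
  burn <- 30; ndr <- 400
  for (r in seq_len(burn + ndr)) {
    xi <- ifa_gibbs_xi(Y, truth$d, truth$A, truth$B, xi, 1)
    if (r > burn)
      G <- G + ifa_grad_diag_hess(xi, truth$d, truth$A, truth$B, Y, Q)$grad / ndr
  }
  # finite differences of the quadrature-evaluated -l(beta)
  nl <- function(beta) {
    pp <- proxlvm:::ifa_unpack(lay, beta)
    -ifa_marginal_loglik(pp$d, pp$A, pp$B, Y, 31)
  }
  idx <- c(1, 5, lay$blocks$a[c(1, 8)], lay$blocks$b[2])
  for (i in idx) {
    e <- numeric(lay$p); e[i] <- 1e-4
    fd <- (nl(beta + e) - nl(beta - e)) / 2e-4
    # Monte-Carlo tolerance: a few standard errors of the averaged gradient
    expect_lt(abs(G[i] - fd), 1.5)
  }
})

test_that("Louis by-product matches finite differences of the quadrature
           marginal log-likelihood on a K = 1 toy", {
  set.seed(47)
  N <- 60; J <- 2
  Q <- matrix(1L, J, 1)
  d <- c(0.2, -0.4); A <- matrix(c(1.1, 0.8), J, 1); B <- matrix(1, 1, 1)
  Xi <- matrix(rnorm(N), N, 1)
  P <- plogis(sweep(Xi %*% t(A), 2, d, "+"))
  Y <- matrix(rbinom(N * J, 1, P), N, J)
  mod <- ifa_usp_model(Y, Q, penalty = "none")
  lay <- proxlvm:::ifa_layout(Q)
  beta <- proxlvm:::ifa_pack(lay, d, A, B)
  set.seed(48)
  H <- louis_hessian(mod, Y, beta, n_draws = 3000, burn_in = 100)
  expect_equal(H, t(H))
  ll <- function(b) {
    pp <- proxlvm:::ifa_unpack(lay, b)
    ifa_marginal_loglik(pp$d, pp$A, pp$B, Y, 41)
  }
  p <- length(beta)
  Hfd <- matrix(0, p, p)
  hstep <- 1e-4
  for (i in 1:p) for (j in 1:p) {
    ei <- numeric(p); ei[i] <- hstep
    ej <- numeric(p); ej[j] <- hstep
    Hfd[i, j] <- (ll(beta + ei + ej) - ll(beta + ei - ej) -
                    ll(beta - ei + ej) + ll(beta - ei - ej)) / (4 * hstep^2)
  }
  # d and a blocks (the free curved-space entries).  Elements where the
  # complete-information and score-variance terms nearly cancel carry
  # absolute Monte-Carlo error, so the check is absolute overall and
  # relative on the dominant diagonal.
  free <- c(lay$blocks$d, lay$blocks$a)
  expect_lt(max(abs(H[free, free] - Hfd[free, free])), 0.5)
  dd <- lay$blocks$d
  expect_lt(max(abs(diag(H)[dd] - diag(Hfd)[dd]) / abs(diag(Hfd)[dd])), 0.05)
})

test_that("confirmatory fits preserve feasibility and reproduce seeds", {
  des <- study_design("I", seed = 77)
  set.seed(77)
  truth <- generate_ifa_params(des)
  Y <- generate_ifa_data(truth, 300)
  ctl <- usp_control(max_iter = 120, burn_in = 40, stop_threshold = 0)
  fit <- fit_ifa(Y, Q = des$Q, penalty = "none", control = ctl,
                 start = truth, seed = 7)
  # the last iterate satisfies the constraints exactly
  expect_lt(max(abs(rowSums(fit$last$B^2) - 1)), 1e-10)
  expect_true(all(fit$last$A[des$Q == 0] == 0))
  expect_true(all(fit$A[des$Q == 0] == 0))
  fit2 <- fit_ifa(Y, Q = des$Q, penalty = "none", control = ctl,
                  start = truth, seed = 7)
  expect_identical(fit$beta, fit2$beta)
})

test_that("an enormous L1 penalty zeroes every loading", {
  set.seed(91)
  Y <- matrix(rbinom(200 * 6, 1, 0.5), 200, 6)
  fit <- fit_ifa(Y, K = 2, penalty = "lasso", lambda = 1e5,
                 control = usp_control(max_iter = 100, burn_in = 20,
                                       stop_threshold = 0), seed = 3)
  expect_true(all(fit$A == 0))
  expect_true(all(fit$last$A == 0))
})

test_that("elastic-net fits split the penalty between the smooth and
           proximal parts", {
  set.seed(97)
  des <- study_design("I", seed = 97)
  truth <- generate_ifa_params(des)
  Y <- generate_ifa_data(truth, 250)
  fit <- fit_ifa(Y, K = 2, penalty = "elastic_net", lambda1 = 2,
                 lambda2 = 5, seed = 11,
                 control = usp_control(max_iter = 120, burn_in = 40,
                                       stop_threshold = 0))
  expect_true(all(is.finite(fit$A)))
  expect_lt(max(abs(rowSums(fit$last$B^2) - 1)), 1e-10)
  # the ridge part shrinks loadings relative to an unpenalized-ridge fit
  fit0 <- fit_ifa(Y, K = 2, penalty = "elastic_net", lambda1 = 1e4,
                  lambda2 = 0, seed = 11,
                  control = usp_control(max_iter = 120, burn_in = 40,
                                        stop_threshold = 0))
  expect_lt(mean(abs(fit0$A)), mean(abs(fit$A)))
})

test_that("iterate histories export with block-named columns", {
  set.seed(99)
  Y <- matrix(rbinom(300, 1, 0.5), 100, 3)
  Q <- matrix(1L, 3, 1)
  fit <- fit_ifa(Y, Q = Q, penalty = "none", seed = 1,
                 control = usp_control(max_iter = 20, burn_in = 5,
                                       stop_threshold = 0,
                                       keep_history = TRUE))
  dir <- tempfile()
  write_fit_result(fit, dir, seed = 1)
  on.exit(unlink(dir, recursive = TRUE))
  H <- utils::read.csv(file.path(dir, "history.csv"))
  expect_equal(nrow(H), 20L)
  expect_equal(colnames(H)[1:4], c("d_1", "d_2", "d_3", "a_1_1"))
  expect_equal(colnames(H)[7], "b_1_1")
})
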