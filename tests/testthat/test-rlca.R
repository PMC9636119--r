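test_that("profile encoding: attribute 1 is the least significant bit", {
  pm <- profile_matrix(3)
  expect_equal(nrow(pm), 8)
  expect_equal(pm[1, ], c(0L, 0L, 0L))
  expect_equal(pm[2, ], c(1L, 0L, 0L))   # code 1 = attribute 1 only
  expect_equal(pm[5, ], c(0L, 0L, 1L))   # code 4 = attribute 3 only
  expect_equal(profile_index(c(1, 1, 0)), 4L)
  expect_equal(profile_index(pm), 1:8)
  expect_equal(profile_labels(2), c("00", "10", "01", "11"))
})

test_that("profile posterior: flat case, two-profile closed form,
           enumeration oracle", {
  # flat likelihood and prior give the uniform posterior
  th <- matrix(0, 4, 8); nu <- numeric(8)
  expect_equal(rlca_profile_posterior(rep(1, 4), th, nu), rep(1 / 8, 8))
  # J = 1, K = 1, y = 1 posterior ratio
  th1 <- matrix(c(-0.7, 1.2), 1, 2); nu1 <- c(0, 0.4)
  post <- rlca_profile_posterior(1, th1, nu1)
  ratio <- exp(nu1[2]) * (exp(th1[2]) * (1 + exp(th1[1]))) /
    (exp(th1[1]) * (1 + exp(th1[2])))
  expect_equal(post[2] / post[1], ratio, tolerance = 1e-12)
  # random instance vs naive per-profile loop
  inst <- small_rlca_instance(51, N = 1, J = 5, K = 3)
  y <- inst$Y[1, ]
  post <- rlca_profile_posterior(y, inst$theta, inst$nu)
  lp <- vapply(seq_len(inst$M), function(a)
    inst$nu[a] + sum(y * inst$theta[, a] - log(1 + exp(inst$theta[, a]))), 0)
  ref <- exp(lp - max(lp)); ref <- ref / sum(ref)
  expect_equal(post, ref, tolerance = 1e-12)
  expect_equal(sum(post), 1, tolerance = 1e-12)
})

test_that("exact profile sampling follows the posterior", {
  # degenerate posterior: always the dominant profile
  th <- matrix(0, 3, 4); nu <- c(0, -50, -50, 20)
  set.seed(1)
  z <- rlca_sample_xi(matrix(0, 50, 3), th, nu)
  expect_true(all(z == 4L))
  # uniform posterior: frequencies within 3 SE
  th0 <- matrix(0, 3, 4); nu0 <- numeric(4)
  set.seed(2)
  z <- rlca_sample_xi(matrix(0, 8000, 3), th0, nu0)
  f <- tabulate(z, 4) / 8000
  expect_lt(max(abs(f - 0.25)), 3 * sqrt(0.25 * 0.75 / 8000))
  # chi-square goodness of fit on a non-uniform toy
  inst <- small_rlca_instance(52, N = 1, J = 4, K = 2)
  y <- inst$Y[1, ]
  post <- rlca_profile_posterior(y, inst$theta, inst$nu)
  set.seed(3)
  zz <- vapply(1:20000, function(i)
    rlca_sample_xi(matrix(y, 1), inst$theta, inst$nu), 1L)
  cnt <- tabulate(zz, inst$M)
  pval <- suppressWarnings(chisq.test(cnt, p = post)$p.value)
  expect_gt(pval, 1e-3)
  # reproducible under a seed
  set.seed(9); a <- rlca_sample_xi(inst$Y, inst$theta, inst$nu)
  set.seed(9); b <- rlca_sample_xi(inst$Y, inst$theta, inst$nu)
  expect_identical(a, b)
})

test_that("complete-data derivatives match finite differences and empty
           classes contribute zeros", {
  inst <- small_rlca_instance(53, N = 40, J = 5, K = 3)
  set.seed(4)
  z <- sample(inst$M, inst$N, replace = TRUE)
  z[z == 3] <- 4   # force an empty class
  gh <- rlca_grad_diag_hess(z, inst$theta, inst$nu, inst$Y)
  idx3 <- (3 - 1) * inst$J + seq_len(inst$J)
  expect_true(all(gh$grad[idx3] == 0))
  expect_true(all(gh$hess[idx3] == 0))
  # softmax residuals sum to zero over all profiles (including baseline)
  nal <- tabulate(z, inst$M)
  pi <- exp(inst$nu) / sum(exp(inst$nu))
  full_grad_nu <- inst$N * pi - nal
  expect_equal(sum(full_grad_nu), 0, tolerance = 1e-10)
  # finite differences of the complete-data negative log-likelihood
  H <- function(beta) {
    th <- matrix(beta[seq_len(inst$J * inst$M)], inst$J, inst$M)
    nu <- c(0, beta[inst$J * inst$M + seq_len(inst$M - 1)])
    lpi <- nu - log(sum(exp(nu)))
    -sum(lpi[z]) - sum(vapply(seq_len(inst$N), function(i)
      sum(inst$Y[i, ] * th[, z[i]] - log(1 + exp(th[, z[i]]))), 0))
  }
  b0 <- c(as.numeric(inst$theta), inst$nu[-1])
  g_fd <- vapply(seq_along(b0), function(i) {
    e <- numeric(length(b0)); e[i] <- 1e-5
    (H(b0 + e) - H(b0 - e)) / 2e-5
  }, 0)
  expect_lt(max(abs(gh$grad - g_fd)), 1e-5)
})

test_that("constraint construction partitions profiles by the mastery
           relation", {
  # all-zero design row: every profile capable, all values tied
  cs <- rlca_constraints(matrix(c(0, 0), 1, 2))
  expect_equal(cs[[1]]$capable, 1:4)
  expect_equal(nrow(cs[[1]]$Aeq), 3)
  expect_equal(nrow(cs[[1]]$Ain), 0)
  # K = 2, q = (1, 0): capable = {10, 11} (indices 2, 4)
  cs <- rlca_constraints(matrix(c(1, 0), 1, 2))
  expect_equal(cs[[1]]$capable, c(2L, 4L))
  expect_equal(cs[[1]]$incapable, c(1L, 3L))
  # the benchmark design matrix: item 13 requires attributes 1 and 2,
  # so 4 of the 16 profiles are capable
  Q <- proxlvm:::study3_qmatrix()
  expect_equal(Q[13, ], c(1L, 1L, 0L, 0L))
  cs <- rlca_constraints(Q)
  expect_equal(length(cs[[13]]$capable), 4L)
  pm <- profile_matrix(4)
  expect_true(all(pm[cs[[13]]$capable, 1] == 1 & pm[cs[[13]]$capable, 2] == 1))
  # the all-ones profile is capable for every item
  for (j in seq_len(nrow(Q))) expect_true(16L %in% cs[[j]]$capable)
})

test_that("DINA parameterization and its feasibility", {
  Q <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  th <- dina_theta(rep(0.5, 3), rep(0.5, 3), Q)
  expect_true(all(th == 0))
  th2 <- dina_theta(rep(0.2, 3), rep(0.2, 3), Q)
  cs <- rlca_constraints(Q)
  expect_equal(th2[1, cs[[1]]$capable], rep(log(4), 2), tolerance = 1e-12)
  expect_equal(th2[1, cs[[1]]$incapable], rep(-log(4), 2), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:5) {
    s <- runif(3, 0.05, 0.45); g <- runif(3, 0.05, 0.45)
    expect_true(rlca_feasible(dina_theta(s, g, Q), cs))
  }
  expect_error(dina_theta(c(0, 0.1, 0.1), rep(0.1, 3), Q), "0, 1")
})

test_that("marginal likelihood is invariant to the profile ordering
           convention", {
  inst <- small_rlca_instance(54, N = 30, J = 4, K = 2)
  ll <- rlca_marginal_loglik(inst$theta, inst$nu, inst$Y)
  # recompute with profiles enumerated in reversed order
  perm <- rev(seq_len(inst$M))
  nu_p <- inst$nu[perm]
  lp <- sweep(inst$Y %*% inst$theta[, perm], 2,
              (nu_p - log(sum(exp(inst$nu)))) -
                colSums(log(1 + exp(inst$theta[, perm]))), "+")
  mx <- apply(lp, 1, max)
  expect_equal(ll, sum(mx + log(rowSums(exp(lp - mx)))), tolerance = 1e-10)
})

test_that("exact sampling makes the averaged gradient an unbiased estimate
           of the marginal score (K = 3 toy)", {
  set.seed(61)
  K <- 3; J <- 6; N <- 80; M <- 8
  Q <- matrix(rbinom(J * K, 1, 0.5), J, K); Q[rowSums(Q) == 0, 1] <- 1L
  s <- runif(J, 0.1, 0.2); g <- runif(J, 0.1, 0.2)
  theta <- dina_theta(s, g, Q)
  nu <- numeric(M)
  z <- sample(M, N, replace = TRUE)
  P <- plogis(t(theta[, z]))
  Y <- matrix(rbinom(N * J, 1, P), N, J)
  G <- numeric(J * M + M - 1)
  R <- 600
  set.seed(62)
  for (r in 1:R) {
    zz <- rlca_sample_xi(Y, theta, nu)
    G <- G + rlca_grad_diag_hess(zz, theta, nu, Y)$grad / R
  }
  nl <- function(beta) {
    th <- matrix(beta[seq_len(J * M)], J, M)
    nu2 <- c(0, beta[J * M + seq_len(M - 1)])
    -rlca_marginal_loglik(th, nu2, Y)
  }
  b0 <- c(as.numeric(theta), nu[-1])
  idx <- c(1, 10, 25, J * M + 2, J * M + 5)
  for (i in idx) {
    e <- numeric(length(b0)); e[i] <- 1e-5
    fd <- (nl(b0 + e) - nl(b0 - e)) / 2e-5
    expect_lt(abs(G[i] - fd), 1)   # a few Monte-Carlo standard errors
  }
})

test_that("fitted parameters satisfy the constraint set and runs are
           reproducible", {
  des <- study_design("III", N = 400, seed = 71)
  set.seed(71)
  dat <- generate_rlca_data(des, N = 400)
  ctl <- usp_control(max_iter = 150, burn_in = 50, stop_threshold = 0)
  fit <- fit_rlca(dat$Y, des$Q, control = ctl, seed = 5)
  expect_true(rlca_feasible(fit$theta, fit$constraints, tol = 1e-7))
  expect_true(rlca_feasible(fit$last$theta, fit$constraints, tol = 1e-7))
  expect_equal(fit$nu[1], 0)
  fit2 <- fit_rlca(dat$Y, des$Q, control = ctl, seed = 5)
  expect_identical(fit$theta, fit2$theta)
  expect_identical(fit$nu, fit2$nu)
})

test_that("the pure-R engine and the compiled engine walk the same
           trajectory", {
  inst <- small_rlca_instance(81, N = 30, J = 4, K = 2)
  s <- runif(inst$J, 0.1, 0.3); g <- runif(inst$J, 0.1, 0.3)
  theta0 <- dina_theta(s, g, inst$Q)
  ctl <- usp_control(max_iter = 6, burn_in = 2, stop_threshold = 0,
                     c1 = 1, c2 = 100, keep_history = TRUE)
  fitC <- fit_rlca(inst$Y, inst$Q,
                   start = list(theta = theta0, nu = numeric(inst$M)),
                   control = ctl, seed = 123)
  mod <- rlca_usp_model(inst$Y, inst$Q)
  beta0 <- c(as.numeric(theta0), numeric(inst$M - 1))
  set.seed(123)
  trR <- usp_run(mod, inst$Y, beta0, ctl)
  expect_equal(dim(fitC$history), dim(trR$history))
  expect_lt(max(abs(fitC$history - trR$history)), 1e-8)
})

test_that("the StEM variant produces feasible estimates for the RLCA model", {
  des <- study_design("III", N = 250, seed = 91)
  set.seed(91)
  dat <- generate_rlca_data(des, N = 250)
  fit <- fit_rlca(dat$Y, des$Q, seed = 4,
                  control = usp_control(max_iter = 40, burn_in = 10,
                                        stop_threshold = 0,
                                        variant = "StEM"))
  expect_true(rlca_feasible(fit$theta, fit$constraints, tol = 1e-7))
  expect_true(all(is.finite(fit$theta)))
})
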