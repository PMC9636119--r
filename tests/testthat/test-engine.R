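test_that("step size follows the polynomial and harmonic schedules", {
  expect_equal(step_size(1, step_schedule(mu = 1, epsilon = 0.01)), 1.0)
  expect_equal(step_size(100), 100^(-0.51), tolerance = 1e-14)
  expect_equal(step_size(4, step_schedule(mode = "harmonic")), 0.25)
  expect_error(step_size(0), "positive")
  # square-summability of the polynomial schedule
  g <- step_size(1:5000)
  expect_true(all(diff(g) < 0))
  expect_lt(sum(g^2), Inf)
})

test_that("truncation clamps into the interval", {
  expect_equal(truncate_interval(0.5, 1, 10), 1)
  expect_equal(truncate_interval(3, 1, 10), 3)
  expect_equal(truncate_interval(99, 1, 10), 10)
  expect_error(truncate_interval(1, 5, 2), "exceed")
})

test_that("scaling update has the expected fixed points and stays bounded", {
  # constant inputs at the fixed point: d_avg stays at h
  h <- 5
  st <- scaling_state(2, c1 = 1, c2 = 10)
  st$delta1 <- rep(h, 2)
  st$d_avg <- rep(h, 2)
  st$t <- 3L
  for (t in 4:20) {
    st <- update_scaling(st, grad = c(0, 0), hess_diag = c(h, h),
                         gamma_t = step_size(t))
    expect_equal(st$d_avg, c(h, h))
  }
  # c1 = c2 = 1 degenerates to the unscaled case whatever the inputs
  st <- scaling_state(3, c1 = 1, c2 = 1)
  set.seed(1)
  for (t in 1:10) {
    st <- update_scaling(st, rnorm(3, 0, 5), rnorm(3, 2, 3),
                         min(step_size(t), 1))
    expect_equal(st$d_avg, rep(1, 3))
  }
  # bounds hold after every update with random streams
  st <- scaling_state(4, c1 = 0.5, c2 = 20)
  for (t in 1:50) {
    st <- update_scaling(st, rnorm(4, 0, 3), runif(4, 0, 40),
                         min(step_size(t), 1))
    expect_true(all(st$d_avg >= 0.5 - 1e-12 & st$d_avg <= 20 + 1e-12))
  }
})

test_that("scaling recursions match an independently coded replay", {
  set.seed(42)
  p <- 6
  grads <- matrix(rnorm(50 * p), 50, p)
  hesss <- matrix(runif(50 * p, 0, 10), 50, p)
  c1 <- 0.2; c2 <- 8
  st <- scaling_state(p, c1, c2)
  # straight-line replay of the two recursions
  d1 <- d2 <- da <- numeric(p)
  for (t in 1:50) {
    g <- min(step_size(t), 1)
    st <- update_scaling(st, grads[t, ], hesss[t, ], g)
    d1 <- (1 - g) * d1 + g * (hesss[t, ] - grads[t, ]^2)
    d2 <- (1 - g) * d2 + g * grads[t, ]
    da <- ((t - 1) / t) * da + pmin(pmax(d1 + d2^2, c1), c2) / t
  }
  expect_equal(st$delta1, d1, tolerance = 1e-12)
  expect_equal(st$delta2, d2, tolerance = 1e-12)
  expect_equal(st$d_avg, da, tolerance = 1e-12)
})

test_that("Polyak-Ruppert averaging: examples and streaming equivalence", {
  expect_equal(polyak_ruppert_average(rep(3, 10), 4), 3)
  expect_equal(polyak_ruppert_average(c(1, 2, 3, 4), 2), 3.5)
  expect_error(polyak_ruppert_average(1:3, 5), "exceed")
  set.seed(7)
  H <- matrix(rnorm(1000 * 3), 1000, 3)
  batch <- polyak_ruppert_average(H, 100)
  stream <- numeric(3); n <- 0
  for (t in 101:1000) { n <- n + 1; stream <- stream + (H[t, ] - stream) / n }
  expect_equal(stream, batch, tolerance = 1e-12)
})

test_that("window stopping check behaves on constructed sequences", {
  b <- matrix(1, 4, 2)
  expect_true(stopping_check(b, window = 3, threshold = 1e-3))
  b[3, ] <- 5
  expect_false(stopping_check(b, window = 3, threshold = 1e-3))
  expect_false(stopping_check(matrix(1, 2, 2), window = 3, threshold = 1))
  # alternating +/- threshold/2 per coordinate passes under the max-norm
  th <- 0.1
  b <- matrix(c(0, th / 2, 0, th / 2), 4, 2)
  expect_true(stopping_check(b, window = 3, threshold = th))
})

test_that("by-product averaging matches the hand-unrolled recursion", {
  sched <- step_schedule()
  expect_equal(byproduct_average(rep(2.5, 20), sched, 5), 2.5)
  # two-value stream, unrolled for t = 1..4
  m <- c(1, 3, 1, 3)
  g2 <- step_size(2); g3 <- step_size(3); g4 <- step_size(4)
  M1 <- 1
  M2 <- M1 + g2 * (3 - M1)
  M3 <- M2 + g3 * (1 - M2)
  M4 <- M3 + g4 * (3 - M3)
  expect_equal(byproduct_average(m, sched, 0), mean(c(M1, M2, M3, M4)))
  # iid stream: averaged value approaches the mean
  set.seed(3)
  x <- rnorm(4000, 1.7, 1)
  expect_lt(abs(byproduct_average(x, sched, 100) - 1.7), 0.1)
  expect_error(byproduct_average(list(1, c(1, 2)), sched), "shape")
})

test_that("engine recovers the MLE on the degenerate Gaussian model", {
  set.seed(5)
  y <- rnorm(100, 2, 1)
  mod <- gaussian_toy_model()
  tr <- usp_run(mod, y, 0, usp_control(max_iter = 2000, burn_in = 200,
                                       stop_threshold = 0, c1 = 1e-2))
  expect_lt(abs(tr$average - mean(y)), 0.01)
  # StEM solves it in one iteration
  tr2 <- usp_run(mod, y, 0, usp_control(max_iter = 3, burn_in = 1,
                                        variant = "StEM", stop_threshold = 0))
  expect_equal(tr2$last, mean(y))
})

test_that("with g = 0 and c1 = c2 = 1 the engine is plain SGD, bitwise", {
  set.seed(6)
  y <- rnorm(50, -1, 1)
  tr <- usp_run(gaussian_toy_model(), y, 0,
                usp_control(max_iter = 40, burn_in = 5, c1 = 1, c2 = 1,
                            stop_threshold = 0, keep_history = TRUE))
  beta <- 0; N <- length(y); S <- sum(y)
  ref <- numeric(40)
  for (t in 1:40) {
    beta <- beta - (1 * t^(-0.5 - 0.01)) * (N * beta - S)
    ref[t] <- beta
  }
  expect_identical(as.numeric(tr$history[, 1]), ref)
})

test_that("USP-PPG equals USP when c1 = c2 in both configurations", {
  set.seed(9)
  y <- rnorm(60, 0.5, 1)
  mod <- latent_gaussian_toy_model()
  set.seed(11)
  tr1 <- usp_run(mod, y, 0, usp_control(max_iter = 100, burn_in = 10,
                                        c1 = 2, c2 = 2, stop_threshold = 0,
                                        keep_history = TRUE))
  set.seed(11)
  tr2 <- usp_run(mod, y, 0, usp_control(max_iter = 100, burn_in = 10,
                                        c1 = 2, variant = "USP-PPG",
                                        stop_threshold = 0,
                                        keep_history = TRUE))
  expect_identical(tr1$history, tr2$history)
})

test_that("runs are bitwise reproducible under a fixed seed", {
  set.seed(13)
  y <- rnorm(40, 1, 1)
  mod <- latent_gaussian_toy_model()
  set.seed(99)
  a <- usp_run(mod, y, 0, usp_control(max_iter = 80, burn_in = 20,
                                      stop_threshold = 0, c1 = 1e-2))
  set.seed(99)
  b <- usp_run(mod, y, 0, usp_control(max_iter = 80, burn_in = 20,
                                      stop_threshold = 0, c1 = 1e-2))
  expect_identical(a$average, b$average)
  expect_identical(a$diffs, b$diffs)
})

test_that("averaged iterate converges at the Monte Carlo rate on the
           conjugate latent-Gaussian toy", {
  # |avg - MLE| should shrink roughly like n^(-1/2) over n = 1e2, 1e3, 1e4
  set.seed(21)
  y <- rnorm(50, 0, sqrt(2))
  mod <- latent_gaussian_toy_model()
  ns <- c(100L, 1000L, 10000L)
  errs <- sapply(ns, function(n) {
    e <- sapply(1:4, function(r) {
      set.seed(1000 + r)
      tr <- usp_run(mod, y, 0,
                    usp_control(max_iter = n, burn_in = n %/% 10L,
                                stop_threshold = 0, c1 = 1e-2))
      abs(tr$average - mean(y))
    })
    mean(e)
  })
  slope <- coef(lm(log(errs) ~ log(ns)))[2]
  expect_gt(slope, -0.7)
  expect_lt(slope, -0.3)
})

test_that("non-finite gradients raise an informative error", {
  mod <- usp_model(
    sample_latent = function(y, beta, xi, t) NULL,
    grad = function(y, xi, beta) NaN,
    diag_hess = function(y, xi, beta) 1,
    prox = function(bt, w, g) bt, n_params = 1L)
  expect_error(usp_run(mod, 1, 0, usp_control(max_iter = 5, burn_in = 1)),
               "non-finite")
})

test_that("louis_hessian collapses to the complete-data Hessian for a
           degenerate (point-mass posterior) model", {
  # y ~ N(beta, 1) written with a 'latent' variable that is a copy of y:
  # the posterior is a point mass, so the Louis estimate equals the
  # complete-data Hessian of the log-likelihood exactly
  y <- c(0.3, -0.2, 1.1)
  mod <- usp_model(
    sample_latent = function(y, beta, xi, t) y,
    grad = function(y, xi, beta) length(y) * beta - sum(y),
    diag_hess = function(y, xi, beta) length(y),
    prox = function(bt, w, g) bt, n_params = 1L,
    loglik_grad_full = function(y, xi, beta) sum(y) - length(y) * beta,
    loglik_hess_full = function(y, xi, beta) matrix(-length(y), 1, 1))
  H <- louis_hessian(mod, y, 0.5, n_draws = 10)
  expect_equal(H, matrix(-3, 1, 1))
  expect_error(louis_hessian(mod, y, 0.5, n_draws = 1), "at least 2")
})

test_that("a single proximal step degenerates correctly", {
  st <- scaling_state(3, c1 = 1, c2 = 1)
  st$d_avg <- rep(1, 3)
  beta <- c(1, -2, 0.5); g <- c(0.2, 0.1, -0.4)
  # no constraint/penalty: a plain scaled gradient step
  expect_identical(proximal_step(beta, g, st, 0.3),
                   beta - 0.3 * g / st$d_avg)
  # zero gradient at a feasible point is a fixed point of the projection
  pr <- function(bt, w, gam) prox_sphere_row(bt, w)
  b0 <- c(0.6, 0.8, 0)
  out <- proximal_step(b0, c(0, 0, 0), st, 0.3, pr)
  expect_equal(out, b0, tolerance = 1e-10)
  expect_error(proximal_step(beta, c(NaN, 0, 0), st, 0.1), "non-finite")
})
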