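#' Step-size schedule
#'
#' Constructs the step-size schedule \eqn{\gamma_t}.  The default mode is the
#' slowly decaying polynomial schedule \eqn{\gamma_t = \mu t^{-1/2-\epsilon}}
#' required for almost-optimal convergence of the averaged iterate; the
#' harmonic mode \eqn{\gamma_t = \mu / t} is the classical Robbins-Monro
#' choice used by the USP-RM2 comparison variant.
#'
#' @param mu positive multiplier (default 1).
#' @param epsilon decay offset in (0, 1/2]; the default 0.01 gives
#'   \eqn{\gamma_t = t^{-0.51}}.
#' @param mode `"polynomial"` for \eqn{\mu t^{-1/2-\epsilon}} or
#'   `"harmonic"` for \eqn{\mu/t}.
#' @return An object of class `step_schedule`.
#' @export
step_schedule <- function(mu = 1, epsilon = 0.01,
                          mode = c("polynomial", "harmonic")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(mu), length(mu) == 1L, mu > 0)
  if (mode == "polynomial")
    stopifnot(epsilon > 0, epsilon <= 0.5)
  structure(list(mu = mu, epsilon = epsilon, mode = mode),
            class = "step_schedule")
}

#' Evaluate the step size at iteration t
#'
#' @param t iteration number, a positive integer (vectorized).
#' @param schedule a [step_schedule()].
#' @return \eqn{\gamma_t}.
#' @examples
#' step_size(100, step_schedule())        # 100^-0.51
#' step_size(4, step_schedule(mode = "harmonic"))  # 0.25
#' @export
step_size <- function(t, schedule = step_schedule()) {
  if (any(t < 1) || any(t != floor(t))) stop("t must be a positive integer")
  if (schedule$mode == "harmonic") return(schedule$mu / t)
  schedule$mu * t^(-0.5 - schedule$epsilon)
}

#' Truncate values into an interval
#'
#' The truncation map \eqn{T(x; c_1, c_2)} that clamps its argument into
#' \eqn{[c_1, c_2]}; used to keep the diagonal curvature estimates strictly
#' positive and bounded.
#'
#' @param x numeric vector.
#' @param c1,c2 bounds with `c1 <= c2`.
#' @return `x` clamped elementwise.
#' @export
truncate_interval <- function(x, c1, c2) {
  if (c1 > c2) stop("c1 must not exceed c2")
  pmin(pmax(x, c1), c2)
}

#' Initialize the diagonal quasi-Newton scaling state
#'
#' The scaling state tracks the two running averages \eqn{\tilde\delta_1}
#' (of the centered second derivative \eqn{\partial^2 H - (\partial H)^2})
#' and \eqn{\tilde\delta_2} (of the first derivative), whose combination
#' \eqn{\tilde\delta_1 + \tilde\delta_2^2} estimates the diagonal of the
#' Hessian of the smooth marginal objective through the Louis identity, plus
#' the truncated iteration-averaged diagonal actually used in the scaled
#' proximal update.  Both running averages start at zero, so the first
#' update (with \eqn{\gamma_1 = 1}) sets them to the first observations.
#'
#' @param p number of parameters.
#' @param c1,c2 truncation bounds, `0 < c1 <= c2`.
#' @return An object of class `scaling_state`.
#' @export
scaling_state <- function(p, c1 = 1e-2, c2 = 1e4) {
  stopifnot(c1 > 0, c2 >= c1)
  structure(list(delta1 = numeric(p), delta2 = numeric(p),
                 d_avg = numeric(p), c1 = c1, c2 = c2, t = 0L),
            class = "scaling_state")
}

#' One update of the diagonal scaling state
#'
#' @param state a [scaling_state()].
#' @param grad complete-data gradient at the current iterate.
#' @param hess_diag complete-data diagonal second derivatives.
#' @param gamma_t step size in (0, 1].
#' @return The updated state; `state$d_avg` always lies in `[c1, c2]`.
#' @export
update_scaling <- function(state, grad, hess_diag, gamma_t) {
  p <- length(state$delta1)
  if (length(grad) != p || length(hess_diag) != p)
    stop("grad/hess_diag length does not match the scaling state")
  stopifnot(gamma_t > 0, gamma_t <= 1)
  t <- state$t + 1L
  state$delta1 <- (1 - gamma_t) * state$delta1 + gamma_t * (hess_diag - grad^2)
  state$delta2 <- (1 - gamma_t) * state$delta2 + gamma_t * grad
  dtil <- truncate_interval(state$delta1 + state$delta2^2, state$c1, state$c2)
  state$d_avg <- ((t - 1) / t) * state$d_avg + dtil / t
  state$t <- t
  state
}

# update_scaling with the optional [kappa*h, h] clamp of the candidate
# (see usp_control(curv_clamp=)); kappa = 0 reduces to update_scaling()
update_scaling_clamped <- function(state, grad, hess_diag, gamma_t, kappa) {
  if (kappa <= 0) return(update_scaling(state, grad, hess_diag, gamma_t))
  t <- state$t + 1L
  state$delta1 <- (1 - gamma_t) * state$delta1 +
    gamma_t * (hess_diag - grad^2)
  state$delta2 <- (1 - gamma_t) * state$delta2 + gamma_t * grad
  dtil <- state$delta1 + state$delta2^2
  pos <- hess_diag > 0
  dtil[pos] <- pmin(pmax(dtil[pos], kappa * hess_diag[pos]), hess_diag[pos])
  dtil <- truncate_interval(dtil, state$c1, state$c2)
  state$d_avg <- ((t - 1) / t) * state$d_avg + dtil / t
  state$t <- t
  state
}

#' One scaled proximal update
#'
#' Computes \eqn{\tilde\beta = \beta - \gamma_t D^{-1} G} under the
#' diagonal metric and applies the scaled proximal operator of the
#' non-smooth part.  With no constraint or penalty (`prox = NULL`) the
#' operator is the identity and the update is a plain scaled stochastic
#' gradient step.
#'
#' @param beta current parameter vector.
#' @param grad complete-data (stochastic) gradient at `beta`.
#' @param scaling a [scaling_state()] whose `d_avg` supplies the strictly
#'   positive diagonal.
#' @param gamma_t step size.
#' @param prox `function(beta_tilde, weights, gamma)` realizing the scaled
#'   proximal operator, or `NULL` for the identity.
#' @return The updated parameter vector.
#' @export
proximal_step <- function(beta, grad, scaling, gamma_t, prox = NULL) {
  if (any(!is.finite(grad))) stop("non-finite gradient")
  if (any(scaling$d_avg <= 0)) stop("scaling diagonal must be positive")
  beta_tilde <- beta - gamma_t * grad / scaling$d_avg
  if (is.null(prox)) beta_tilde
  else prox(beta_tilde, scaling$d_avg, gamma_t)
}

#' Polyak-Ruppert average of an iterate history
#'
#' @param history matrix with one iterate per row (or a numeric vector for a
#'   scalar parameter).
#' @param burn_in number of leading iterates to discard.
#' @return The arithmetic mean of rows `burn_in + 1, ..., n`.
#' @export
polyak_ruppert_average <- function(history, burn_in = 0L) {
  if (is.vector(history)) history <- matrix(history, ncol = 1L)
  n <- nrow(history)
  if (n <= burn_in) stop("history length must exceed burn_in")
  out <- unname(colMeans(history[(burn_in + 1L):n, , drop = FALSE]))
  if (ncol(history) == 1L) out <- out[1L]
  out
}

#' Window-based stopping check on successive iterate differences
#'
#' Returns `TRUE` when all of the last `window` successive differences (in
#' max-norm) of the supplied iterates fall below `threshold`.  Returns
#' `FALSE` when fewer than `window + 1` iterates are available.
#'
#' @param recent_betas matrix of iterates, one per row (most recent last).
#' @param window number of successive differences monitored (default 3).
#' @param threshold positive stopping threshold.
#' @export
stopping_check <- function(recent_betas, window = 3L, threshold = 1e-3) {
  stopifnot(window >= 1L, threshold > 0)
  if (is.vector(recent_betas)) recent_betas <- matrix(recent_betas, ncol = 1L)
  n <- nrow(recent_betas)
  if (n < window + 1L) return(FALSE)
  for (s in seq_len(window)) {
    d <- max(abs(recent_betas[n - s + 1L, ] - recent_betas[n - s, ]))
    if (d >= threshold) return(FALSE)
  }
  TRUE
}

#' Recursive by-product averaging
#'
#' Applies the stochastic-approximation smoothing
#' \eqn{M^{(t)} = M^{(t-1)} + \gamma_t (m_t - M^{(t-1)})} (with
#' \eqn{M^{(1)} = m_1}) to a stream of conditional-expectation integrands and
#' returns the Polyak-Ruppert average of the smoothed sequence.  This is the
#' device by which posterior expectations (for instance the observed
#' information matrix) are obtained as a by-product of the main iteration.
#'
#' @param m_values list of numeric arrays of a common shape, or a matrix
#'   with one value per row.
#' @param schedule a [step_schedule()] supplying \eqn{\gamma_t}.
#' @param burn_in number of leading smoothed values excluded from the
#'   average.
#' @return The averaged array, with the shape of the stream elements.
#' @export
byproduct_average <- function(m_values, schedule = step_schedule(),
                              burn_in = 0L) {
  if (is.matrix(m_values))
    m_values <- lapply(seq_len(nrow(m_values)), function(i) m_values[i, ])
  n <- length(m_values)
  if (n == 0L) stop("empty by-product stream")
  if (n <= burn_in) stop("stream length must exceed burn_in")
  shp <- dim(m_values[[1L]])
  len <- length(m_values[[1L]])
  M <- as.numeric(m_values[[1L]])
  acc <- numeric(len)
  nacc <- 0L
  if (burn_in < 1L) { acc <- acc + M; nacc <- 1L }
  if (n > 1L) for (t in 2L:n) {
    mt <- m_values[[t]]
    if (length(mt) != len) stop("by-product shape changed mid-stream")
    M <- M + step_size(t, schedule) * (as.numeric(mt) - M)
    if (t > burn_in) { acc <- acc + M; nacc <- nacc + 1L }
  }
  out <- acc / nacc
  if (!is.null(shp)) dim(out) <- shp
  out
}

#' Run configuration for the stochastic proximal engine
#'
#' @param max_iter maximum number of iterations `n`.
#' @param burn_in burn-in size excluded from the trajectory average
#'   (must be `< max_iter`).
#' @param mu,epsilon step-size constants, \eqn{\gamma_t = \mu t^{-1/2-\epsilon}}.
#' @param c1,c2 truncation bounds for the diagonal curvature estimate.
#'   The default `c1 = NULL` selects the lower bound automatically as one
#'   quarter of the median positive complete-data diagonal curvature at the
#'   first iteration, which adapts the bound to the problem's scale; a
#'   numeric value fixes it.
#' @param stop_threshold window stopping threshold; `0` disables adaptive
#'   stopping so that exactly `max_iter` iterations run.
#' @param stop_window window size for the stopping rule.
#' @param variant one of `"USP"`, `"USP-PPG"`, `"USP-RM1"`, `"USP-RM2"`,
#'   `"StEM"`.  `USP-PPG` forces `c2 = c1` (no second-order information,
#'   perturbed proximal gradient); `USP-RM1` returns the last iterate
#'   instead of the average; `USP-RM2` additionally uses \eqn{\gamma_t =
#'   \mu/t}; `StEM` replaces the proximal step by full maximization of the
#'   complete-data objective.
#' @param keep_history keep the full (thinned) iterate history.
#' @param thin thinning interval for the stored history.
#' @param stem_tol,stem_max_inner convergence tolerance and iteration cap of
#'   the StEM inner maximization.
#' @param gibbs_sweeps MCMC sweeps per stochastic step (model back-ends
#'   that sample exactly ignore this).
#' @param verbose emit a per-iteration debug line (iteration, step size,
#'   max parameter change, range of the scaling diagonal); the compiled
#'   fits record the same diagnostics in the returned trace instead.
#' @param curv_clamp optional scale-free stabilizer for the curvature
#'   estimate: when positive, the per-iteration Louis candidate
#'   \eqn{\tilde\delta} is clamped into
#'   \eqn{[\kappa h_i, h_i]} (with \eqn{h_i} the current complete-data
#'   diagonal second derivative, applied only where \eqn{h_i > 0}) before
#'   the \eqn{[c_1, c_2]} truncation.  The marginal information always
#'   lies in \eqn{[0, h_i]}, so the clamp removes transient negative
#'   excursions of the noisy estimate without changing its limit.  `0`
#'   disables the clamp.
#' @return An object of class `usp_control`.
#' @export
usp_control <- function(max_iter = 1000L, burn_in = 50L, mu = 1,
                        epsilon = 0.01, c1 = NULL, c2 = 1e4,
                        stop_threshold = 1e-3, stop_window = 3L,
                        variant = c("USP", "USP-PPG", "USP-RM1", "USP-RM2",
                                    "StEM"),
                        keep_history = FALSE, thin = 1L,
                        stem_tol = 1e-6, stem_max_inner = 500L,
                        gibbs_sweeps = 1L, curv_clamp = 0,
                        verbose = FALSE) {
  variant <- match.arg(variant)
  stopifnot(max_iter >= 1L, burn_in >= 0L, burn_in < max_iter,
            stop_threshold >= 0, stop_window >= 1L,
            thin >= 1L, gibbs_sweeps >= 1L)
  if (!is.null(c1)) stopifnot(c1 > 0, c2 >= c1)
  if (variant == "USP-PPG") {
    if (is.null(c1)) c1 <- 1
    c2 <- c1
  }
  structure(list(max_iter = as.integer(max_iter),
                 burn_in = as.integer(burn_in), mu = mu, epsilon = epsilon,
                 c1 = c1, c2 = c2, stop_threshold = stop_threshold,
                 stop_window = as.integer(stop_window), variant = variant,
                 keep_history = keep_history, thin = as.integer(thin),
                 stem_tol = stem_tol,
                 stem_max_inner = as.integer(stem_max_inner),
                 gibbs_sweeps = as.integer(gibbs_sweeps),
                 curv_clamp = curv_clamp, verbose = isTRUE(verbose)),
            class = "usp_control")
}

auto_c1 <- function(c1, hess_diag) {
  if (!is.null(c1)) return(c1)
  hp <- hess_diag[hess_diag > 0]
  if (length(hp) == 0L) return(1e-2)
  0.25 * median(hp)
}

variant_code <- function(variant) {
  match(variant, c("USP", "USP-PPG", "USP-RM1", "USP-RM2", "StEM")) - 1L
}

#' Model interface for the generic engine
#'
#' Bundles the operations the model-agnostic engine [usp_run()] requires: a
#' latent-variable sampler targeting the posterior at the current
#' parameters, the complete-data gradient and diagonal second derivatives
#' of \eqn{H(\xi, \beta) = -\log f(y, \xi | \beta) + R_1(\beta)}, and the
#' scaled proximal operator realizing the non-smooth part
#' \eqn{g = R_2 + I_B}.
#'
#' @param sample_latent `function(y, beta, xi, t)` returning a new latent
#'   draw (may be `NULL` for models without latent variables).
#' @param grad `function(y, xi, beta)` returning the length-`p` gradient.
#' @param diag_hess `function(y, xi, beta)` returning the length-`p`
#'   diagonal second derivatives.
#' @param prox `function(beta_tilde, weights, gamma)` returning the scaled
#'   proximal update; the identity for unconstrained, unpenalized models.
#' @param n_params parameter count `p`.
#' @param objective optional `function(y, xi, beta)` returning
#'   \eqn{H(\xi,\beta)}.
#' @param full_maximize optional `function(y, xi, beta)` solving the
#'   complete-data problem exactly (used by the StEM variant when present).
#' @param byproduct optional `function(y, xi, beta)` returning an array to
#'   be accumulated by the by-product averaging machinery.
#' @param loglik_grad_full,loglik_hess_full optional complete-data score and
#'   Hessian of `log f(y, xi | beta)` used by [louis_hessian()]; when the
#'   Hessian is absent it is obtained by central differences of the score.
#' @param blocks optional named list of index vectors labelling parameter
#'   blocks.
#' @return An object of class `usp_model`.
#' @export
usp_model <- function(sample_latent, grad, diag_hess, prox, n_params,
                      objective = NULL, full_maximize = NULL,
                      byproduct = NULL, loglik_grad_full = NULL,
                      loglik_hess_full = NULL, blocks = NULL) {
  stopifnot(is.function(sample_latent), is.function(grad),
            is.function(diag_hess), is.function(prox), n_params >= 1L)
  structure(list(sample_latent = sample_latent, grad = grad,
                 diag_hess = diag_hess, prox = prox,
                 n_params = as.integer(n_params), objective = objective,
                 full_maximize = full_maximize, byproduct = byproduct,
                 loglik_grad_full = loglik_grad_full,
                 loglik_hess_full = loglik_hess_full, blocks = blocks),
            class = "usp_model")
}

#' Run the stochastic proximal algorithm on a generic model
#'
#' The reference (pure R) implementation of the engine: alternates the
#' model's stochastic step with the scaled proximal update, maintains the
#' truncated diagonal curvature average, applies the window stopping rule,
#' and returns the Polyak-Ruppert average of the post-burn-in iterates
#' (or the last iterate for the non-averaging variants).
#'
#' @param model a [usp_model()].
#' @param y observed data, passed through to the model callbacks.
#' @param beta0 feasible starting parameter vector.
#' @param control a [usp_control()].
#' @return An object of class `usp_trace` with elements `average` (the
#'   returned estimate), `last`, `history` (if kept), `diffs`, `n_iter`,
#'   `stopped`, `scaling`, and `byproduct_avg`.
#' @export
usp_run <- function(model, y, beta0, control = usp_control()) {
  stopifnot(inherits(model, "usp_model"), inherits(control, "usp_control"))
  p <- model$n_params
  if (length(beta0) != p) stop("beta0 length must equal model$n_params")
  variant <- control$variant
  averaging <- variant %in% c("USP", "USP-PPG", "StEM")
  sched <- step_schedule(control$mu, control$epsilon,
                         if (variant == "USP-RM2") "harmonic" else "polynomial")
  state <- NULL   # created on first use (the c1 = NULL rule needs curvature)
  beta <- as.numeric(beta0)
  xi <- NULL
  avg <- numeric(p); avg_prev <- numeric(p); navg <- 0L
  Mbp <- NULL; bp_acc <- NULL; bp_n <- 0L
  diffs <- numeric(0)
  hist <- if (control$keep_history) vector("list", 0L) else NULL
  n_iter <- control$max_iter; stopped <- FALSE

  for (t in seq_len(control$max_iter)) {
    xi <- model$sample_latent(y, beta, xi, t)
    beta_old <- beta
    gam <- step_size(t, sched)
    if (variant != "StEM") {
      g <- model$grad(y, xi, beta)
      h <- model$diag_hess(y, xi, beta)
      if (any(!is.finite(g)))
        stop(sprintf("non-finite gradient at iteration %d", t))
      if (is.null(state))
        state <- scaling_state(p, auto_c1(control$c1, h), control$c2)
      state <- update_scaling_clamped(state, g, h, min(gam, 1),
                                      control$curv_clamp)
      beta <- proximal_step(beta, g, state, gam, model$prox)
    } else if (!is.null(model$full_maximize)) {
      beta <- model$full_maximize(y, xi, beta)
    } else {
      damp <- 1
      for (it in seq_len(control$stem_max_inner)) {
        g <- model$grad(y, xi, beta)
        h <- model$diag_hess(y, xi, beta)
        if (is.null(state))
          state <- scaling_state(p, auto_c1(control$c1, h), control$c2)
        Din <- truncate_interval(h, state$c1, state$c2)
        bnew <- model$prox(beta - damp * g / Din, Din, damp)
        dd <- max(abs(bnew - beta)); beta <- bnew
        if (dd < control$stem_tol) break
      }
    }
    if (any(!is.finite(beta)))
      stop(sprintf("non-finite parameter update at iteration %d", t))

    if (!is.null(model$byproduct)) {
      m <- as.numeric(model$byproduct(y, xi, beta))
      if (is.null(Mbp)) { Mbp <- m; bp_acc <- numeric(length(m)) }
      else Mbp <- Mbp + gam * (m - Mbp)
      if (t > control$burn_in) { bp_acc <- bp_acc + Mbp; bp_n <- bp_n + 1L }
    }

    diff_t <- max(abs(beta - beta_old))
    if (averaging && t > control$burn_in) {
      navg <- navg + 1L
      avg_prev <- avg
      avg <- avg + (beta - avg) / navg
      # the estimator is the trajectory average: monitor its movement
      if (navg > 1L) diff_t <- max(abs(avg - avg_prev))
    }
    diffs <- c(diffs, diff_t)
    if (control$verbose)
      message(sprintf("t=%d gamma=%.4g max|dbeta|=%.4g d_avg=[%.3g, %.3g]",
                      t, gam, diff_t,
                      if (is.null(state)) NA else min(state$d_avg),
                      if (is.null(state)) NA else max(state$d_avg)))
    if (control$keep_history && t %% control$thin == 0L)
      hist[[length(hist) + 1L]] <- beta
    if (control$stop_threshold > 0 &&
        t >= control$burn_in + control$stop_window &&
        length(diffs) >= control$stop_window &&
        all(diffs[(length(diffs) - control$stop_window + 1L):length(diffs)] <
            control$stop_threshold)) {
      n_iter <- t; stopped <- TRUE; break
    }
  }

  structure(list(
    average = if (averaging && navg > 0L) avg else beta,
    last = beta,
    history = if (!is.null(hist)) do.call(rbind, hist) else NULL,
    diffs = diffs, n_iter = n_iter, stopped = stopped, scaling = state,
    byproduct_avg = if (bp_n > 0L) bp_acc / bp_n else NULL,
    xi = xi, control = control), class = "usp_trace")
}

#' @export
print.usp_trace <- function(x, ...) {
  cat(sprintf("usp_trace: %s, %d iterations (%s), p = %d\n",
              x$control$variant, x$n_iter,
              if (x$stopped) "stopped adaptively" else "iteration cap",
              length(x$average)))
  invisible(x)
}

#' Louis-formula estimate of the marginal log-likelihood Hessian
#'
#' Approximates \eqn{\partial^2 l / \partial\beta\partial\beta^\top} at a
#' fixed parameter value by Monte Carlo, using the identity
#' \deqn{E[\partial^2 \log f + (\partial \log f)(\partial \log f)^\top | y]
#'   - E[\partial \log f | y] E[\partial \log f | y]^\top}
#' with the conditional expectations estimated by the by-product averaging
#' recursion over a stream of posterior draws of the latent variables.
#'
#' @param model a [usp_model()] supplying `loglik_grad_full` (and optionally
#'   `loglik_hess_full`; otherwise the complete-data Hessian is obtained by
#'   central differences of the score).
#' @param y observed data.
#' @param beta parameter value at which the Hessian is evaluated.
#' @param n_draws number of posterior draws (at least 2).
#' @param burn_in draws discarded from the front of the averaging.
#' @param schedule smoothing schedule for the by-product recursion; at a
#'   fixed parameter value the harmonic default makes the recursion an
#'   exact running mean, whose Monte Carlo error decays at the plain
#'   square-root rate.
#' @param fd_step relative step for the finite-difference Hessian fallback.
#' @return A symmetric p x p matrix.
#' @export
louis_hessian <- function(model, y, beta, n_draws = 500L,
                          burn_in = min(50L, n_draws %/% 5L),
                          schedule = step_schedule(mode = "harmonic"),
                          fd_step = 1e-5) {
  if (n_draws < 2L) stop("at least 2 posterior draws are required")
  if (is.null(model$loglik_grad_full))
    stop("model must provide loglik_grad_full")
  p <- length(beta)
  hess_fun <- model$loglik_hess_full
  if (is.null(hess_fun)) {
    hess_fun <- function(y, xi, beta) {
      H <- matrix(0, p, p)
      for (i in seq_len(p)) {
        hstep <- fd_step * (1 + abs(beta[i]))
        bp <- beta; bp[i] <- bp[i] + hstep
        bm <- beta; bm[i] <- bm[i] - hstep
        H[, i] <- (model$loglik_grad_full(y, xi, bp) -
                   model$loglik_grad_full(y, xi, bm)) / (2 * hstep)
      }
      (H + t(H)) / 2
    }
  }
  xi <- NULL
  m1 <- vector("list", n_draws)   # hess + score score'
  m2 <- vector("list", n_draws)   # score
  for (t in seq_len(n_draws)) {
    xi <- model$sample_latent(y, beta, xi, t)
    s <- model$loglik_grad_full(y, xi, beta)
    m1[[t]] <- hess_fun(y, xi, beta) + tcrossprod(s)
    m2[[t]] <- s
  }
  E1 <- byproduct_average(m1, schedule, burn_in)
  E2 <- byproduct_average(m2, schedule, burn_in)
  H <- matrix(E1, p, p) - tcrossprod(E2)
  (H + t(H)) / 2
}
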