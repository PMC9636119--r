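#' Attribute profile enumeration
#'
#' Profiles \eqn{\alpha \in \{0,1\}^K} are enumerated with attribute 1 as
#' the least significant bit: column index \eqn{m} (1-based) corresponds to
#' the profile with code \eqn{m - 1 = \sum_k \alpha_k 2^{k-1}}, so index 1
#' is always the all-zero profile.
#'
#' @param K number of attributes.
#' @return A `2^K x K` binary matrix with one profile per row.
#' @export
profile_matrix <- function(K) {
  M <- 2^K
  out <- matrix(0L, M, K)
  for (k in seq_len(K)) out[, k] <- bitwAnd(0:(M - 1), bitwShiftL(1L, k - 1L)) > 0
  storage.mode(out) <- "integer"
  out
}

#' @rdname profile_matrix
#' @param alpha binary profile vector (or matrix with one profile per row).
#' @return `profile_index`: the 1-based column index of the profile.
#' @export
profile_index <- function(alpha) {
  if (is.matrix(alpha)) return(as.integer(alpha %*% 2^(seq_len(ncol(alpha)) - 1) + 1))
  as.integer(sum(alpha * 2^(seq_along(alpha) - 1)) + 1L)
}

#' @rdname profile_matrix
#' @return `profile_labels`: bitstring labels, attribute 1 first.
#' @export
profile_labels <- function(K) {
  apply(profile_matrix(K), 1, paste, collapse = "")
}

#' Monotone constraint set from a Q-matrix
#'
#' For each item, partitions the \eqn{2^K} attribute profiles into the
#' capable class \eqn{\{\alpha \succeq q_j\}} (profiles mastering every
#' required attribute) and the rest, and emits the equality and inequality
#' rows of the per-item projection QP: all capable values equal, the
#' capable value no smaller than any other value, and every value no
#' smaller than the all-zero profile's value.
#'
#' @param Q J x K binary design matrix.
#' @return An object of class `rlca_constraints`: a list with one element
#'   per item, each containing `capable`, `incapable` (1-based profile
#'   indices), `Aeq` and `Ain` (constraint rows over the \eqn{2^K}
#'   item parameters).
#' @export
rlca_constraints <- function(Q) {
  Q <- as.matrix(Q)
  J <- nrow(Q); K <- ncol(Q); M <- 2^K
  prof <- profile_matrix(K)
  out <- vector("list", J)
  for (j in seq_len(J)) {
    cap <- which(apply(prof, 1, function(a) all(a >= Q[j, ])))
    inc <- setdiff(seq_len(M), cap)
    nAeq <- length(cap) - 1L
    Aeq <- matrix(0, nAeq, M)
    if (nAeq > 0) for (s in seq_len(nAeq)) {
      Aeq[s, cap[1]] <- 1; Aeq[s, cap[s + 1L]] <- -1
    }
    rows <- list()
    for (a in inc) {
      r <- numeric(M); r[cap[1]] <- 1; r[a] <- -1   # capable >= theta_a
      rows[[length(rows) + 1L]] <- r
      if (a != 1L) {                                # theta_a >= theta_0
        r <- numeric(M); r[a] <- 1; r[1L] <- -1
        rows[[length(rows) + 1L]] <- r
      }
    }
    Ain <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0L, M)
    out[[j]] <- list(capable = cap, incapable = inc, Aeq = Aeq, Ain = Ain)
  }
  structure(out, class = "rlca_constraints", Q = Q, K = K)
}

#' Check feasibility of an RLCA parameter matrix
#'
#' @param theta J x 2^K matrix of class-specific logits.
#' @param constraints an [rlca_constraints()] object.
#' @param tol feasibility tolerance.
#' @return `TRUE` if every equality/inequality holds within `tol`.
#' @export
rlca_feasible <- function(theta, constraints, tol = 1e-8) {
  for (j in seq_along(constraints)) {
    cs <- constraints[[j]]
    v <- theta[j, ]
    if (nrow(cs$Aeq) && max(abs(cs$Aeq %*% v)) > tol) return(FALSE)
    if (nrow(cs$Ain) && min(cs$Ain %*% v) < -tol) return(FALSE)
  }
  TRUE
}

#' Exact posterior over attribute profiles
#'
#' The posterior of a person's profile is categorical with probabilities
#' proportional to \eqn{\exp(\nu_\alpha) \prod_j
#' \exp(y_{ij}\theta_{j\alpha}) / (1 + \exp(\theta_{j\alpha}))}, computed in
#' log space and normalized.
#'
#' @param y_i binary response vector of length J (or an N x J matrix for
#'   all persons at once).
#' @param theta J x 2^K logit matrix.
#' @param nu structural log-odds over all 2^K profiles (first entry, the
#'   all-zero profile, is the baseline and is forced to 0).
#' @return A probability vector over profiles (or an N x 2^K matrix).
#' @export
rlca_profile_posterior <- function(y_i, theta, nu) {
  nu <- as.numeric(nu); nu[1] <- 0
  single <- !is.matrix(y_i)
  Ym <- if (single) matrix(y_i, 1) else y_i
  colK <- colSums(log1pexp(theta))
  lp <- sweep(Ym %*% theta, 2, nu - colK, "+")
  mx <- apply(lp, 1, max)
  W <- exp(lp - mx)
  W <- W / rowSums(W)
  if (single) as.numeric(W) else W
}

#' Exact sampling of attribute profiles from the posterior
#'
#' Independent categorical draws per person by inverse-CDF over the exact
#' posterior [rlca_profile_posterior()].
#'
#' @param Y N x J binary response matrix.
#' @inheritParams rlca_profile_posterior
#' @return Integer vector of 1-based profile column indices (profile code
#'   = index - 1).
#' @export
rlca_sample_xi <- function(Y, theta, nu) {
  W <- rlca_profile_posterior(Y, theta, nu)
  if (!is.matrix(W)) W <- matrix(W, 1)
  N <- nrow(W)
  z <- integer(N)
  for (i in seq_len(N)) {
    u <- runif(1) * sum(W[i, ])
    acc <- 0
    zi <- ncol(W)
    for (a in seq_len(ncol(W))) {
      acc <- acc + W[i, a]
      if (u <= acc) { zi <- a; break }
    }
    z[i] <- zi
  }
  z
}

#' Complete-data gradient and diagonal Hessian for the RLCA model
#'
#' Derivatives of the complete-data negative log-likelihood with respect to
#' the packed parameter vector (theta column-major, then the free
#' structural log-odds \eqn{\nu_\alpha, \alpha \ne 0}).  For
#' \eqn{\theta_{j\alpha}}: \eqn{n_\alpha p_{j\alpha} - s_{j\alpha}} with
#' diagonal Hessian \eqn{n_\alpha p(1-p)}; for \eqn{\nu_\alpha}:
#' \eqn{N\pi_\alpha - n_\alpha} with diagonal Hessian
#' \eqn{N\pi_\alpha(1-\pi_\alpha)}.
#'
#' @param z integer vector of sampled profile indices (1-based).
#' @inheritParams rlca_profile_posterior
#' @param Y N x J binary responses.
#' @return List with `grad`, `hess`, and `blocks`.
#' @export
rlca_grad_diag_hess <- function(z, theta, nu, Y) {
  J <- nrow(theta); M <- ncol(theta); N <- nrow(Y)
  nu <- as.numeric(nu); nu[1] <- 0
  nalpha <- tabulate(z, nbins = M)
  S <- matrix(0, J, M)
  for (a in which(nalpha > 0))
    S[, a] <- colSums(Y[z == a, , drop = FALSE])
  P <- 1 / (1 + exp(-theta))
  Gt <- sweep(P, 2, nalpha, "*") - S
  Ht <- sweep(P * (1 - P), 2, nalpha, "*")
  pi <- exp(nu - max(nu)); pi <- pi / sum(pi)
  Gn <- N * pi[-1] - nalpha[-1]
  Hn <- N * pi[-1] * (1 - pi[-1])
  list(grad = c(as.numeric(Gt), Gn), hess = c(as.numeric(Ht), Hn),
       blocks = list(theta = seq_len(J * M), nu = J * M + seq_len(M - 1)))
}

#' Marginal log-likelihood of the restricted latent class model
#'
#' Direct evaluation by summation over all \eqn{2^K} profiles.
#'
#' @inheritParams rlca_grad_diag_hess
#' @export
rlca_marginal_loglik <- function(theta, nu, Y) {
  nu <- as.numeric(nu); nu[1] <- 0
  colK <- colSums(log1pexp(theta))
  lpi <- nu - max(nu) - log(sum(exp(nu - max(nu))))
  lp <- sweep(Y %*% theta, 2, lpi - colK, "+")
  mx <- apply(lp, 1, max)
  sum(mx + log(rowSums(exp(lp - mx))))
}

#' DINA item parameters
#'
#' Fills the J x 2^K logit matrix of the Deterministic Input Noisy And
#' model: \eqn{\theta_{j\alpha} = \log((1-s_j)/s_j)} for capable profiles
#' (\eqn{\alpha \succeq q_j}) and \eqn{\log(g_j/(1-g_j))} otherwise, from
#' slipping and guessing probabilities `s`, `g`.
#'
#' @param s,g vectors of slipping and guessing probabilities in (0, 1).
#' @param Q J x K binary design matrix.
#' @return The J x 2^K theta matrix; feasible for [rlca_constraints()]
#'   whenever `s + g < 1`.
#' @export
dina_theta <- function(s, g, Q) {
  if (length(s) != nrow(Q) || length(g) != nrow(Q))
    stop("s and g must have one entry per item")
  if (any(s <= 0 | s >= 1 | g <= 0 | g >= 1))
    stop("s and g must lie in (0, 1)")
  J <- nrow(Q); K <- ncol(Q); M <- 2^K
  prof <- profile_matrix(K)
  theta <- matrix(0, J, M)
  for (j in seq_len(J)) {
    cap <- apply(prof, 1, function(a) all(a >= Q[j, ]))
    theta[j, ] <- ifelse(cap, log((1 - s[j]) / s[j]), log(g[j] / (1 - g[j])))
  }
  theta
}

#' Fit a restricted latent class model by the stochastic proximal algorithm
#'
#' Exact posterior sampling of the attribute profiles alternates with a
#' scaled proximal update in which each item's \eqn{2^K} logits are
#' projected onto the monotonicity polyhedron by an active-set QP; the
#' structural log-odds \eqn{\nu} are unconstrained apart from the pinned
#' baseline \eqn{\nu_0 = 0}.
#'
#' @param Y N x J binary response matrix.
#' @param Q J x K binary design matrix.
#' @param control a [usp_control()].
#' @param start optional list with `theta` (J x 2^K) and `nu` (length 2^K,
#'   first entry 0); the default is +1 on capable profiles, -1 elsewhere,
#'   and `nu = 0`.
#' @param seed optional integer seed.
#' @return An object of class `rlca_fit` with averaged `theta`, `nu`
#'   (length 2^K including the baseline 0), last iterates, and trace
#'   diagnostics.
#' @export
fit_rlca <- function(Y, Q, control = usp_control(), start = NULL,
                     seed = NULL) {
  Y <- as.matrix(Y)
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  Q <- as.matrix(Q)
  J <- ncol(Y); K <- ncol(Q); M <- 2^K
  if (nrow(Q) != J) stop("Q must have one row per item")
  if (K > 8) stop("K > 8 is unsupported")
  cons <- rlca_constraints(Q)
  if (is.null(start)) {
    theta0 <- matrix(-1, J, M)
    for (j in seq_len(J)) theta0[j, cons[[j]]$capable] <- 1
    start <- list(theta = theta0, nu = numeric(M))
  }
  if (!is.null(seed)) set.seed(seed)
  res <- .rlca_usp(Y, start$theta, as.numeric(start$nu[-1]),
                   lapply(cons, `[[`, "Aeq"), lapply(cons, `[[`, "Ain"),
                   variant_code(control$variant), control$max_iter,
                   control$burn_in, control$mu, control$epsilon,
                   if (is.null(control$c1)) -1 else control$c1,
                   control$c2, control$stop_threshold,
                   control$stop_window, control$keep_history, control$thin,
                   control$stem_tol, control$stem_max_inner,
                   control$curv_clamp)
  structure(list(theta = res$theta, nu = c(0, as.numeric(res$nu)),
                 last = list(theta = res$last_theta,
                             nu = c(0, as.numeric(res$last_nu))),
                 d_avg = as.numeric(res$d_avg),
                 n_iter = res$n_iter, stopped = res$stopped,
                 diffs = as.numeric(res$diffs), history = res$history,
                 z = as.integer(res$z) + 1L,
                 constraints = cons, Q = Q,
                 control = control), class = "rlca_fit")
}

#' @export
print.rlca_fit <- function(x, ...) {
  K <- ncol(x$Q)
  cat(sprintf("rlca_fit (%s): J = %d items, K = %d attributes (%d profiles), %d iterations%s\n",
              x$control$variant, nrow(x$theta), K, 2^K, x$n_iter,
              if (x$stopped) " (stopped adaptively)" else ""))
  cat(sprintf("  feasible: %s\n", rlca_feasible(x$theta, x$constraints)))
  invisible(x)
}

#' Assemble a generic-engine model interface for the RLCA model
#'
#' Exposes the restricted latent class back-end through the [usp_model()]
#' contract (packed layout: theta column-major, then free nu).  Sampling,
#' derivatives and the QP projection match the compiled fast path.
#'
#' @inheritParams fit_rlca
#' @return A [usp_model()].
#' @export
rlca_usp_model <- function(Y, Q) {
  Q <- as.matrix(Q)
  J <- ncol(Y); K <- ncol(Q); M <- 2^K
  cons <- rlca_constraints(Q)
  p <- J * M + M - 1L
  unpack <- function(beta) {
    list(theta = matrix(beta[seq_len(J * M)], J, M),
         nu = c(0, beta[J * M + seq_len(M - 1L)]))
  }
  usp_model(
    sample_latent = function(y, beta, xi, t) {
      par <- unpack(beta)
      rlca_sample_xi(y, par$theta, par$nu)
    },
    grad = function(y, xi, beta) {
      par <- unpack(beta)
      rlca_grad_diag_hess(xi, par$theta, par$nu, y)$grad
    },
    diag_hess = function(y, xi, beta) {
      par <- unpack(beta)
      rlca_grad_diag_hess(xi, par$theta, par$nu, y)$hess
    },
    prox = function(beta_tilde, weights, gamma) {
      out <- beta_tilde
      for (j in seq_len(J)) {
        idx <- j + J * (seq_len(M) - 1L)
        out[idx] <- prox_qp_monotone(out[idx], weights[idx], cons[[j]])
      }
      out
    },
    n_params = p,
    objective = function(y, xi, beta) {
      par <- unpack(beta)
      lpi <- par$nu - log(sum(exp(par$nu - max(par$nu)))) - max(par$nu)
      ll <- sum(lpi[xi])
      for (a in unique(xi)) {
        rows <- which(xi == a)
        th <- par$theta[, a]
        ll <- ll + sum(y[rows, , drop = FALSE] %*% th) -
          length(rows) * sum(log1pexp(th))
      }
      -ll
    },
    loglik_grad_full = function(y, xi, beta) {
      par <- unpack(beta)
      -rlca_grad_diag_hess(xi, par$theta, par$nu, y)$grad
    },
    loglik_hess_full = function(y, xi, beta) {
      # complete-data log-likelihood Hessian: diagonal in theta (cells are
      # separate Bernoulli blocks), dense softmax block in nu, no cross terms
      par <- unpack(beta)
      nal <- tabulate(xi, nbins = M)
      P <- 1 / (1 + exp(-par$theta))
      H <- matrix(0, p, p)
      diag(H)[seq_len(J * M)] <- -as.numeric(sweep(P * (1 - P), 2, nal, "*"))
      pi_f <- exp(par$nu - max(par$nu)); pi_f <- pi_f / sum(pi_f)
      Hnu <- -nrow(y) * (diag(pi_f) - tcrossprod(pi_f))
      H[J * M + seq_len(M - 1L), J * M + seq_len(M - 1L)] <- Hnu[-1, -1]
      H
    },
    blocks = list(theta = seq_len(J * M), nu = J * M + seq_len(M - 1L)))
}
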