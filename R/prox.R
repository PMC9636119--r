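#' Soft-thresholding operator
#'
#' Closed-form solution of the scalar lasso proximal subproblem
#' \eqn{\arg\min_x \frac12 (x - \tilde\beta)^2 + \kappa |x|}:
#' shrink toward zero by \eqn{\kappa}, mapping the dead zone
#' \eqn{[-\kappa, \kappa]} to exactly zero.  Under the diagonal metric the
#' threshold for coordinate \eqn{i} is \eqn{\kappa = \lambda\gamma/\delta_i}.
#'
#' @param beta_tilde numeric vector.
#' @param kappa nonnegative threshold (scalar or vector).
#' @return The thresholded vector.
#' @examples
#' soft_threshold(0.5, 0.2)   # 0.3
#' soft_threshold(0.1, 0.2)   # 0
#' @export
soft_threshold <- function(beta_tilde, kappa) {
  if (any(kappa < 0)) stop("kappa must be nonnegative")
  sign(beta_tilde) * pmax(abs(beta_tilde) - kappa, 0)
}

#' Weighted projection of a Cholesky row onto the unit sphere
#'
#' Solves \eqn{\min_b \sum_l \delta_l (b_l - \tilde b_l)^2} subject to
#' \eqn{\|b\| = 1} and the strictly-upper-triangular zero pattern, by the
#' method of Lagrange multipliers: \eqn{b_l = \delta_l \tilde b_l /
#' (\delta_l + \lambda^*)} with \eqn{\lambda^*} the root of
#' \eqn{\|b(\lambda)\| = 1}, located by bisection on
#' \eqn{(-\min_l \delta_l, \infty)}.  When the free part of
#' \eqn{\tilde b} is identically zero the minimizer is not unique; the first
#' free coordinate is deterministically set to 1 and a warning is raised.
#'
#' @param b_tilde target vector (length K).
#' @param weights strictly positive weights (diagonal of the metric).
#' @param free_mask logical vector; `FALSE` entries are structural zeros.
#' @return A vector with exact unit norm and zeros on masked coordinates.
#' @export
prox_sphere_row <- function(b_tilde, weights,
                            free_mask = rep(TRUE, length(b_tilde))) {
  stopifnot(length(weights) == length(b_tilde),
            length(free_mask) == length(b_tilde), all(weights > 0))
  if (!any(free_mask)) stop("at least one coordinate must be free")
  out <- numeric(length(b_tilde))
  res <- .prox_sphere(as.numeric(b_tilde[free_mask]),
                      as.numeric(weights[free_mask]))
  if (res$degenerate)
    warning("degenerate sphere projection target; returning a deterministic unit vector")
  out[free_mask] <- res$b
  out
}

#' Projection onto a polyhedron under a diagonal metric
#'
#' Solves the strictly convex quadratic program
#' \eqn{\min_x (x - t)^\top D (x - t)} subject to `Aeq x = beq` and
#' `Ain x >= bin` by a primal active-set method, starting from a supplied
#' feasible point.
#'
#' @param target the point to project.
#' @param weights strictly positive diagonal of `D`.
#' @param Aeq,beq equality rows (may have zero rows).
#' @param Ain,bin inequality rows (may have zero rows).
#' @param x0 feasible starting point; defaults to the weighted-mean constant
#'   vector, feasible for homogeneous difference constraints.
#' @return The unique minimizer.
#' @export
solve_qp <- function(target, weights, Aeq = NULL, beq = NULL,
                     Ain = NULL, bin = NULL, x0 = NULL) {
  p <- length(target)
  stopifnot(length(weights) == p, all(weights > 0))
  if (is.null(Aeq)) Aeq <- matrix(0, 0L, p)
  if (is.null(Ain)) Ain <- matrix(0, 0L, p)
  if (is.null(beq)) beq <- numeric(nrow(Aeq))
  if (is.null(bin)) bin <- numeric(nrow(Ain))
  if (is.null(x0)) x0 <- rep(sum(weights * target) / sum(weights), p)
  feas <- c(if (nrow(Aeq)) abs(Aeq %*% x0 - beq), if (nrow(Ain)) bin - Ain %*% x0)
  if (length(feas) && max(feas) > 1e-8) stop("x0 is not feasible")
  as.numeric(.qp_active_set(as.numeric(weights), as.numeric(target),
                            Aeq, as.numeric(beq), Ain, as.numeric(bin),
                            as.numeric(x0)))
}

#' Monotone-constraint projection for a restricted latent class item block
#'
#' Projects one item's vector of class-specific logits \eqn{\theta_{j,\cdot}}
#' (or the full `J x 2^K` block stacked per item) onto the feasible set in
#' which all capable profiles (those mastering every required attribute)
#' share a single value that dominates every other profile's value, each of
#' which in turn dominates the all-zero profile's value.  The equalities are
#' encoded as explicit rows of the per-item quadratic program.
#'
#' @param beta_tilde numeric vector of length `2^K` (one item).
#' @param weights strictly positive weights of the same length.
#' @param constraints a single item's element of [rlca_constraints()].
#' @return The projected vector; constraints hold to solver tolerance.
#' @export
prox_qp_monotone <- function(beta_tilde, weights, constraints) {
  stopifnot(length(beta_tilde) == length(weights))
  solve_qp(beta_tilde, weights, Aeq = constraints$Aeq, Ain = constraints$Ain)
}

#' Build a composite scaled proximal operator
#'
#' Dispatches over the non-smooth part \eqn{g = R_2 + I_B} of the
#' objective, returning `function(beta_tilde, weights, gamma)` that applies
#' blockwise: the identity to unconstrained blocks, soft-thresholding to
#' L1-penalized loadings, weighted sphere projection to each Cholesky row,
#' and the monotone QP projection to restricted-LCA item blocks.
#'
#' @param spec one of `"none"`, `"l1"`, `"sphere"`, `"l1_sphere"`,
#'   `"monotone_qp"`.
#' @param blocks named list of index vectors: `penalized` (L1 block),
#'   `sphere_rows` (list of index vectors, one per Cholesky row),
#'   `items` (list of index vectors, one per item) as required by the spec.
#' @param lambda L1 penalty weight (for `"l1"` and `"l1_sphere"`).
#' @param constraints list of per-item constraint sets
#'   (for `"monotone_qp"`).
#' @return A function `(beta_tilde, weights, gamma) -> beta`.
#' @export
make_prox <- function(spec = c("none", "l1", "sphere", "l1_sphere",
                               "monotone_qp"),
                      blocks = list(), lambda = 0, constraints = NULL) {
  spec <- match.arg(spec)
  if (spec == "none") return(function(beta_tilde, weights, gamma) beta_tilde)
  if (spec %in% c("l1", "l1_sphere") && is.null(blocks$penalized))
    stop("blocks$penalized is required for L1 specs")
  if (spec %in% c("sphere", "l1_sphere") && is.null(blocks$sphere_rows))
    stop("blocks$sphere_rows is required for sphere specs")
  if (spec == "monotone_qp" && (is.null(blocks$items) || is.null(constraints)))
    stop("blocks$items and constraints are required for monotone_qp")
  function(beta_tilde, weights, gamma) {
    out <- beta_tilde
    if (spec %in% c("l1", "l1_sphere")) {
      idx <- blocks$penalized
      out[idx] <- soft_threshold(out[idx], lambda * gamma / weights[idx])
    }
    if (spec %in% c("sphere", "l1_sphere")) {
      for (idx in blocks$sphere_rows)
        out[idx] <- prox_sphere_row(out[idx], weights[idx])
    }
    if (spec == "monotone_qp") {
      for (j in seq_along(blocks$items)) {
        idx <- blocks$items[[j]]
        out[idx] <- prox_qp_monotone(out[idx], weights[idx],
                                     constraints[[j]])
      }
    }
    out
  }
}
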