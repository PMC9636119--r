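# ---- simulation designs ----------------------------------------------------

# Sparse loading pattern of the exploratory study: 80 items, 5 factors.
# Items 1-50 are simple-structure (10 per factor); items 51-60 and 61-70 load
# on the 10 unordered factor pairs; items 71-80 on the 10 unordered triples.
study2_pattern <- function() {
  items <- list(
    c(1:10, 51, 52, 54, 57, 61, 62, 64, 67, 71, 72, 73, 75, 76, 78),
    c(11:20, 51, 53, 55, 58, 61, 63, 65, 68, 71, 72, 74, 75, 77, 79),
    c(21:30, 52, 53, 56, 59, 62, 63, 66, 69, 71, 73, 74, 76, 77, 80),
    c(31:40, 54, 55, 56, 60, 64, 65, 66, 70, 72, 73, 74, 78, 79, 80),
    c(41:50, 57, 58, 59, 60, 67, 68, 69, 70, 75, 76, 77, 78, 79, 80))
  Q <- matrix(0L, 80, 5)
  for (k in 1:5) Q[items[[k]], k] <- 1L
  Q
}

# Design matrix of the restricted-LCA study: 20 items, 4 attributes
# (columns of the printed table transposed to rows = items).
study3_qmatrix <- function() {
  q <- rbind(
    c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1),
    c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1),
    c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1),
    c(1, 1, 0, 0), c(1, 0, 1, 0), c(0, 1, 1, 0), c(1, 0, 0, 1),
    c(1, 1, 1, 0), c(1, 1, 0, 1), c(1, 0, 1, 1), c(0, 1, 1, 1))
  storage.mode(q) <- "integer"
  q
}

#' Simulation study designs
#'
#' The three benchmark designs: `"I"` confirmatory IFA (N = 1000, J = 20,
#' K = 2, items 1-5 on factor 1, 6-10 on factor 2, 11-20 on both, factor
#' correlation 0.4); `"II"` exploratory IFA with a sparse 80 x 5 loading
#' pattern and factor correlations 0.4, estimated with an L1 penalty
#' \eqn{\lambda_N = \sqrt{\log J / N}}; `"III"` restricted LCA with 20
#' items, 4 attributes, DINA-generated item parameters with slipping and
#' guessing drawn from U(0.05, 0.2), and uniform profile probabilities.
#'
#' @param study `"I"`, `"II"`, or `"III"`.
#' @param N sample size (default: the design's base size).
#' @param n_reps number of replications.
#' @param seed root seed; replication r uses `seed + 1000 * r`.
#' @return An object of class `study_design`.
#' @export
study_design <- function(study = c("I", "II", "III"), N = NULL,
                         n_reps = 50L, seed = 1L) {
  study <- match.arg(study)
  if (study == "I") {
    Q <- matrix(0L, 20, 2)
    Q[1:5, 1] <- 1L; Q[6:10, 2] <- 1L; Q[11:20, ] <- 1L
    out <- list(study = "I", N = if (is.null(N)) 1000L else N, J = 20L,
                K = 2L, Q = Q, rho = 0.4)
  } else if (study == "II") {
    Q <- study2_pattern()
    NN <- if (is.null(N)) 1000L else N
    out <- list(study = "II", N = NN, J = 80L, K = 5L, Q = Q, rho = 0.4,
                lambda = sqrt(log(80) / NN))
  } else {
    out <- list(study = "III", N = if (is.null(N)) 1000L else N, J = 20L,
                K = 4L, Q = study3_qmatrix(), s_range = c(0.05, 0.2),
                g_range = c(0.05, 0.2))
  }
  out$n_reps <- as.integer(n_reps)
  out$seed <- as.integer(seed)
  structure(out, class = "study_design")
}

#' Generate item factor model parameters for a study design
#'
#' Intercepts i.i.d. standard normal; nonzero loadings i.i.d. uniform on
#' (0.5, 1.5) on the design's support pattern; factor covariance compound
#' symmetric with unit diagonal and off-diagonal `rho`, reparameterized by
#' its lower Cholesky factor.
#'
#' @param design a [study_design()] for study I or II.
#' @return List with `d`, `A`, `B`, `Sigma`, `Q`.
#' @export
generate_ifa_params <- function(design) {
  stopifnot(design$study %in% c("I", "II"))
  J <- design$J; K <- design$K; Q <- design$Q
  d <- rnorm(J)
  A <- matrix(0, J, K)
  nz <- which(Q == 1)
  A[nz] <- runif(length(nz), 0.5, 1.5)
  Sigma <- matrix(design$rho, K, K); diag(Sigma) <- 1
  B <- t(chol(Sigma))
  list(d = d, A = A, B = B, Sigma = Sigma, Q = Q)
}

#' Generate binary responses from an item factor model
#'
#' Draws latent factors \eqn{\xi_i \sim N(0, BB^\top)} and Bernoulli
#' responses under local independence.
#'
#' @param params list with `d`, `A`, `B` (as from [generate_ifa_params()]).
#' @param N number of persons.
#' @return N x J binary matrix.
#' @export
generate_ifa_data <- function(params, N) {
  K <- ncol(params$B)
  Xi <- matrix(rnorm(N * K), N, K) %*% t(params$B)
  P <- 1 / (1 + exp(-sweep(Xi %*% t(params$A), 2, params$d, "+")))
  Y <- matrix(rbinom(length(P), 1L, P), N, ncol(P))
  Y
}

#' Generate restricted-LCA data from the DINA design
#'
#' Slipping and guessing parameters are drawn i.i.d. uniform on the
#' design's range, converted to the class logit matrix by [dina_theta()];
#' attribute profiles are uniform over the \eqn{2^K} classes
#' (\eqn{\nu \equiv 0}) and responses Bernoulli under local independence.
#'
#' @param design a [study_design()] for study III.
#' @param N number of persons (default: the design's).
#' @return List with `Y`, `theta` (truth), `nu` (zeros), `s`, `g`, `z`
#'   (true profile indices), `Q`.
#' @export
generate_rlca_data <- function(design, N = design$N) {
  stopifnot(design$study == "III")
  J <- design$J; K <- design$K; M <- 2^K
  s <- runif(J, design$s_range[1], design$s_range[2])
  g <- runif(J, design$g_range[1], design$g_range[2])
  theta <- dina_theta(s, g, design$Q)
  z <- sample.int(M, N, replace = TRUE)
  P <- t(theta[, z])                     # N x J logits
  P <- 1 / (1 + exp(-P))
  Y <- matrix(rbinom(length(P), 1L, P), N, J)
  list(Y = Y, theta = theta, nu = numeric(M), s = s, g = g, z = z,
       Q = design$Q)
}

# all permutations of 1..K (K! rows)
all_permutations <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(K - 1L)
  out <- matrix(0L, 0, K)
  for (pos in seq_len(K)) {
    block <- t(apply(sub, 1, function(pp) append(pp, K, after = pos - 1L)))
    out <- rbind(out, block)
  }
  out
}

#' Column-swap mean squared error of a loading matrix
#'
#' The estimation error of an exploratory loading matrix, minimized over
#' all column permutations of the estimate to account for factor label
#' indeterminacy: \eqn{\min_{P} \|A_{hat} P - A\|_F^2 / (JK)}.  Computed by
#' exact enumeration over the \eqn{K!} permutations (`K <= 8`).
#'
#' @param A_hat,A_true J x K matrices.
#' @return The minimized normalized squared Frobenius distance.
#' @export
mse_loadings_swap <- function(A_hat, A_true) {
  stopifnot(all(dim(A_hat) == dim(A_true)))
  K <- ncol(A_true)
  if (K > 8) stop("K > 8 is unsupported (factorial enumeration)")
  perms <- all_permutations(K)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    m <- mean((A_hat[, perms[r, ], drop = FALSE] - A_true)^2)
    if (m < best) best <- m
  }
  best
}

#' Mean squared error over a (masked) parameter block
#'
#' @param est,truth numeric arrays of equal shape.
#' @param mask optional logical array restricting the average (for instance
#'   the free loadings of a confirmatory design).
#' @return Mean of squared differences over the (masked) entries.
#' @export
mse_block <- function(est, truth, mask = NULL) {
  stopifnot(length(est) == length(truth))
  d2 <- (as.numeric(est) - as.numeric(truth))^2
  if (!is.null(mask)) {
    m <- as.logical(mask)
    if (!any(m)) stop("empty mask")
    d2 <- d2[m]
  }
  mean(d2)
}
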