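#' Run a simulation study
#'
#' Replicates one of the three benchmark designs: generate (or reuse) true
#' parameters, simulate data, fit with the requested algorithm variants,
#' and score with the study's metrics.  Study I scores each stochastic
#' variant against the Gauss-Hermite quadrature EM solution (the
#' computational target), starting all methods at the generating
#' parameters; studies II and III score against the generating truth.
#'
#' @param design a [study_design()].
#' @param variants character vector of algorithm variants (study I defaults
#'   to all five; II/III to `"USP"`).
#' @param control optional [usp_control()] overriding the study defaults
#'   (study I: fixed 1000 iterations, burn-in 500; II/III: adaptive stop at
#'   threshold 1e-3 with window 3, burn-in 50).
#' @param redraw_truth redraw the true parameters each replication
#'   (studies II/III; study I draws the truth once per study).
#' @param max_iter iteration cap for the adaptive-stop studies.
#' @param n_quad quadrature points per dimension for the study-I EM
#'   reference.
#' @param progress print one line per replication.
#' @return An object of class `study_result`: `per_rep` (one row per
#'   replication x variant x metric) and `summary` (25%, median, 75%
#'   empirical quantiles, linear interpolation) plus the design.
#' @export
run_study <- function(design, variants = NULL, control = NULL,
                      redraw_truth = TRUE, max_iter = NULL, n_quad = 31L,
                      progress = FALSE) {
  stopifnot(inherits(design, "study_design"))
  switch(design$study,
         "I" = run_study1(design, variants, control, n_quad, progress),
         "II" = run_study2(design, variants, control, redraw_truth,
                           max_iter, progress),
         "III" = run_study3(design, variants, control, redraw_truth,
                            max_iter, progress))
}

rep_seed <- function(design, r) design$seed + 1000L * r

study_summarize <- function(per_rep) {
  agg <- do.call(rbind, lapply(
    split(per_rep, list(per_rep$variant, per_rep$metric, per_rep$N),
          drop = TRUE),
    function(df) {
      qs <- quantile(df$mse, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(variant = df$variant[1], metric = df$metric[1],
                 N = df$N[1], q25 = qs[1], median = qs[2], q75 = qs[3],
                 n_reps = nrow(df))
    }))
  rownames(agg) <- NULL
  agg
}

run_study1 <- function(design, variants, control, n_quad, progress) {
  if (is.null(variants))
    variants <- c("USP", "USP-PPG", "USP-RM1", "USP-RM2", "StEM")
  set.seed(design$seed)
  truth <- generate_ifa_params(design)
  rows <- list()
  for (r in seq_len(design$n_reps)) {
    set.seed(rep_seed(design, r))
    Y <- generate_ifa_data(truth, design$N)
    em <- ifa_em(Y, design$Q, n_quad = n_quad, tol = 1e-7,
                 start = truth)
    for (v in variants) {
      ctl <- if (is.null(control))
        usp_control(max_iter = 1000L, burn_in = 500L, stop_threshold = 0,
                    variant = v,
                    c1 = if (v == "USP-PPG") 1 else NULL)
      else { c2 <- control; c2$variant <- v
             if (v == "USP-PPG") { c2$c1 <- 1; c2$c2 <- 1 }; c2 }
      fit <- fit_ifa(Y, Q = design$Q, penalty = "none", control = ctl,
                     start = truth, seed = rep_seed(design, r) + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, variant = v, N = design$N,
        metric = c("d", "a", "sigma12"),
        mse = c(mse_block(fit$d, em$d),
                mse_block(fit$A, em$A, mask = design$Q == 1),
                (fit$Sigma[1, 2] - em$Sigma[1, 2])^2))
    }
    if (progress)
      message(sprintf("study I rep %d/%d done", r, design$n_reps))
  }
  per_rep <- do.call(rbind, rows)
  structure(list(design = design, per_rep = per_rep,
                 summary = study_summarize(per_rep)),
            class = "study_result")
}

run_study2 <- function(design, variants, control, redraw_truth, max_iter,
                       progress) {
  if (is.null(variants)) variants <- "USP"
  if (is.null(max_iter)) max_iter <- 1500L
  set.seed(design$seed)
  truth_fixed <- generate_ifa_params(design)
  rows <- list()
  for (r in seq_len(design$n_reps)) {
    set.seed(rep_seed(design, r))
    truth <- if (redraw_truth) generate_ifa_params(design) else truth_fixed
    Y <- generate_ifa_data(truth, design$N)
    for (v in variants) {
      ctl <- if (is.null(control))
        usp_control(max_iter = max_iter, burn_in = 50L,
                    stop_threshold = 1e-3, variant = v,
                    c1 = if (v == "USP-PPG") 1 else NULL)
      else { c2 <- control; c2$variant <- v; c2 }
      fit <- fit_ifa(Y, K = design$K, penalty = "lasso",
                     lambda = design$lambda, control = ctl,
                     seed = rep_seed(design, r) + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, variant = v, N = design$N, metric = "loading_swap",
        mse = mse_loadings_swap(fit$A, truth$A))
    }
    if (progress)
      message(sprintf("study II rep %d/%d done", r, design$n_reps))
  }
  per_rep <- do.call(rbind, rows)
  structure(list(design = design, per_rep = per_rep,
                 summary = study_summarize(per_rep)),
            class = "study_result")
}

run_study3 <- function(design, variants, control, redraw_truth, max_iter,
                       progress) {
  if (is.null(variants)) variants <- "USP"
  if (is.null(max_iter)) max_iter <- 4000L
  set.seed(design$seed)
  truth_fixed <- generate_rlca_data(design)      # draws s, g (and data, unused)
  rows <- list()
  for (r in seq_len(design$n_reps)) {
    set.seed(rep_seed(design, r))
    dat <- if (redraw_truth) generate_rlca_data(design)
           else { d2 <- truth_fixed
                  z <- sample.int(2^design$K, design$N, replace = TRUE)
                  P <- 1 / (1 + exp(-t(d2$theta[, z])))
                  d2$Y <- matrix(rbinom(length(P), 1L, P), design$N, design$J)
                  d2$z <- z; d2 }
    for (v in variants) {
      ctl <- if (is.null(control))
        usp_control(max_iter = max_iter, burn_in = 50L,
                    stop_threshold = 1e-3, variant = v,
                    c1 = if (v == "USP-PPG") 1 else NULL)
      else { c2 <- control; c2$variant <- v; c2 }
      fit <- fit_rlca(dat$Y, design$Q, control = ctl,
                      seed = rep_seed(design, r) + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, variant = v, N = design$N,
        metric = c("theta", "nu"),
        mse = c(mse_block(fit$theta, dat$theta),
                mse_block(fit$nu[-1], dat$nu[-1])))
    }
    if (progress)
      message(sprintf("study III rep %d/%d done", r, design$n_reps))
  }
  per_rep <- do.call(rbind, rows)
  structure(list(design = design, per_rep = per_rep,
                 summary = study_summarize(per_rep)),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study %s: N = %d, %d replications\n",
              x$design$study, x$design$N, x$design$n_reps))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
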