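#' Read and write numeric matrices as headerless CSV
#'
#' Matrix files are plain comma-separated values with no header and `.`
#' decimal separator, one row per line.
#'
#' @param path file path.
#' @param integer coerce to integer (for binary response and design
#'   matrices); non-binary entries in a matrix read with `integer = TRUE`
#'   raise an error naming the offending cell.
#' @return A numeric (or integer) matrix.
#' @export
read_matrix_csv <- function(path, integer = FALSE) {
  df <- utils::read.table(path, sep = ",", header = FALSE,
                          colClasses = "numeric")
  m <- as.matrix(df)
  dimnames(m) <- NULL
  if (integer) {
    bad <- which(!(m %in% c(0, 1)))
    if (length(bad)) {
      i <- ((bad[1] - 1) %% nrow(m)) + 1
      j <- ((bad[1] - 1) %/% nrow(m)) + 1
      stop(sprintf("non-binary entry at row %d, column %d of %s", i, j, path))
    }
    storage.mode(m) <- "integer"
  }
  m
}

#' @rdname read_matrix_csv
#' @param m matrix to write.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a run configuration from JSON or YAML
#'
#' Accepts a file whose top-level keys mirror the [usp_control()] arguments
#' (unknown keys are rejected).  The format is chosen by extension
#' (`.json` vs `.yml`/`.yaml`).
#'
#' @param path configuration file path.
#' @return A [usp_control()].
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else stop("config must be .json, .yml or .yaml")
  known <- names(formals(usp_control))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(usp_control, cfg)
}

#' @rdname read_run_config
#' @param control a [usp_control()] to serialize.
#' @export
write_run_config <- function(control, path) {
  cfg <- unclass(control)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Export a fitted model to a directory
#'
#' Writes a JSON summary (`fit.json`: configuration echo, seed, iteration
#' count, stopping information, scalar summaries; floats kept at full
#' precision) plus CSV blocks of the parameter estimates: for an item
#' factor fit `d.csv`, `A.csv`, `B.csv`, `Sigma.csv`; for a restricted
#' latent class fit `theta.csv` (columns labelled by profile bitstring) and
#' `nu.csv`.
#'
#' @param fit an `ifa_fit` or `rlca_fit`.
#' @param dir output directory (created if needed).
#' @param seed the seed used for the fit (echoed into the summary).
#' @return `dir`, invisibly.
#' @export
write_fit_result <- function(fit, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ctl <- unclass(fit$control)
  ctl <- ctl[!vapply(ctl, is.null, logical(1))]
  info <- list(class = class(fit)[1], control = ctl, seed = seed,
               n_iter = fit$n_iter, stopped = fit$stopped,
               package_version = as.character(utils::packageVersion("proxlvm")))
  history_names <- NULL
  if (inherits(fit, "ifa_fit")) {
    info$penalty <- fit$penalty
    info$nonzero_loadings <- sum(fit$A != 0)
    lay <- fit$layout
    an <- character(0)
    for (j in seq_len(lay$J)) for (k in seq_len(lay$K))
      if (!is.na(lay$amap[j, k])) an <- c(an, sprintf("a_%d_%d", j, k))
    history_names <- c(sprintf("d_%d", seq_len(lay$J)), an,
                       sprintf("b_%d_%d", lay$bpairs[, 1], lay$bpairs[, 2]))
    write_matrix_csv(matrix(fit$d, ncol = 1), file.path(dir, "d.csv"))
    write_matrix_csv(fit$A, file.path(dir, "A.csv"))
    write_matrix_csv(fit$B, file.path(dir, "B.csv"))
    write_matrix_csv(fit$Sigma, file.path(dir, "Sigma.csv"))
  } else if (inherits(fit, "rlca_fit")) {
    K <- ncol(fit$Q)
    info$feasible <- rlca_feasible(fit$theta, fit$constraints)
    labs <- profile_labels(K)
    history_names <- c(outer(seq_len(nrow(fit$theta)), labs,
                             function(j, l) paste0("theta_", j, "_", l)),
                       paste0("nu_", labs[-1]))
    th <- fit$theta
    utils::write.table(
      rbind(profile_labels(K), format(th, digits = 17)),
      file.path(dir, "theta.csv"), sep = ",", row.names = FALSE,
      col.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(profile = profile_labels(K),
                 nu = format(fit$nu, digits = 17)),
      file.path(dir, "nu.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  } else stop("unsupported fit object")
  if (!is.null(fit$history)) {
    H <- fit$history
    colnames(H) <- history_names
    utils::write.table(H, file.path(dir, "history.csv"), sep = ",",
                       row.names = FALSE, col.names = TRUE, quote = FALSE)
  }
  jsonlite::write_json(info, file.path(dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
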