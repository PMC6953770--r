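#' Load a snapshot series from delimited text files
#'
#' Reads one cells-by-markers table per time point (CSV or TSV with a header
#' row of marker names) and assembles them, sorted by time, into a
#' [snapshot_series()].
#'
#' @param manifest A data frame with columns `path` and `time`, or the path
#'   of a CSV manifest with those columns.
#' @param markers Optional character vector restricting the marker columns
#'   (all files must contain them).
#' @return A [snapshot_series()].
#' @export
load_snapshots <- function(manifest, markers = NULL) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  stopifnot(is.data.frame(manifest),
            all(c("path", "time") %in% names(manifest)))
  manifest <- manifest[order(manifest$time), , drop = FALSE]
  missing <- !file.exists(manifest$path)
  if (any(missing))
    stop("missing snapshot file(s): ",
         paste(manifest$path[missing], collapse = ", "), call. = FALSE)
  tables <- lapply(manifest$path, function(p) {
    sep <- if (grepl("\\.tsv$|\\.txt$", p)) "\t" else ","
    utils::read.table(p, header = TRUE, sep = sep, check.names = FALSE)
  })
  cols <- if (is.null(markers)) names(tables[[1]]) else markers
  for (i in seq_along(tables)) {
    absent <- setdiff(cols, names(tables[[i]]))
    if (length(absent) > 0)
      stop(sprintf("file '%s' is missing column(s): %s",
                   manifest$path[i], paste(absent, collapse = ", ")),
           call. = FALSE)
    tab <- tables[[i]][, cols, drop = FALSE]
    bad <- !vapply(tab, is.numeric, TRUE)
    if (any(bad))
      stop(sprintf("file '%s' has non-numeric column(s): %s",
                   manifest$path[i], paste(cols[bad], collapse = ", ")),
           call. = FALSE)
    tables[[i]] <- as.matrix(tab)
  }
  snapshot_series(manifest$time, tables, markers = cols)
}

#' Standard mass-cytometry preprocessing
#'
#' Applies the variance-stabilising transform
#' \eqn{x \mapsto \mathrm{arcsinh}(x/\mathrm{cofactor})} (cofactor 5 is the
#' CyTOF convention) and optionally z-scores each marker using the mean and
#' standard deviation pooled across *all* time points, so that time points
#' remain on a common scale.  Markers with zero pooled variance are dropped
#' with a warning.
#'
#' @param series A [snapshot_series()].
#' @param cofactor arcsinh cofactor; `NULL` skips the transform.
#' @param zscore Standardise markers with pooled statistics.
#' @return A transformed [snapshot_series()].
#' @export
preprocess_snapshots <- function(series, cofactor = 5, zscore = TRUE) {
  stopifnot(inherits(series, "ddd_snapshots"))
  samples <- series$samples
  if (!is.null(cofactor))
    samples <- lapply(samples, function(m) asinh(m / cofactor))
  markers <- series$markers
  if (isTRUE(zscore)) {
    pooled <- do.call(rbind, samples)
    mu <- colMeans(pooled)
    sd_ <- apply(pooled, 2, stats::sd)
    keep <- sd_ > 0
    if (!all(keep)) {
      warning("dropping zero-variance marker(s): ",
              paste(markers[!keep], collapse = ", "))
      markers <- markers[keep]
    }
    samples <- lapply(samples, function(m)
      sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], "/"))
  }
  snapshot_series(series$times, samples, markers = markers)
}

#' Split-window autonomy diagnostic
#'
#' An autonomous process is fitted equally well on any sub-window of the time
#' course.  This refits the model on user-specified windows of time points --
#' all sharing one basis, so errors are comparable -- and reports per-time and
#' mean percentage errors per window.  A window whose error stays high even
#' when fitted on its own indicates loss of autonomy (e.g. an unobserved
#' driver changing mid-course), not merely a single aberrant snapshot.
#'
#' @param coefs Coefficient series for the full time course.
#' @param basis A `ddd_basis` (or mass matrix) shared by every window.
#' @param windows Named list of strictly increasing time-point index vectors;
#'   default is the full window.
#' @param config A [fit_config()].
#' @return An object of class `ddd_autonomy`: list with `fits` (one
#'   `ddd_pf_model` per window) and `errors` (data frame: window, time,
#'   pct_error) plus `means` (data frame: window, mean_pct_error).
#' @export
autonomy_report <- function(coefs, basis, windows = NULL,
                            config = fit_config()) {
  stopifnot(inherits(coefs, "ddd_coefficients"))
  R <- length(coefs$times)
  if (is.null(windows)) windows <- list(full = seq_len(R))
  if (is.null(names(windows)))
    names(windows) <- paste0("window", seq_along(windows))
  fits <- list()
  err_rows <- list()
  for (w in names(windows)) {
    idx <- windows[[w]]
    if (length(idx) < 2)
      stop(sprintf("window '%s' has fewer than 2 time points", w),
           call. = FALSE)
    sub <- coefficient_series(coefs$times[idx], coefs$C[idx, , drop = FALSE])
    fits[[w]] <- fit_pf(sub, basis, config)
    err_rows[[w]] <- data.frame(window = w, time = coefs$times[idx],
                                pct_error = fits[[w]]$pct_errors)
  }
  errors <- do.call(rbind, err_rows)
  rownames(errors) <- NULL
  means <- data.frame(window = names(windows),
                      mean_pct_error = vapply(fits, function(f)
                        f$mean_pct_error, 0))
  rownames(means) <- NULL
  structure(list(fits = fits, errors = errors, means = means),
            class = "ddd_autonomy")
}

#' @export
print.ddd_autonomy <- function(x, ...) {
  cat("Split-window autonomy report (percentage errors):\n")
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Serialise a fitted model to JSON
#'
#' Stores the rate matrix (row-major), initial condition, original and
#' rescaled times, basis parameters, per-time errors, convergence metadata
#' and the fit configuration, so a fit is fully reproducible and portable.
#'
#' @param model A `ddd_pf_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pf_model <- function(model, path) {
  stopifnot(inherits(model, "ddd_pf_model"))
  obj <- list(
    P = as.data.frame(model$P),
    cstar = model$cstar,
    times = model$times,
    rescaled_times = model$taus,
    pct_errors = model$pct_errors,
    mean_pct_error = model$mean_pct_error,
    mse = model$mse,
    beta = model$beta,
    converged = model$converged,
    iterations = model$iterations,
    config = unclass(model$config))
  if (!is.null(model$basis))
    obj$basis <- list(means = as.data.frame(model$basis$means),
                      covariances = lapply(model$basis$covariances,
                                           as.data.frame),
                      source_time = model$basis$source_time)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' One YAML file with optional `simulate`, `basis`, `fit` and `graph`
#' sections; each section holds arguments of the corresponding
#' configuration constructor.
#'
#' @param path YAML file path.
#' @return Named list of configuration objects (absent sections get
#'   defaults).
#' @export
read_ddd_config <- function(path) {
  raw <- yaml::read_yaml(path)
  list(
    simulate = do.call(simulation_config, as_args(raw$simulate)),
    basis = do.call(basis_config, as_args(raw$basis)),
    fit = do.call(fit_config, as_args(raw$fit)),
    graph = if (is.null(raw$graph)) list() else raw$graph)
}

# YAML 1.1 parses a bare key `n` as boolean FALSE; restore it
as_args <- function(x) {
  if (is.null(x)) return(list())
  names(x)[names(x) == "FALSE"] <- "n"
  x
}
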