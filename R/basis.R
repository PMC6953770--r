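#' L2 inner product of two Gaussian densities
#'
#' For multivariate normal densities the inner product
#' \eqn{\int N(x;\mu_a,\Sigma_a)\,N(x;\mu_b,\Sigma_b)\,dx} has the closed
#' form \eqn{N(\mu_a;\, \mu_b,\, \Sigma_a + \Sigma_b)}; it is symmetric in
#' its arguments and strictly positive.
#'
#' @param mu_a,mu_b Component means (equal length).
#' @param Sigma_a,Sigma_b Component covariances.
#' @param log Return the log inner product instead.
#' @return Scalar overlap (or its log).
#' @examples
#' gaussian_overlap(0, 0, matrix(1), matrix(1))   # 1 / (2 sqrt(pi))
#' @export
gaussian_overlap <- function(mu_a, Sigma_a, mu_b, Sigma_b, log = FALSE) {
  stopifnot(length(mu_a) == length(mu_b))
  S <- as.matrix(Sigma_a) + as.matrix(Sigma_b)
  lv <- log_dmvnorm(matrix(mu_a, nrow = 1), as.numeric(mu_b), S)
  if (log) lv else exp(lv)
}

#' Gram (mass) matrix of a Gaussian basis
#'
#' \eqn{M_{ij} = \langle \psi_i, \psi_j \rangle}, computed analytically with
#' [gaussian_overlap()].  The result is symmetric with strictly positive
#' entries; near-duplicate components make it numerically singular, which is
#' reported as a warning.
#'
#' @param means \eqn{N \times d} matrix of component means.
#' @param covariances List of \eqn{N} covariance matrices.
#' @return Symmetric \eqn{N \times N} matrix.
#' @export
mass_matrix <- function(means, covariances) {
  means <- as.matrix(means)
  N <- nrow(means)
  stopifnot(length(covariances) == N)
  M <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in i:N) {
    M[i, j] <- M[j, i] <- gaussian_overlap(means[i, ], covariances[[i]],
                                           means[j, ], covariances[[j]])
  }
  ev_min <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-10 * max(abs(M)))
    warning("mass matrix is not positive definite; basis has near-duplicate components")
  M
}

#' Build the Gaussian-mixture basis from a snapshot series
#'
#' For each time point a Gaussian mixture is fitted ([fit_time_gmm()]; the
#' number of components is fixed or chosen by [select_k_by_aic()]), each cell
#' is hard-assigned to its maximum-responsibility component, components
#' representing less than `alpha` of the time point's cells are dropped, and
#' the surviving components are concatenated in time order (earliest first).
#' All basis functions are probability densities, so the basis weights
#' \eqn{\omega_j = \int \psi_j} are all 1 and the admissible coefficient set
#' is the probability simplex.
#'
#' @param series A [snapshot_series()].
#' @param config A [basis_config()].
#' @return An object of class `ddd_basis` with elements `means`
#'   (\eqn{N \times d}), `covariances` (list), `source_time` (index of the
#'   originating time point per component), `M` (mass matrix), `config`.
#' @export
build_basis <- function(series, config = basis_config()) {
  stopifnot(inherits(series, "ddd_snapshots"),
            inherits(config, "ddd_basis_config"))
  means <- NULL; covariances <- list(); source_time <- integer(0)
  for (r in seq_along(series$times)) {
    X <- series$samples[[r]]
    cfg_r <- config
    cfg_r$seed <- config$seed + 101L * r
    k <- if (identical(config$k, "auto")) select_k_by_aic(X, cfg_r)
         else as.integer(config$k)
    fit <- fit_time_gmm(X, k, cfg_r)
    assign_frac <- tabulate(max.col(fit$responsibilities, ties.method = "first"),
                            k) / nrow(X)
    keep <- assign_frac >= config$alpha
    if (!any(keep))
      stop(sprintf("all %d components dropped at time point %d (alpha = %g)",
                   k, r, config$alpha), call. = FALSE)
    means <- rbind(means, fit$means[keep, , drop = FALSE])
    covariances <- c(covariances, fit$covariances[keep])
    source_time <- c(source_time, rep(r, sum(keep)))
  }
  structure(list(means = means, covariances = covariances,
                 source_time = source_time,
                 weights = rep(1, nrow(means)),
                 M = mass_matrix(means, covariances),
                 config = config),
            class = "ddd_basis")
}

#' Assemble a Gaussian basis directly from component parameters
#'
#' Bypasses mixture fitting; useful for hand-specified or synthetic bases.
#'
#' @param means \eqn{N \times d} matrix of component means.
#' @param covariances List of \eqn{N} covariance matrices.
#' @param source_time Optional originating time-point index per component.
#' @return A `ddd_basis`.
#' @export
gaussian_basis <- function(means, covariances, source_time = NULL) {
  means <- as.matrix(means)
  stopifnot(length(covariances) == nrow(means))
  if (is.null(source_time)) source_time <- rep(1L, nrow(means))
  structure(list(means = means,
                 covariances = lapply(covariances, as.matrix),
                 source_time = as.integer(source_time),
                 weights = rep(1, nrow(means)),
                 M = mass_matrix(means, covariances),
                 config = NULL),
            class = "ddd_basis")
}

#' @export
print.ddd_basis <- function(x, ...) {
  cat(sprintf("Gaussian basis: N = %d components, d = %d, from %d time points\n",
              nrow(x$means), ncol(x$means), length(unique(x$source_time))))
  invisible(x)
}

# n x N matrix of log basis densities at the rows of X
log_basis_densities <- function(X, basis) {
  N <- nrow(basis$means)
  out <- matrix(0, nrow(X), N)
  for (j in seq_len(N))
    out[, j] <- log_dmvnorm(X, basis$means[j, ], basis$covariances[[j]])
  out
}

#' Encode snapshots as simplex coefficient vectors
#'
#' Each snapshot is projected onto the basis by
#' \eqn{c_{r,j} \propto \sum_i \psi_j(x_{r,i})}, normalised to unit sum.
#' Densities are evaluated in log space and combined by log-sum-exp, so
#' high-dimensional bases do not underflow.
#'
#' @param series A [snapshot_series()].
#' @param basis A `ddd_basis` from [build_basis()].
#' @return An object of class `ddd_coefficients`: list with `times` and `C`
#'   (\eqn{R \times N} matrix, rows on the probability simplex).
#' @export
basis_coefficients <- function(series, basis) {
  stopifnot(inherits(series, "ddd_snapshots"), inherits(basis, "ddd_basis"))
  if (ncol(series$samples[[1]]) != ncol(basis$means))
    stop("basis dimension does not match data dimension", call. = FALSE)
  R <- length(series$times)
  N <- nrow(basis$means)
  C <- matrix(0, R, N)
  for (r in seq_len(R)) {
    ld <- log_basis_densities(series$samples[[r]], basis)
    # log sum_i psi_j(x_i), stable per column
    lc <- apply(ld, 2, logsumexp)
    if (all(!is.finite(lc)) || max(lc) < log(.Machine$double.xmin))
      stop(sprintf("all basis densities underflow at time point %d; basis does not cover the data", r),
           call. = FALSE)
    C[r, ] <- exp(lc - logsumexp(lc))
  }
  structure(list(times = series$times, C = C), class = "ddd_coefficients")
}

#' Assemble a coefficient series directly
#'
#' Useful for synthetic experiments where coefficients are generated from a
#' known model rather than encoded from data.
#'
#' @param times Observation times.
#' @param C \eqn{R \times N} matrix of simplex rows.
#' @return An object of class `ddd_coefficients`.
#' @export
coefficient_series <- function(times, C) {
  C <- as.matrix(C)
  stopifnot(length(times) == nrow(C), all(diff(times) > 0))
  if (any(C < -1e-10) || any(abs(rowSums(C) - 1) > 1e-8))
    stop("coefficient rows must lie on the probability simplex", call. = FALSE)
  structure(list(times = as.numeric(times), C = C),
            class = "ddd_coefficients")
}
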