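#' Configuration for the snapshot SDE simulator
#'
#' Defaults reproduce the bistable-well benchmark: overdamped Langevin
#' dynamics with diffusion constant \eqn{D = 1/4} integrated by
#' Euler--Maruyama with step \eqn{\delta t = 2^{-9}}, initial condition
#' \eqn{N((1,1)^\top/2,\, I_2/2)} reflected into the positive quadrant, and
#' 2000 independent trajectories harvested at each of the observation times
#' \eqn{t \in \{0, 1, 2, 3, 5, 8, 13, 21, 34, 55\}}.
#'
#' @param D Diffusion constant (\eqn{\ge 0}).
#' @param dt Euler--Maruyama time step (> 0).
#' @param mu0 Mean of the Gaussian initial condition.
#' @param Sigma0 Covariance of the Gaussian initial condition.
#' @param times Strictly increasing observation times.
#' @param n Trajectories harvested per observation time (\eqn{n_r}).
#' @param seed Integer seed; every observation time draws from its own
#'   deterministically derived stream, so dropping or resizing one time point
#'   leaves the others bit-identical.
#' @return An object of class `ddd_sim_config`.
#' @export
simulation_config <- function(D = 1 / 4, dt = 2^-9,
                              mu0 = c(0.5, 0.5), Sigma0 = diag(2) / 2,
                              times = c(0, 1, 2, 3, 5, 8, 13, 21, 34, 55),
                              n = 2000, seed = 1L) {
  stopifnot(is.numeric(D), length(D) == 1, D >= 0,
            is.numeric(dt), length(dt) == 1, dt > 0,
            is.numeric(times), length(times) >= 1, all(diff(times) > 0),
            is.numeric(n), length(n) == 1, n >= 1)
  Sigma0 <- as.matrix(Sigma0)
  stopifnot(length(mu0) == nrow(Sigma0), nrow(Sigma0) == ncol(Sigma0))
  structure(list(D = D, dt = dt, mu0 = as.numeric(mu0), Sigma0 = Sigma0,
                 times = as.numeric(times), n = as.integer(n),
                 seed = as.integer(seed)),
            class = "ddd_sim_config")
}

#' Snapshot time series container
#'
#' The universal input of the pipeline: one sample matrix per observation
#' time, from mutually independent batches (destructive sampling -- no
#' observation unit is tracked across time points).
#'
#' @param times Strictly increasing observation times, length \eqn{R}.
#' @param samples List of \eqn{R} numeric matrices (\eqn{n_r \times d}), all
#'   with the same number of columns.
#' @param markers Optional column (marker) names.
#' @return An object of class `ddd_snapshots` with elements `times`,
#'   `samples` and `markers`.
#' @export
snapshot_series <- function(times, samples, markers = NULL) {
  stopifnot(is.numeric(times), length(times) == length(samples),
            all(diff(times) > 0))
  samples <- lapply(samples, as.matrix)
  d <- unique(vapply(samples, ncol, 1L))
  if (length(d) != 1)
    stop("all sample matrices must have the same number of columns",
         call. = FALSE)
  for (i in seq_along(samples)) {
    if (any(!is.finite(samples[[i]])))
      stop(sprintf("non-finite values in snapshot %d", i), call. = FALSE)
  }
  if (is.null(markers)) markers <- colnames(samples[[1]])
  if (is.null(markers)) markers <- paste0("x", seq_len(d))
  samples <- lapply(samples, function(m) { colnames(m) <- markers; m })
  structure(list(times = as.numeric(times), samples = samples,
                 markers = markers),
            class = "ddd_snapshots")
}

#' @export
print.ddd_snapshots <- function(x, ...) {
  cat(sprintf("Snapshot series: R = %d time points, d = %d dimensions\n",
              length(x$times), ncol(x$samples[[1]])))
  cat("  times:", paste(signif(x$times, 4), collapse = ", "), "\n")
  cat("  cells:", paste(vapply(x$samples, nrow, 1L), collapse = ", "), "\n")
  invisible(x)
}

#' Perturb snapshots with additive Gaussian measurement noise
#'
#' Adds an independent zero-mean Gaussian draw to every sample point of the
#' selected time points, emulating measurement error.  Used by the benchmark
#' robustness study: perturbing a single time point mimics a locally
#' non-autonomous observation, perturbing all time points mimics systematic
#' measurement noise.
#'
#' @param series A [snapshot_series()].
#' @param which Indices of time points to perturb; `NULL` perturbs all.
#' @param sd Standard deviation per coordinate (covariance `sd^2 * I`);
#'   the benchmark uses `1/2` (covariance \eqn{I_2/4}).
#' @param seed Integer seed.
#' @return A perturbed [snapshot_series()].
#' @export
perturb_snapshots <- function(series, which = NULL, sd = 0.5, seed = 1L) {
  stopifnot(inherits(series, "ddd_snapshots"))
  if (is.null(which)) which <- seq_along(series$times)
  set.seed(seed)
  samples <- series$samples
  for (r in which) {
    X <- samples[[r]]
    samples[[r]] <- X + matrix(stats::rnorm(length(X), sd = sd),
                               nrow(X), ncol(X))
  }
  snapshot_series(series$times, samples, markers = series$markers)
}

#' Drop time points from a snapshot series
#'
#' @param series A [snapshot_series()].
#' @param which Indices of time points to remove.
#' @return A smaller [snapshot_series()].
#' @export
drop_snapshots <- function(series, which) {
  keep <- setdiff(seq_along(series$times), which)
  if (length(keep) < 2) stop("fewer than 2 time points left", call. = FALSE)
  snapshot_series(series$times[keep], series$samples[keep],
                  markers = series$markers)
}

#' Simulate destructively sampled snapshots from an SDE
#'
#' For every observation time \eqn{t_r}, `n` fresh trajectories are drawn
#' from the Gaussian initial condition (reflected into the positive
#' quadrant), integrated forward by Euler--Maruyama under
#' \eqn{dX_t = -\nabla V(X_t)\,dt + \sqrt{2D}\,dW_t}, and harvested at
#' \eqn{t_r}.  Batches for different time points use independent trajectories,
#' mimicking destructive single-cell sampling.  Reflecting boundaries along
#' the coordinate axes are enforced after every step by taking coordinate-wise
#' absolute values.  If `dt` does not divide an observation time exactly the
#' final step is shortened, keeping the scheme order 1.
#'
#' @param config A [simulation_config()].
#' @param potential A [potential_spec()]; defaults to [bistable_potential()].
#' @return A [snapshot_series()] with one \eqn{n \times d} matrix per time.
#' @examples
#' cfg <- simulation_config(times = c(0, 1, 2), n = 100, seed = 7)
#' s <- simulate_snapshots(cfg)
#' all(s$samples[[3]] >= 0)
#' @export
simulate_snapshots <- function(config, potential = bistable_potential()) {
  stopifnot(inherits(config, "ddd_sim_config"),
            inherits(potential, "ddd_potential"))
  d <- potential$dimension
  if (length(config$mu0) != d)
    stop("config dimension does not match potential dimension", call. = FALSE)
  L <- chol(config$Sigma0)
  sqrt2D <- sqrt(2 * config$D)
  samples <- vector("list", length(config$times))
  for (r in seq_along(config$times)) {
    # independent, reproducible stream per observation time, derived from the
    # time value itself so dropping a time point leaves the others unchanged
    set.seed((config$seed %% 32768L) * 30011L +
               (round(1000 * config$times[r]) %% 30011L))
    n <- config$n
    X <- matrix(stats::rnorm(n * d), n, d) %*% L +
      matrix(config$mu0, n, d, byrow = TRUE)
    X <- abs(X)                      # reflect the initial draw too
    t_end <- config$times[r]
    t_cur <- 0
    while (t_cur < t_end - 1e-12) {
      h <- min(config$dt, t_end - t_cur)
      G <- potential$gradient(X)
      X <- X - h * G + (sqrt2D * sqrt(h)) * matrix(stats::rnorm(n * d), n, d)
      X <- abs(X)
      t_cur <- t_cur + h
    }
    samples[[r]] <- X
  }
  snapshot_series(config$times, samples)
}
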