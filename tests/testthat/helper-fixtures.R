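# Shared generators for property-style tests.

# random rate matrix: non-negative off-diagonals, zero column sums
rand_rate_matrix <- function(N, scale = 1) {
  P <- matrix(stats::runif(N * N), N, N) * scale
  diag(P) <- 0
  diag(P) <- -colSums(P)
  P
}

rand_simplex <- function(N) {
  x <- stats::rexp(N)
  x / sum(x)
}

# small 2-d Gaussian basis with distinct anisotropic components
toy_basis <- function(N = 3, seed = 1) {
  set.seed(seed)
  means <- matrix(stats::runif(2 * N, 0, 4), N, 2)
  covs <- lapply(seq_len(N), function(i) {
    A <- matrix(stats::rnorm(4, sd = 0.3), 2, 2)
    crossprod(A) + diag(2) * 0.3
  })
  gaussian_basis(means, covs)
}

# noise-free coefficient series generated by a known model
synthetic_coefs <- function(P_true, cstar, times) {
  taus <- rescale_times(times)
  C <- t(vapply(taus, function(u) propagate(P_true, cstar, u),
                numeric(length(cstar))))
  coefficient_series(times, C)
}

# tiny snapshot series for pipeline tests
tiny_series <- function(n = 150, times = c(0, 1, 2), seed = 7) {
  simulate_snapshots(simulation_config(times = times, n = n, seed = seed))
}

# mixture density of a basis at points (rows of X) with coefficients c
mixture_density <- function(X, basis, coef) {
  rowSums(vapply(seq_len(nrow(basis$means)), function(j) {
    coef[j] * exp(ddd:::log_dmvnorm(X, basis$means[j, ],
                                    basis$covariances[[j]]))
  }, numeric(nrow(X))))
}
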