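test_that("gaussian_overlap matches closed forms and is symmetric", {
  # identical standard normals: density of N(0, 2I) at 0
  expect_equal(gaussian_overlap(0, matrix(1), 0, matrix(1)),
               1 / (2 * sqrt(pi)))
  expect_equal(gaussian_overlap(c(0, 0), diag(2), c(0, 0), diag(2)),
               1 / (4 * pi))
  a <- list(mu = c(1, 2), S = matrix(c(1, .3, .3, 2), 2))
  b <- list(mu = c(-1, 0.5), S = matrix(c(.5, -.1, -.1, .7), 2))
  expect_equal(gaussian_overlap(a$mu, a$S, b$mu, b$S),
               gaussian_overlap(b$mu, b$S, a$mu, a$S))
  # 100-sigma separation underflows to (essentially) zero
  expect_lt(gaussian_overlap(0, matrix(1), 100, matrix(1)), 1e-300)
  expect_error(gaussian_overlap(0, matrix(0), 0, matrix(0)), "positive definite")
})

test_that("mass matrix is symmetric and matches Monte-Carlo quadrature", {
  b1 <- gaussian_basis(matrix(c(0, 0), 1), list(diag(2)))
  expect_equal(b1$M, matrix(1 / (4 * pi)))
  basis <- toy_basis(N = 3, seed = 2)
  expect_identical(basis$M, t(basis$M))
  expect_true(all(basis$M > 0))
  # MC oracle: E_{x ~ psi_i}[psi_j(x)] over 20 random pairs, 3 sigma
  set.seed(42)
  n_mc <- 50000
  for (rep in 1:20) {
    i <- sample(3, 1); j <- sample(3, 1)
    L <- chol(basis$covariances[[i]])
    X <- matrix(rnorm(2 * n_mc), n_mc, 2) %*% L +
      matrix(basis$means[i, ], n_mc, 2, byrow = TRUE)
    vals <- exp(ddd:::log_dmvnorm(X, basis$means[j, ],
                                  basis$covariances[[j]]))
    est <- mean(vals)
    se <- sd(vals) / sqrt(n_mc)
    expect_lt(abs(est - basis$M[i, j]), 3 * se + 1e-12)
  }
})

test_that("mass matrix admits a Cholesky factor after tiny jitter", {
  basis <- toy_basis(N = 5, seed = 3)
  expect_silent(chol(basis$M + diag(1e-10, 5)))
})

test_that("EM recovers a single Gaussian and enforces the covariance floor", {
  set.seed(8)
  X <- matrix(rnorm(600, mean = 2, sd = 0.3), 300, 2)
  fit <- fit_time_gmm(X, 1, basis_config(seed = 1))
  se <- 0.3 / sqrt(300)
  expect_true(all(abs(fit$means - 2) < 3 * se))
  expect_true(all(fit$responsibilities == 1))
  # floor: every fitted variance at least the regularisation value
  fitr <- fit_time_gmm(X, 2, basis_config(regularisation = 0.5, seed = 1))
  diags <- unlist(lapply(fitr$covariances, diag))
  expect_true(all(diags >= 0.5 - 1e-12))
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))   # Mclust needs its namespace attached
  set.seed(15)
  X <- rbind(matrix(rnorm(400, 0, 0.5), 200, 2),
             matrix(rnorm(400, 5, 0.7), 200, 2))
  ours <- fit_time_gmm(X, 2, basis_config(seed = 2))
  ref <- Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  # same clustering solution: matched means within a small tolerance
  ours_means <- ours$means[order(ours$means[, 1]), ]
  ref_means <- t(ref$parameters$mean)[order(t(ref$parameters$mean)[, 1]), ]
  expect_equal(ours_means, ref_means, tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(ours$loglik, ref$loglik, tolerance = 1e-3)
})

test_that("AIC flattening selects the generating number of components", {
  set.seed(30)
  X1 <- matrix(rnorm(500, 0, 1), 250, 2)
  cfg <- basis_config(max_components = 4, seed = 5)
  expect_equal(select_k_by_aic(X1, cfg), 1)
  expect_equal(select_k_by_aic(X1, basis_config(max_components = 1, seed = 5)), 1)
  X3 <- rbind(matrix(rnorm(300, 0, 0.5), 150, 2),
              matrix(rnorm(300, 10, 0.5), 150, 2),
              cbind(rnorm(150, 0, 0.5), rnorm(150, 10, 0.5)))
  expect_equal(select_k_by_aic(X3, basis_config(max_components = 6, seed = 5)), 3)
})

test_that("build_basis concatenates per-time components and applies the drop rate", {
  s <- tiny_series(n = 200, times = c(0, 1, 2), seed = 12)
  b <- build_basis(s, basis_config(k = 2, alpha = 0, seed = 1))
  expect_equal(nrow(b$means), 6)               # k per time point, none dropped
  expect_equal(b$source_time, rep(1:3, each = 2))
  expect_identical(dim(b$M), c(6L, 6L))
  # a 4% cluster is dropped at alpha = 0.3
  set.seed(77)
  X <- rbind(matrix(rnorm(960, 0, 0.4), 480, 2),
             matrix(rnorm(40, 10, 0.4), 20, 2))
  s2 <- snapshot_series(c(0, 1), list(X, X))
  b2 <- build_basis(s2, basis_config(k = 2, alpha = 0.3, seed = 1))
  expect_equal(nrow(b2$means), 2)              # one survivor per time point
  b3 <- build_basis(s2, basis_config(k = 2, alpha = 0, seed = 1))
  expect_equal(nrow(b3$means), 4)
  expect_error(build_basis(s2, basis_config(k = 2, alpha = 0.99, seed = 1)),
               "dropped")
})

test_that("coefficients implement the density-sum projection on the simplex", {
  s <- tiny_series(n = 100, times = c(0, 1), seed = 9)
  b1 <- gaussian_basis(matrix(c(1, 1), 1), list(diag(2)))
  c1 <- basis_coefficients(s, b1)
  expect_equal(as.numeric(c1$C), c(1, 1))
  # two identical components split the mass evenly
  b2 <- gaussian_basis(rbind(c(1, 1), c(1, 1)), list(diag(2), diag(2)))
  expect_equal(as.numeric(basis_coefficients(s, b2)$C),
               rep(0.5, 4))
  # hand computation on 3 printed points and 2 diagonal Gaussians
  pts <- rbind(c(0, 0), c(1, 1), c(2, 0.5))
  s3 <- snapshot_series(c(0, 1), list(pts, pts))
  mu <- list(c(0, 0), c(2, 1))
  b3 <- gaussian_basis(rbind(mu[[1]], mu[[2]]), list(diag(2) * 0.8, diag(2) * 1.3))
  got <- basis_coefficients(s3, b3)$C[1, ]
  dens <- vapply(mu, function(m) {
    sdv <- sqrt(if (identical(m, c(0, 0))) 0.8 else 1.3)
    sum(dnorm(pts[, 1], m[1], sdv) * dnorm(pts[, 2], m[2], sdv))
  }, 0)
  expect_equal(got, dens / sum(dens), tolerance = 1e-12)
})

test_that("coefficient rows are simplex vectors and permute with the basis", {
  s <- tiny_series(n = 120, times = c(0, 1, 2), seed = 14)
  b <- build_basis(s, basis_config(k = 2, seed = 2))
  co <- basis_coefficients(s, b)
  expect_true(all(co$C >= 0))
  expect_true(all(abs(rowSums(co$C) - 1) < 1e-12))
  perm <- c(3, 1, 6, 2, 5, 4)
  bp <- gaussian_basis(b$means[perm, ], b$covariances[perm],
                       b$source_time[perm])
  expect_equal(bp$M, b$M[perm, perm], ignore_attr = TRUE)
  expect_equal(basis_coefficients(s, bp)$C, co$C[, perm])
})

test_that("an uncovering basis is reported rather than silently underflowing", {
  s <- tiny_series(n = 50, times = c(0, 1), seed = 3)
  far <- gaussian_basis(matrix(c(1e4, 1e4), 1), list(diag(2) * 1e-4))
  expect_error(basis_coefficients(s, far), "underflow|cover")
})
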