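test_that("time rescaling maps the course onto the unit interval", {
  expect_equal(rescale_times(c(0, 55)), c(0, 1))
  tt <- c(0, 1, 2, 3, 5, 8, 13, 21, 34, 55)
  expect_equal(rescale_times(tt), tt / 55)
  expect_equal(rescale_times(c(0, 0.25, 1)), c(0, 0.25, 1))
  expect_error(rescale_times(c(2, 2)), "increasing")
})

test_that("propagation reduces to closed forms and conserves probability", {
  expect_equal(propagate(matrix(0, 3, 3), c(.2, .3, .5), 0.7), c(.2, .3, .5))
  # two-state chain: c(tau) = ((1+e^-2tau)/2, (1-e^-2tau)/2)
  P2 <- matrix(c(-1, 1, 1, -1), 2)
  for (tau in c(0, 0.3, 1, 2.5)) {
    expect_equal(propagate(P2, c(1, 0), tau),
                 c((1 + exp(-2 * tau)) / 2, (1 - exp(-2 * tau)) / 2),
                 tolerance = 1e-12)
  }
  set.seed(5)
  for (i in 1:10) {
    N <- sample(2:6, 1)
    p <- propagate(rand_rate_matrix(N, scale = 3), rand_simplex(N), runif(1, 0, 2))
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_gt(min(p), -1e-12)
  }
})

test_that("relative error is the M-weighted relative L2 distance", {
  set.seed(6)
  N <- 4
  P <- rand_rate_matrix(N)
  cstar <- rand_simplex(N)
  M <- toy_basis(N, seed = 4)$M
  tau <- 0.8
  pred <- propagate(P, cstar, tau)
  expect_equal(relative_error(P, cstar, pred, M, tau), 0, tolerance = 1e-14)
  # observation at half the prediction: numerator equals ||c_r||_M^2
  expect_equal(relative_error(P, cstar, pred / 2, M, tau), 1, tolerance = 1e-10)
  expect_error(relative_error(P, cstar, rep(0, N), M, tau), "zero")
})

test_that("relative error agrees with grid quadrature of the density-space integrals", {
  basis <- toy_basis(N = 3, seed = 10)
  set.seed(10)
  P <- rand_rate_matrix(3)
  cstar <- rand_simplex(3)
  c_r <- rand_simplex(3)
  tau <- 0.6
  eps2 <- relative_error(P, cstar, c_r, basis$M, tau)
  # quadrature oracle: integrate the actual Gaussian mixtures on a fine grid
  g <- seq(-6, 10, by = 0.02)
  grid <- as.matrix(expand.grid(x1 = g, x2 = g))
  pred <- propagate(P, cstar, tau)
  num <- sum((mixture_density(grid, basis, pred) -
                mixture_density(grid, basis, c_r))^2) * 0.02^2
  den <- sum(mixture_density(grid, basis, c_r)^2) * 0.02^2
  expect_equal(eps2, num / den, tolerance = 1e-3)
})

test_that("objective is the mean per-time relative error", {
  set.seed(2)
  N <- 3
  M <- toy_basis(N, seed = 5)$M
  C <- t(replicate(4, rand_simplex(N)))
  co <- coefficient_series(c(0, 1, 2, 4), C)
  P <- rand_rate_matrix(N)
  taus <- rescale_times(co$times)
  manual <- mean(vapply(1:4, function(r)
    relative_error(P, C[1, ], C[r, ], M, taus[r]), 0))
  expect_equal(pf_objective(P, C[1, ], co, M), manual)
  # stationary data: P = 0 and c* = c_1 give zero error
  Cs <- matrix(rep(rand_simplex(N), 3), 3, byrow = TRUE)
  cos_ <- coefficient_series(0:2, Cs)
  expect_equal(pf_objective(matrix(0, N, N), Cs[1, ], cos_, M), 0)
})

test_that("series and Frechet gradients match finite differences", {
  set.seed(17)
  h <- 1e-6
  for (inst in 1:10) {
    N <- sample(3:6, 1)
    P <- rand_rate_matrix(N, scale = 2)
    cstar <- rand_simplex(N)
    c_r <- rand_simplex(N)
    M <- toy_basis(N, seed = inst)$M
    tau <- runif(1, 0.1, 1)
    gs <- grad_P(P, cstar, c_r, M, tau, method = "series")
    gf <- grad_P(P, cstar, c_r, M, tau, method = "frechet")
    expect_equal(gs, gf, tolerance = 1e-10)
    fd <- matrix(0, N, N)
    for (i in seq_len(N)) for (j in seq_len(N)) {
      Pp <- P; Pp[i, j] <- Pp[i, j] + h
      Pm <- P; Pm[i, j] <- Pm[i, j] - h
      fd[i, j] <- (relative_error(Pp, cstar, c_r, M, tau) -
                     relative_error(Pm, cstar, c_r, M, tau)) / (2 * h)
    }
    expect_equal(gs, fd, tolerance = 1e-5)
    gc_ <- grad_cstar(P, cstar, c_r, M, tau)
    fdc <- vapply(seq_len(N), function(i) {
      e <- rep(0, N); e[i] <- h
      (relative_error(P, cstar + e, c_r, M, tau) -
         relative_error(P, cstar - e, c_r, M, tau)) / (2 * h)
    }, 0)
    expect_equal(gc_, fdc, tolerance = 1e-5)
  }
})

test_that("gradient degenerate cases vanish as the series structure dictates", {
  set.seed(23)
  N <- 4
  P <- rand_rate_matrix(N)
  cstar <- rand_simplex(N)
  M <- diag(N)
  tau <- 0.5
  pred <- propagate(P, cstar, tau)
  expect_equal(grad_P(P, cstar, pred, M, tau), matrix(0, N, N),
               tolerance = 1e-12)
  expect_equal(grad_cstar(P, cstar, pred, M, tau), rep(0, N),
               tolerance = 1e-12)
  c_r <- rand_simplex(N)
  expect_equal(grad_P(P, cstar, c_r, M, 0), matrix(0, N, N))
  # P = 0: the c* gradient is 2 M (c* - c_r) / ||c_r||_M^2
  expect_equal(grad_cstar(matrix(0, N, N), cstar, c_r, M, tau),
               2 * as.numeric(M %*% (cstar - c_r)) /
                 as.numeric(c_r %*% M %*% c_r))
})

test_that("lasso penalty and its subgradient follow the mass-weighted L1 form", {
  M <- toy_basis(3, seed = 6)$M
  P <- rand_rate_matrix(3)
  expect_equal(lasso_penalty(P, M, 0)$value, 0)
  expect_equal(lasso_penalty(P, M, 0)$gradient, matrix(0, 3, 3) * M)
  # single off-diagonal rate p: two nonzero terms, beta (M_ij + M_jj) p
  P1 <- matrix(0, 3, 3); P1[2, 1] <- 0.7; P1[1, 1] <- -0.7
  expect_equal(lasso_penalty(P1, M, 2)$value, 2 * (M[2, 1] + M[1, 1]) * 0.7)
  expect_equal(lasso_penalty(P, M, 1.5)$value, 1.5 * sum(abs(M * P)))
  g <- lasso_penalty(P, M, 1)$gradient
  expect_equal(diag(g), -diag(M))
  expect_equal(g[1, 2], M[1, 2])
})

test_that("noise-free coefficients from a known model are recovered", {
  set.seed(41)
  N <- 5
  P_true <- rand_rate_matrix(N, scale = 2)
  c_true <- rand_simplex(N)
  times <- c(0, 1, 2, 3, 4, 6)
  co <- synthetic_coefs(P_true, c_true, times)
  fit <- fit_pf(co, diag(N), fit_config(factr = 10))
  expect_lt(fit$mse, 1e-8)
  pred <- predict(fit)
  expect_equal(pred, co$C, tolerance = 1e-4, ignore_attr = TRUE)
  expect_true(all(abs(colSums(fit$P)) < 1e-12))
  off <- fit$P; diag(off) <- 0
  expect_true(all(off >= 0))
})

test_that("stationary coefficient series fit to zero error", {
  set.seed(55)
  N <- 3
  c0 <- rand_simplex(N)
  co <- coefficient_series(0:3, matrix(rep(c0, 4), 4, byrow = TRUE))
  fit <- fit_pf(co, toy_basis(N, seed = 7)$M, fit_config(factr = 10))
  expect_lt(fit$objective, 1e-10)
})

test_that("the lasso solution never beats the unpenalised fit on raw error", {
  set.seed(61)
  N <- 4
  P_true <- rand_rate_matrix(N, scale = 1.5)
  co <- synthetic_coefs(P_true, rand_simplex(N), c(0, 1, 2, 4, 7))
  M <- toy_basis(N, seed = 8)$M
  plain <- fit_pf(co, M)
  lasso <- fit_pf(co, M, fit_config(beta_divisor = 50))
  expect_gte(pf_objective(lasso$P, lasso$cstar, co, M) + 1e-12,
             pf_objective(plain$P, plain$cstar, co, M))
  expect_equal(lasso$beta, 1 / (50 * mean(M)))
})

test_that("fitted models conserve probability along the whole trajectory", {
  set.seed(71)
  N <- 4
  co <- synthetic_coefs(rand_rate_matrix(N, scale = 2), rand_simplex(N),
                        c(0, 1, 3, 5))
  fit <- fit_pf(co, toy_basis(N, seed = 9)$M)
  for (tau in seq(0, 1, by = 0.1)) {
    p <- propagate(fit$P, fit$cstar, tau)
    expect_lt(abs(sum(p) - 1), 1e-10)
    expect_gt(min(p), -1e-10)
  }
})
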