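#' Basis-construction configuration
#'
#' Controls how the Gaussian-mixture basis is built from each snapshot.
#'
#' @param k Number of mixture components per time point, or `"auto"` to pick
#'   it per time point by AIC flattening (see [select_k_by_aic()]).
#' @param regularisation Hard floor applied to every diagonal entry of each
#'   component covariance after each EM M-step.  For arcsinh/z-scored mass
#'   cytometry data a value of 1/2 is a good default; 0 disables the floor.
#' @param alpha Drop rate: after hard-assigning each cell to its
#'   maximum-responsibility component, components representing fewer than
#'   `alpha` of that time point's cells are removed from the basis.
#' @param max_components Largest k tried when `k = "auto"`.
#' @param aic_threshold Relative AIC improvement below which the curve is
#'   declared flat (see [select_k_by_aic()]).
#' @param em_restarts EM restarts kept from different initialisations; the
#'   best non-degenerate fit wins.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param seed Integer seed for k-means++ initialisation.
#' @return An object of class `ddd_basis_config`.
#' @export
basis_config <- function(k = 3, regularisation = 0, alpha = 0,
                         max_components = 10, aic_threshold = 0.01,
                         em_restarts = 5, max_iter = 500, tol = 1e-8,
                         seed = 1L) {
  stopifnot(identical(k, "auto") || (is.numeric(k) && k >= 1),
            regularisation >= 0, alpha >= 0, alpha < 1,
            max_components >= 1, em_restarts >= 1)
  structure(list(k = k, regularisation = regularisation, alpha = alpha,
                 max_components = as.integer(max_components),
                 aic_threshold = aic_threshold,
                 em_restarts = as.integer(em_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "ddd_basis_config")
}

# k-means++ seeding (Arthur & Vassilvitskii) for EM initialisation
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  if (k > 1) for (j in 2:k) {
    p <- d2 / sum(d2)
    idx[j] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ])^2))
  }
  X[idx, , drop = FALSE]
}

# One EM run; returns NULL on degeneracy.
em_gmm_once <- function(X, k, regularisation, max_iter, tol) {
  n <- nrow(X); d <- ncol(X)
  centers <- kmeanspp_centers(X, k)
  km <- tryCatch(stats::kmeans(X, centers = centers, iter.max = 50),
                 error = function(e) NULL)
  if (is.null(km)) return(NULL)
  prop <- tabulate(km$cluster, k) / n
  if (any(prop == 0)) return(NULL)
  mu <- km$centers
  Sigma <- lapply(seq_len(k), function(j) {
    Xi <- X[km$cluster == j, , drop = FALSE]
    S <- if (nrow(Xi) > d) stats::cov(Xi) else stats::cov(X)
    S <- S + diag(1e-8, d)
    diag(S) <- pmax(diag(S), regularisation)
    S
  })
  ll_old <- -Inf
  logR <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      lj <- tryCatch(log_dmvnorm(X, mu[j, ], Sigma[[j]]),
                     error = function(e) NULL)
      if (is.null(lj)) return(NULL)
      logR[, j] <- log(prop[j]) + lj
    }
    m <- apply(logR, 1, max)
    lse <- m + log(rowSums(exp(logR - m)))
    ll <- sum(lse)
    R <- exp(logR - lse)
    nk <- colSums(R)
    if (any(nk < d + 1e-3)) return(NULL)     # empty/degenerate component
    prop <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(R[, j] * X) / nk[j]
      Xc <- sweep(X, 2, mu[j, ])
      S <- crossprod(sqrt(R[, j]) * Xc) / nk[j]
      S <- (S + t(S)) / 2 + diag(1e-8, d)
      diag(S) <- pmax(diag(S), regularisation)  # covariance floor per M-step
      Sigma[[j]] <- S
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(means = mu, covariances = Sigma, proportions = prop,
       responsibilities = R, loglik = ll,
       n_params = (k - 1) + k * d + k * d * (d + 1) / 2)
}

#' Fit a Gaussian mixture to one snapshot
#'
#' Expectation--maximisation with k-means++ initialisation, a hard floor on
#' covariance diagonal entries applied inside every M-step, and restarts that
#' keep the best non-degenerate fit.  Posterior responsibilities are returned
#' so poorly populated components can later be pruned by drop rate.
#'
#' @param X Sample matrix (\eqn{n \times d}).
#' @param k Number of components.
#' @param config A [basis_config()].
#' @return List with `means` (\eqn{k \times d}), `covariances` (list of
#'   \eqn{d \times d}), `proportions`, `responsibilities` (\eqn{n \times k}),
#'   `loglik`, `aic`.
#' @export
fit_time_gmm <- function(X, k, config = basis_config()) {
  X <- as.matrix(X)
  k <- as.integer(k)
  if (nrow(X) <= k * ncol(X))
    stop("too few samples for the requested number of components",
         call. = FALSE)
  set.seed(config$seed + 31L * k)
  best <- NULL
  for (restart in seq_len(config$em_restarts)) {
    fit <- em_gmm_once(X, k, config$regularisation, config$max_iter,
                       config$tol)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best))
    stop(sprintf(
      "EM degenerate for k = %d after %d restarts; reduce k or raise the covariance regularisation",
      k, config$em_restarts), call. = FALSE)
  # deterministic order: components sorted by mixing proportion (desc)
  ord <- order(best$proportions, decreasing = TRUE)
  best$means <- best$means[ord, , drop = FALSE]
  best$covariances <- best$covariances[ord]
  best$proportions <- best$proportions[ord]
  best$responsibilities <- best$responsibilities[, ord, drop = FALSE]
  best$aic <- 2 * best$n_params - 2 * best$loglik
  best
}

#' Choose the number of mixture components by AIC flattening
#'
#' Fits mixtures with \eqn{k = 1, \ldots,} `max_components` and returns the
#' smallest \eqn{k} at which the relative AIC improvement from \eqn{k} to
#' \eqn{k+1} drops below `aic_threshold` (default 1\%) -- the point where the
#' AIC curve flattens out.  Degenerate fits at large \eqn{k} terminate the
#' scan.
#'
#' @inheritParams fit_time_gmm
#' @return Integer \eqn{k}.
#' @export
select_k_by_aic <- function(X, config = basis_config()) {
  X <- as.matrix(X)
  kmax <- config$max_components
  aic <- rep(NA_real_, kmax)
  for (k in seq_len(kmax)) {
    fit <- tryCatch(fit_time_gmm(X, k, config), error = function(e) NULL)
    if (is.null(fit)) break
    aic[k] <- fit$aic
    if (k > 1) {
      improvement <- (aic[k - 1] - aic[k]) / abs(aic[k - 1])
      if (improvement < config$aic_threshold) return(k - 1L)
    }
  }
  max(which(!is.na(aic)))
}
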