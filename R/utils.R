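# Internal numerical helpers shared across modules.

#' @importFrom Matrix expm Matrix
mat_exp <- function(A) {
  as.matrix(Matrix::expm(Matrix::Matrix(A, sparse = FALSE)))
}

# log N(x; mu, Sigma) for each row of x (n x d). Cholesky-based; no
# dependency on a density package so the d = 18 case stays in log space.
log_dmvnorm <- function(x, mu, Sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  d <- ncol(x)
  L <- tryCatch(chol(Sigma), error = function(e)
    stop("covariance matrix is not positive definite", call. = FALSE))
  xc <- sweep(x, 2, mu)
  z <- backsolve(L, t(xc), transpose = TRUE)   # L^T z = xc^T  =>  z = L^-T xc^T
  q <- colSums(z^2)
  -0.5 * q - sum(log(diag(L))) - 0.5 * d * log(2 * pi)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

stopifnot_finite_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("'%s' must be a finite numeric matrix", name), call. = FALSE)
  invisible(x)
}

# symmetric PSD square root, used for eigenfunction graphs
sym_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}
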