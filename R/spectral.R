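#' Eigen-decomposition of the fitted rate matrix
#'
#' Solves \eqn{P v_\lambda = \lambda v_\lambda} for all \eqn{N} eigenpairs,
#' normalises each eigenvector in the M-weighted norm
#' (\eqn{v_\lambda^\top M v_\lambda = 1}; complex vectors use the Hermitian
#' form \eqn{v^H M v}), and sorts by descending real part with ties broken by
#' ascending \eqn{|\Im(\lambda)|}.  A rate matrix with zero column sums always
#' has a zero eigenvalue (the steady state); all other eigenvalues of an
#' irreducible fit have non-positive real part.  Because times are rescaled
#' to the unit interval, eigenvalues are in units of inverse rescaled time:
#' \eqn{|\Re(\lambda)| < 1} would correspond to dynamics slower than the
#' observation window.
#'
#' @param model A `ddd_pf_model`, or a rate matrix (then `M` is required).
#' @param M Mass matrix; taken from the model when omitted.
#' @return An object of class `ddd_spectrum`: list with `values` (complex),
#'   `vectors` (complex \eqn{N \times N}, M-normalised columns), `M`, and
#'   `defective` flag.
#' @export
pf_eigen <- function(model, M = NULL) {
  if (inherits(model, "ddd_pf_model")) {
    P <- model$P
    if (is.null(M)) M <- model$M
  } else P <- as.matrix(model)
  if (is.null(M)) stop("'M' is required when passing a bare matrix",
                       call. = FALSE)
  e <- eigen(P)
  ord <- order(-Re(e$values), abs(Im(e$values)))
  values <- as.complex(e$values[ord])
  vectors <- matrix(as.complex(e$vectors[, ord]), nrow(P))
  defective <- FALSE
  sv <- svd(vectors, nu = 0, nv = 0)$d
  if (sum(sv > max(sv) * 1e-10) < ncol(P)) {
    defective <- TRUE
    warning("rate matrix is numerically defective; eigenvectors reported as-is")
  }
  for (j in seq_len(ncol(vectors))) {
    v <- vectors[, j]
    nrm <- sqrt(abs(Re((Conj(v) %*% M %*% v)[1])))
    if (nrm > 0) v <- v / nrm
    # deterministic sign/phase: largest-magnitude entry made real positive
    i0 <- which.max(Mod(v))
    ph <- v[i0] / Mod(v[i0])
    v <- v / ph
    if (max(Mod(Im(v))) < 1e-10 * max(Mod(v))) v <- complex(real = Re(v))
    vectors[, j] <- v
  }
  structure(list(values = values, vectors = vectors, M = M,
                 defective = defective),
            class = "ddd_spectrum")
}

#' @export
print.ddd_spectrum <- function(x, ...) {
  cat("Perron-Frobenius spectrum (1/rescaled time):\n")
  v <- x$values[seq_len(min(8, length(x$values)))]
  cat(paste0("  ", format(signif(v, 4)), collapse = "\n"), "\n")
  if (length(x$values) > 8) cat(sprintf("  ... (%d total)\n", length(x$values)))
  invisible(x)
}

#' Steady-state distribution of the rate matrix
#'
#' The right null vector of \eqn{P} (eigenvalue 0), rescaled to a
#' non-negative unit-sum coefficient vector.  Multiple numerically zero
#' eigenvalues indicate a reducible chain; all corresponding vectors are then
#' returned with a flag.
#'
#' @param P Rate matrix or `ddd_pf_model`.
#' @param tol Magnitude below which an eigenvalue counts as zero.
#' @return List with `pi` (simplex vector, or matrix of columns when
#'   degenerate), `unique` (logical), `residual` (\eqn{\|P\pi\|_\infty}).
#' @export
steady_state <- function(P, tol = 1e-8) {
  if (inherits(P, "ddd_pf_model")) P <- P$P
  e <- eigen(P)
  zero <- which(Mod(e$values) < tol * max(1, max(Mod(e$values))))
  if (length(zero) == 0)
    stop("no zero eigenvalue found; not a conservative rate matrix",
         call. = FALSE)
  vecs <- sapply(zero, function(j) {
    v <- Re(e$vectors[, j])
    v <- v / sum(v)
    pmax(v, 0) / sum(pmax(v, 0))
  })
  unique_ss <- length(zero) == 1
  if (!unique_ss)
    warning("multiple zero eigenvalues: reducible chain, steady state not unique")
  pi_hat <- if (unique_ss) as.numeric(vecs) else vecs
  res <- if (unique_ss) max(abs(P %*% pi_hat)) else
    max(abs(P %*% vecs))
  list(pi = pi_hat, unique = unique_ss, residual = res)
}

#' Rank-1 eigenfunction graph
#'
#' For an M-normalised eigenvector \eqn{v_\lambda} the symmetric rank-1
#' adjacency \eqn{G_\lambda = (M^{1/2} v_\lambda)(M^{1/2} v_\lambda)^\top}
#' (with the symmetric PSD square root of \eqn{M}) visualises the
#' eigenfunction in high dimension: a positive entry \eqn{(i,j)} means basis
#' functions \eqn{i} and \eqn{j} carry the same sign, a negative entry
#' opposite signs (probability flowing between them).  Complex conjugate
#' pairs yield separate graphs for the real and imaginary parts.
#'
#' @param spectrum A `ddd_spectrum` from [pf_eigen()].
#' @param which Index of the eigenpair (1 = leading).
#' @return For a real eigenvalue, a list with `lambda`, `G`
#'   (\eqn{N \times N}); for a complex one, additionally `G_imag`.
#' @export
eigen_graph <- function(spectrum, which = 1) {
  stopifnot(inherits(spectrum, "ddd_spectrum"))
  v <- spectrum$vectors[, which]
  lambda <- spectrum$values[which]
  Ms <- sym_sqrt(spectrum$M)
  is_complex <- max(abs(Im(v))) > 1e-10 * max(Mod(v))
  wr <- as.numeric(Ms %*% Re(v))
  out <- list(lambda = lambda, G = tcrossprod(wr))
  if (is_complex) {
    wi <- as.numeric(Ms %*% Im(v))
    out$G_imag <- tcrossprod(wi)
  }
  out
}
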