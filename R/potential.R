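#' Potential-energy specification for SDE simulation
#'
#' A potential specification bundles an energy function \eqn{V(x)} with its
#' analytic gradient so that overdamped Langevin dynamics
#' \eqn{dX_t = -\nabla V(X_t)\,dt + \sqrt{2D}\,dW_t} can be integrated by
#' [simulate_snapshots()].  Both functions must accept an \eqn{n \times d}
#' matrix of points (one per row) and return, respectively, a length-\eqn{n}
#' vector of energies and an \eqn{n \times d} matrix of gradients.
#'
#' @param dimension State-space dimension \eqn{d}.
#' @param value Function mapping an \eqn{n \times d} matrix to \eqn{n} energies.
#' @param gradient Function mapping an \eqn{n \times d} matrix to an
#'   \eqn{n \times d} matrix \eqn{\nabla V}.
#' @return An object of class `ddd_potential`.
#' @seealso [bistable_potential()] for the built-in benchmark well.
#' @export
potential_spec <- function(dimension, value, gradient) {
  stopifnot(is.function(value), is.function(gradient),
            is.numeric(dimension), length(dimension) == 1, dimension >= 1)
  structure(list(dimension = as.integer(dimension),
                 value = value, gradient = gradient),
            class = "ddd_potential")
}

#' The bistable two-path potential well
#'
#' A two-dimensional potential with a shallow basin at the initial state
#' \eqn{(1,1)^\top/2} and two terminal wells at \eqn{(4,2)^\top} and
#' \eqn{(2,4)^\top}:
#' \deqn{V(x) = \left(\tfrac25\|x\|^2 - x_1 x_2\right)^2
#'   - \tfrac12 e^{-\frac12\|x-(\frac12,\frac12)^\top\|^2}
#'   - e^{-\|x-(4,2)^\top\|^2} - e^{-\|x-(2,4)^\top\|^2}.}
#' Because \eqn{2\|x\|^2 - 5x_1x_2 = (2x_1 - x_2)(2x_2 - x_1)}, the squared
#' term vanishes exactly on the two rays \eqn{y = 2x} and \eqn{y = x/2}:
#' particles initialised near the origin commit stochastically to one of
#' these two valleys and settle in the Gaussian wells at their ends,
#' emulating a binary cell-fate decision.  The well is symmetric under
#' swapping the two coordinates.
#'
#' @return A `ddd_potential` of dimension 2.
#' @examples
#' pot <- bistable_potential()
#' potential_value(pot, c(2, 4)) < potential_value(pot, c(3, 3))
#' @export
bistable_potential <- function() {
  value <- function(x) {
    x <- as_points(x, 2)
    x1 <- x[, 1]; x2 <- x[, 2]
    s <- x1^2 + x2^2
    a <- 0.4 * s - x1 * x2
    r0 <- (x1 - 0.5)^2 + (x2 - 0.5)^2
    r1 <- (x1 - 4)^2 + (x2 - 2)^2
    r2 <- (x1 - 2)^2 + (x2 - 4)^2
    a^2 - 0.5 * exp(-0.5 * r0) - exp(-r1) - exp(-r2)
  }
  gradient <- function(x) {
    x <- as_points(x, 2)
    x1 <- x[, 1]; x2 <- x[, 2]
    s <- x1^2 + x2^2
    a <- 0.4 * s - x1 * x2
    e0 <- exp(-0.5 * ((x1 - 0.5)^2 + (x2 - 0.5)^2))
    e1 <- exp(-((x1 - 4)^2 + (x2 - 2)^2))
    e2 <- exp(-((x1 - 2)^2 + (x2 - 4)^2))
    g1 <- 2 * a * (0.8 * x1 - x2) +
      0.5 * e0 * (x1 - 0.5) + 2 * e1 * (x1 - 4) + 2 * e2 * (x1 - 2)
    g2 <- 2 * a * (0.8 * x2 - x1) +
      0.5 * e0 * (x2 - 0.5) + 2 * e1 * (x2 - 2) + 2 * e2 * (x2 - 4)
    cbind(g1, g2, deparse.level = 0)
  }
  potential_spec(2, value, gradient)
}

as_points <- function(x, d) {
  if (is.null(dim(x))) {
    if (length(x) != d)
      stop(sprintf("point must have %d coordinates", d), call. = FALSE)
    x <- matrix(x, nrow = 1)
  }
  x <- as.matrix(x)
  if (ncol(x) != d)
    stop(sprintf("points must have %d columns", d), call. = FALSE)
  if (any(!is.finite(x)))
    stop("points must be finite", call. = FALSE)
  x
}

#' Evaluate a potential or its gradient
#'
#' @param potential A [potential_spec()] object.
#' @param x A point (length-\eqn{d} vector) or an \eqn{n \times d} matrix of
#'   points, one per row.
#' @return `potential_value()`: a numeric vector of energies;
#'   `potential_gradient()`: an \eqn{n \times d} gradient matrix (a vector
#'   input returns a single-row matrix dropped to a vector).
#' @export
potential_value <- function(potential, x) {
  stopifnot(inherits(potential, "ddd_potential"))
  drop(potential$value(as_points(x, potential$dimension)))
}

#' @rdname potential_value
#' @export
potential_gradient <- function(potential, x) {
  stopifnot(inherits(potential, "ddd_potential"))
  g <- potential$gradient(as_points(x, potential$dimension))
  if (is.null(dim(x))) drop(g) else g
}
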