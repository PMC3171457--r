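# Potential-energy model contract: scalar value, gradient and Hessian over
# the full internal-coordinate vector, with the unconstrained/constrained
# split attached. Analytic derivatives are used when supplied; otherwise a
# numeric fallback (central differences) stands in, which degrades the
# exactness guarantee of the constraint Jacobian to gradient-FD accuracy.

#' Construct a potential-energy model over internal coordinates
#'
#' @param value function(q) -> scalar energy, \code{q} a named numeric vector
#'   in the canonical coordinate ordering.
#' @param gradient function(q) -> numeric vector (same length as q), or
#'   \code{NULL} to fall back to central differences of \code{value}.
#' @param hessian function(q) -> symmetric matrix, or \code{NULL} to fall
#'   back to central differences of the gradient (step 1e-5).
#' @param coords character vector of coordinate names (canonical order).
#' @param split a \code{"coord_split"} over \code{coords}.
#' @param check if \code{TRUE}, spot-check gradient/Hessian consistency with
#'   \code{value} by FD probes at \code{check_at}.
#' @param check_at named numeric vector at which to run the consistency probe.
#' @return an object of class \code{"potential_model"}.
#' @export
potential_model <- function(value, gradient = NULL, hessian = NULL,
                            coords, split, check = FALSE, check_at = NULL) {
  stopifnot(inherits(split, "coord_split"))
  if (!setequal(c(split$u, split$d), coords)) {
    stop("split does not cover the model coordinates exactly")
  }
  mode <- if (is.null(gradient) || is.null(hessian)) "numeric-fallback" else "analytic"
  if (is.null(gradient)) gradient <- function(q) fd_gradient(value, q, 1e-6)
  if (is.null(hessian)) {
    grad_fn <- gradient
    hessian <- function(q) fd_jacobian_of(grad_fn, q, 1e-5)
  }
  model <- structure(
    list(value = value, gradient = gradient, hessian = hessian,
         coords = coords, split = split,
         M = split$M, L = split$L, derivative_mode = mode),
    class = "potential_model"
  )
  if (check) {
    at <- if (is.null(check_at)) stats::setNames(rep(0.1, length(coords)), coords) else check_at
    g <- gradient(at)
    g_fd <- fd_gradient(value, at, 1e-6)
    if (max(abs(g - g_fd)) > 1e-4 * max(1, max(abs(g)))) {
      stop("gradient inconsistent with value under FD probe")
    }
    H <- hessian(at)
    if (max(abs(H - t(H))) > 1e-10 * max(1, max(abs(H)))) {
      stop("Hessian is not symmetric to 1e-10 relative")
    }
  }
  model
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("<potential_model> M = %d unconstrained, L = %d constrained (%s derivatives)\n",
              x$M, x$L, x$derivative_mode))
  invisible(x)
}

fd_gradient <- function(f, q, h) {
  vapply(seq_along(q), function(i) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    (f(qp) - f(qm)) / (2 * h)
  }, numeric(1))
}

fd_jacobian_of <- function(g, q, h) {
  cols <- vapply(seq_along(q), function(i) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    (g(qp) - g(qm)) / (2 * h)
  }, numeric(length(q)))
  H <- (cols + t(cols)) / 2  # symmetrize away FD noise
  if (any(!is.finite(H))) stop("numeric-fallback Hessian has non-finite entries")
  H
}

# Assemble the full coordinate vector from (u, d) per the model's split.
assemble_q <- function(model, u, d) {
  q <- stats::setNames(numeric(length(model$coords)), model$coords)
  q[model$split$u] <- u
  q[model$split$d] <- d
  q
}

#' Extract the constrained Hessian sub-blocks
#'
#' Evaluates the model Hessian at (u, d) and returns the d-d and d-u blocks
#' in the split ordering: \code{H_dd} (L x L, symmetric) and \code{H_du}
#' (L x M).
#'
#' @param model a \code{"potential_model"}.
#' @param u unconstrained coordinate values (length M).
#' @param d constrained coordinate values (length L).
#' @return list with elements \code{H_dd} and \code{H_du}.
#' @export
hessian_blocks <- function(model, u, d) {
  q <- assemble_q(model, u, d)
  H <- model$hessian(q)
  if (any(!is.finite(H))) stop("Hessian evaluation produced non-finite entries")
  dimnames(H) <- list(model$coords, model$coords)
  H_dd <- H[model$split$d, model$split$d, drop = FALSE]
  H_dd <- (H_dd + t(H_dd)) / 2
  list(H_dd = H_dd,
       H_du = H[model$split$d, model$split$u, drop = FALSE])
}

#' Quadratic potential model from a symmetric matrix
#'
#' \eqn{V(z) = \tfrac12 z^T K z} over coordinates ordered (u, d). For such a
#' model the constrained minimizer is affine in u and the constraint Jacobian
#' is the constant \eqn{-K_{dd}^{-1} K_{du}}; used for closed-form checks.
#'
#' @param K symmetric matrix of size (M + L); the d-d block must be positive
#'   definite.
#' @param M number of unconstrained coordinates.
#' @param L number of constrained coordinates.
#' @return a \code{"potential_model"} with coordinates \code{u1..uM, d1..dL}.
#' @export
quadratic_model <- function(K, M, L) {
  stopifnot(nrow(K) == M + L, ncol(K) == M + L)
  K <- (K + t(K)) / 2
  coords <- c(paste0("u", seq_len(M)), paste0("d", seq_len(L)))
  sp <- coord_split(coords[seq_len(M)], coords[M + seq_len(L)])
  potential_model(
    value = function(q) 0.5 * sum(q * (K %*% q)),
    gradient = function(q) as.numeric(K %*% q),
    hessian = function(q) K,
    coords = coords, split = sp
  )
}

#' Observable over the (u, d) coordinates
#'
#' A position-dependent observable restricted to the constrained subspace:
#' supplies its value and its partial derivatives with respect to the
#' unconstrained and constrained coordinates.
#'
#' @param value function(u, d) -> scalar.
#' @param grad_u function(u, d) -> M-vector of partials w.r.t. u.
#' @param grad_d function(u, d) -> L-vector of partials w.r.t. d.
#' @return an object of class \code{"observable"}.
#' @export
observable <- function(value, grad_u, grad_d) {
  structure(list(value = value, grad_u = grad_u, grad_d = grad_d),
            class = "observable")
}
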