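# The exact algorithm: define f(u) by minimizing V over the constrained
# coordinates d at fixed u, certify the stationary point is a true minimum
# (H_dd positive definite), and obtain the constraint Jacobian J = df/du by
# solving the linear system H_dd J = -H_du. Chain-ruling J into observables
# or body-fixed atomic positions gives derivatives along the constrained
# subspace using only quantities evaluated at the point itself.

#' Minimize the potential over the constrained coordinates at fixed u
#'
#' Newton iteration with a Levenberg-style positive-definite safeguard and
#' backtracking line search; the analytic Hessian is reused for the step, so
#' Newton costs nothing beyond what the constraint Jacobian already needs.
#' At convergence the routine certifies that the stationary point is a
#' minimum (Cholesky of \code{H_dd} succeeds) and solves for the Jacobian.
#'
#' @param model a \code{"potential_model"}.
#' @param u unconstrained coordinate values (length M).
#' @param d0 warm-start for the constrained coordinates (length L); the
#'   minimization is local and basins are selected by this start.
#' @param tol infinity-norm gradient tolerance; defaults to 1e-10 for
#'   analytic models and 1e-8 for numeric-fallback derivatives.
#' @param max_iter iteration cap (default 500).
#' @return an object of class \code{"constrained_point"} with elements
#'   \code{u}, \code{d_star}, \code{energy}, \code{grad_d_residual_norm},
#'   \code{H_dd}, \code{H_du}, \code{J}, \code{min_eig_H_dd},
#'   \code{iterations}, \code{condition_estimate}.
#' @export
minimize_constrained <- function(model, u, d0, tol = NULL, max_iter = 500L) {
  if (is.null(tol)) {
    tol <- if (model$derivative_mode == "analytic") 1e-10 else 1e-8
  }
  L <- model$L
  stopifnot(length(u) == model$M, length(d0) == L, all(is.finite(d0)))
  d <- as.numeric(d0)

  grad_d <- function(d) model$gradient(assemble_q(model, u, d))[
    match(model$split$d, model$coords)]
  val <- function(d) model$value(assemble_q(model, u, d))

  g <- grad_d(d)
  iter <- 0L
  while (max(abs(g)) > tol && iter < max_iter) {
    iter <- iter + 1L
    H_dd <- hessian_blocks(model, u, d)$H_dd
    # positive-definite safeguard: shift until Cholesky succeeds
    tau <- 0
    repeat {
      ch <- tryCatch(chol(H_dd + diag(tau, L)), error = function(e) NULL)
      if (!is.null(ch)) break
      tau <- if (tau == 0) 1e-6 * max(1, max(abs(diag(H_dd)))) else 10 * tau
      if (tau > 1e12) stop("cannot regularize H_dd; minimization aborted")
    }
    step <- -backsolve(ch, forwardsolve(t(ch), g))
    # backtracking on the energy; the acceptance test carries a few-ulp
    # slack so that full Newton steps are not rejected once the energy
    # decrease falls below floating-point resolution
    f0 <- val(d); g0n <- max(abs(g)); alpha <- 1
    slack <- 4 * .Machine$double.eps * (abs(f0) + 1)
    repeat {
      d_new <- d + alpha * step
      f_new <- val(d_new)
      if (is.finite(f_new) &&
          f_new <= f0 + 1e-4 * alpha * sum(g * step) + slack) break
      if (alpha < 1e-10) {
        # last resort: the full Newton step, if it contracts the gradient
        d_try <- d + step
        if (max(abs(grad_d(d_try))) < g0n) d_new <- d_try
        break
      }
      alpha <- alpha / 2
    }
    d <- d_new
    g <- grad_d(d)
  }
  if (max(abs(g)) > tol) {
    stop(sprintf("constrained minimization did not converge in %d iterations (residual %.3e)",
                 max_iter, max(abs(g))))
  }

  blocks <- hessian_blocks(model, u, d)
  ev_min <- min(eigen(blocks$H_dd, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) {
    stop(sprintf("stationary point is not a minimum: H_dd has min eigenvalue %.3e (saddle or maximum)",
                 ev_min))
  }
  point <- structure(
    list(u = u, d_star = stats::setNames(d, model$split$d),
         energy = val(d),
         grad_d_residual_norm = max(abs(g)),
         H_dd = blocks$H_dd, H_du = blocks$H_du,
         min_eig_H_dd = ev_min,
         iterations = iter,
         model = model),
    class = "constrained_point"
  )
  point$J <- constrained_jacobian(point)
  point$condition_estimate <- attr(point$J, "condition_estimate")
  point
}

#' @export
print.constrained_point <- function(x, ...) {
  cat(sprintf(
    "<constrained_point> M = %d, L = %d; energy %.6g; grad residual %.2e; min eig H_dd %.3g\n",
    length(x$u), length(x$d_star), x$energy, x$grad_d_residual_norm,
    x$min_eig_H_dd))
  invisible(x)
}

#' Constraint Jacobian from the Hessian sub-blocks
#'
#' Solves \eqn{H_{dd} J = -H_{du}} by a symmetric positive-definite (Cholesky)
#' factorization, one triangular solve per unconstrained coordinate. Emits a
#' warning when the condition estimate of \code{H_dd} exceeds 1e12.
#'
#' @param point a \code{"constrained_point"} (or any list with \code{H_dd}
#'   and \code{H_du}).
#' @return the L x M matrix \code{J} with \code{J[I, i]} = \eqn{\partial f^I
#'   / \partial u^i}; carries the condition estimate as an attribute.
#' @export
constrained_jacobian <- function(point) {
  H_dd <- point$H_dd; H_du <- point$H_du
  ch <- tryCatch(chol(H_dd), error = function(e) {
    ev <- min(eigen(H_dd, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf("H_dd is not positive definite (min eigenvalue %.3e)", ev))
  })
  J <- -backsolve(ch, forwardsolve(t(ch), H_du))
  if (!is.matrix(J)) J <- matrix(J, nrow = nrow(H_dd))
  dimnames(J) <- dimnames(H_du)
  resid <- max(abs(H_dd %*% J + H_du))
  scale <- max(abs(H_du))
  if (scale > 0 && resid > 1e-10 * scale) {
    warning(sprintf("Jacobian solve residual %.3e exceeds 1e-10 relative", resid / scale))
  }
  kap <- kappa(H_dd, exact = FALSE)
  if (kap > 1e12) {
    warning(sprintf("H_dd condition estimate %.3e exceeds 1e12; Jacobian may be inaccurate", kap))
  }
  attr(J, "condition_estimate") <- kap
  J
}

#' Total derivative of an observable along the constrained subspace
#'
#' \eqn{D O / D u_i = \partial O/\partial u_i + \sum_I (\partial O/\partial
#' d_I) J[I, i]} evaluated at \code{(u, f(u))}. With \code{J = 0} (hard
#' constraints, constant d) this reduces to the plain partial derivative.
#'
#' @param observable an \code{"observable"}.
#' @param point a \code{"constrained_point"}.
#' @return numeric M-vector of total derivatives.
#' @export
observable_total_derivative <- function(observable, point) {
  u <- point$u; d <- point$d_star
  gu <- observable$grad_u(u, d)
  gd <- observable$grad_d(u, d)
  if (length(gu) != length(u) || length(gd) != length(d)) {
    stop("observable partials have wrong dimensions")
  }
  as.numeric(gu + crossprod(point$J, gd))
}

#' Derivatives of body-fixed atomic positions along the constrained subspace
#'
#' Chain rule over the geometric Jacobian:
#' \eqn{D x'_\beta / D u_i = \partial x'_\beta/\partial u_i + \sum_I
#' (\partial x'_\beta/\partial d_I) J[I, i]}.
#'
#' @param topology a valid \code{"zmat_topology"}.
#' @param split the \code{"coord_split"} used by the model.
#' @param point a \code{"constrained_point"} at \code{(u, f(u))}.
#' @param geo a \code{"geom_jacobian"} evaluated at the internals
#'   \code{(u, f(u))}; a stale-geometry error is raised if it was evaluated
#'   elsewhere (beyond 1e-10).
#' @return array \code{[atom, xyz, unconstrained coordinate]} of class
#'   \code{"constrained_cartesian_derivs"}.
#' @export
euclidean_constrained_derivatives <- function(topology, split, point, geo) {
  g_int <- attr(geo, "internals")
  expect <- stats::setNames(numeric(length(g_int)), names(g_int))
  expect[split$u] <- point$u
  expect[split$d] <- point$d_star
  dev <- max(abs(angular_aware_diff(g_int, expect, names(g_int))))
  if (dev > 1e-10) {
    stop(sprintf("stale geometry: geometric Jacobian evaluated %.3e away from the constrained point",
                 dev))
  }
  n <- topology$n
  out <- array(0, dim = c(n, 3, split$M),
               dimnames = list(NULL, c("x", "y", "z"), split$u))
  G <- unclass(geo)
  Gd <- G[, , split$d, drop = FALSE]
  for (i in seq_len(split$M)) {
    ui <- split$u[i]
    acc <- G[, , ui]
    for (I in seq_len(split$L)) {
      acc <- acc + Gd[, , I] * point$J[I, i]
    }
    out[, , i] <- acc
  }
  structure(out, class = "constrained_cartesian_derivs")
}

# difference that treats dihedrals modulo 2*pi
angular_aware_diff <- function(a, b, nms) {
  d <- a - b
  is_ang <- grepl("^phi", nms)
  d[is_ang] <- wrap_angle(d[is_ang])
  d
}

#' Long-format view of constrained Cartesian derivatives
#' @param x a \code{"constrained_cartesian_derivs"}.
#' @param ... unused.
#' @return tibble with columns \code{atom}, \code{coordinate}, \code{dx},
#'   \code{dy}, \code{dz}.
#' @export
as_tibble.constrained_cartesian_derivs <- function(x, ...) {
  un <- dimnames(x)[[3]]
  dplyr::bind_rows(purrr::map(un, function(ui) {
    tibble::tibble(atom = seq_len(dim(x)[1]), coordinate = ui,
                   dx = x[, 1, ui], dy = x[, 2, ui], dz = x[, 3, ui])
  }))
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy a constrained point into its Jacobian entries
#'
#' @param x a \code{"constrained_point"}.
#' @param ... unused.
#' @return tibble with one row per (constrained, unconstrained) pair and the
#'   Jacobian entry \code{dJ = df_I/du_i}.
#' @export
tidy.constrained_point <- function(x, ...) {
  J <- x$J
  tibble::tibble(
    constrained = rep(rownames(J), times = ncol(J)),
    unconstrained = rep(colnames(J), each = nrow(J)),
    derivative = as.numeric(J)
  )
}

#' One-row summary of a constrained point
#'
#' @param x a \code{"constrained_point"}.
#' @param ... unused.
#' @return tibble with energy, residual, minimum H_dd eigenvalue, condition
#'   estimate and iteration count.
#' @export
glance.constrained_point <- function(x, ...) {
  tibble::tibble(
    energy = x$energy,
    grad_d_residual_norm = x$grad_d_residual_norm,
    min_eig_H_dd = x$min_eig_H_dd,
    condition_estimate = x$condition_estimate,
    iterations = x$iterations
  )
}
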