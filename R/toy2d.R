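# A 2D toy system with one unconstrained coordinate x and one stiffly bound
# coordinate y. The stiff harmonic term holds y near y0, the x^2 y coupling
# shifts the minimizer with x, and the small quartic term keeps the
# constrained minimizer f(x) genuinely implicit (no compact closed form),
# while the Hessian entries remain closed-form:
#   V(x, y) = a/2 x^2 + c x^2 y + k/2 (y - y0)^2 + q y^4
#   dV/dy   = c x^2 + k (y - y0) + 4 q y^3        (stationarity in y)
#   H_yy    = k + 12 q y^2,  H_xy = 2 c x,  H_xx = a + 2 c y

#' Parameters of the 2D toy potential
#'
#' Defaults: \code{a = 1}, \code{c = 0.3}, \code{k = 100} (stiff direction),
#' \code{y0 = 1}, \code{q = 0.5}, with the unconstrained coordinate scanned
#' over \code{x_range = c(-2, 2)}. The stiff coefficient is large enough that
#' \code{H_yy = k + 12 q y^2 > 0} everywhere.
#'
#' @param a harmonic coefficient on x.
#' @param c x^2-y coupling strength.
#' @param k stiff harmonic constant on y.
#' @param y0 harmonic center of y.
#' @param q quartic coefficient on y.
#' @param x_range numeric length-2 scan range of x.
#' @return a list of class \code{"toy2d_params"}.
#' @export
toy2d_params <- function(a = 1, c = 0.3, k = 100, y0 = 1, q = 0.5,
                         x_range = c(-2, 2)) {
  stopifnot(k > 0, q >= 0)
  structure(list(a = a, c = c, k = k, y0 = y0, q = q, x_range = x_range),
            class = "toy2d_params")
}

#' Potential model of the 2D toy system
#'
#' Analytic value, gradient and Hessian with coordinates \code{c("x", "y")},
#' x unconstrained and y constrained (M = L = 1).
#'
#' @param params a \code{"toy2d_params"}.
#' @return a \code{"potential_model"}.
#' @export
toy2d_model <- function(params = toy2d_params()) {
  p <- params
  sp <- coord_split("x", "y")
  potential_model(
    value = function(q) {
      x <- q[["x"]]; y <- q[["y"]]
      0.5 * p$a * x^2 + p$c * x^2 * y + 0.5 * p$k * (y - p$y0)^2 + p$q * y^4
    },
    gradient = function(q) {
      x <- q[["x"]]; y <- q[["y"]]
      c(p$a * x + 2 * p$c * x * y,
        p$c * x^2 + p$k * (y - p$y0) + 4 * p$q * y^3)
    },
    hessian = function(q) {
      x <- q[["x"]]; y <- q[["y"]]
      matrix(c(p$a + 2 * p$c * y, 2 * p$c * x,
               2 * p$c * x, p$k + 12 * p$q * y^2), 2, 2)
    },
    coords = c("x", "y"), split = sp
  )
}

#' Distance-to-origin observable for the toy system
#'
#' \eqn{r(x, y) = \sqrt{x^2 + y^2}} with partials \eqn{x/r} and \eqn{y/r};
#' along the constrained curve the total derivative is
#' \eqn{(x + f(x) f'(x))/r}.
#'
#' @return an \code{"observable"}.
#' @export
toy2d_observable <- function() {
  observable(
    value = function(u, d) sqrt(u[[1]]^2 + d[[1]]^2),
    grad_u = function(u, d) u[[1]] / sqrt(u[[1]]^2 + d[[1]]^2),
    grad_d = function(u, d) d[[1]] / sqrt(u[[1]]^2 + d[[1]]^2)
  )
}
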