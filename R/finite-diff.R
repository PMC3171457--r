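# Finite-difference comparator: estimates the constrained derivatives by
# displacing one unconstrained coordinate, re-minimizing the constrained
# coordinates at the displaced point, and differencing. This is the natural
# alternative the exact Hessian-based route is validated against, and it
# carries the two pathologies the exact route avoids: rounding error at
# small steps (aggravated by stiff coordinates and truncated printed
# precision) and truncation/basin-identity error at large steps.

#' Finite-difference estimate of a constrained derivative
#'
#' Displaces unconstrained coordinate \code{i} by \code{delta} (forward
#' scheme) or by \code{+-delta/2} (central scheme), re-minimizes the
#' constrained coordinates at each endpoint (warm-started from the
#' undisplaced minimizer), and differences the requested quantity:
#' the constrained minimizer \code{f(u)} itself, an observable restricted to
#' the constrained subspace, or the body-fixed Cartesian coordinates.
#'
#' @param model a \code{"potential_model"}.
#' @param u unconstrained coordinate values (length M).
#' @param i index (or name) of the displaced unconstrained coordinate.
#' @param delta step size, in the coordinate's own units (radians for
#'   dihedrals).
#' @param scheme \code{"forward"} (default) or \code{"central"}.
#' @param d0 warm start for the base minimization; defaults to the model's
#'   equilibrium guess via \code{base_point}.
#' @param what \code{"minimizer"}, \code{"observable"} or \code{"euclidean"}.
#' @param observable an \code{"observable"} (for \code{what = "observable"}).
#' @param topology,split,frame topology context (for \code{what =
#'   "euclidean"}).
#' @param truncate_decimals if non-NULL, round the minimized constrained
#'   coordinates to this many decimal places at each endpoint before
#'   differencing, emulating finite printed output precision.
#' @param basin_hop_tol per-coordinate jump threshold between endpoint
#'   minimizers above which a basin-hop warning is emitted (default 0.5).
#' @param base_point optional precomputed \code{"constrained_point"} at
#'   \code{u} (reused across deltas).
#' @return numeric vector: the FD estimate of the derivative of the requested
#'   quantity with respect to \code{u_i} (length L for \code{"minimizer"}, 1
#'   for \code{"observable"}, 3N for \code{"euclidean"}, flattened atom-major).
#' @export
fd_derivative <- function(model, u, i, delta, scheme = c("forward", "central"),
                          d0 = NULL, what = c("minimizer", "observable", "euclidean"),
                          observable = NULL, topology = NULL, split = NULL,
                          frame = "z-xz", truncate_decimals = NULL,
                          basin_hop_tol = 0.5, base_point = NULL) {
  scheme <- match.arg(scheme)
  what <- match.arg(what)
  if (delta <= 0) stop("delta must be positive")
  if (is.character(i)) i <- match(i, model$split$u)
  stopifnot(!is.na(i), i >= 1, i <= model$M)

  if (is.null(base_point)) {
    if (is.null(d0)) stop("either d0 or base_point must be supplied")
    base_point <- minimize_constrained(model, u, d0)
  }
  d_base <- as.numeric(base_point$d_star)

  endpoint <- function(shift) {
    u_s <- u; u_s[i] <- u_s[i] + shift
    pt <- tryCatch(
      minimize_constrained(model, u_s, d_base),
      error = function(e) stop(sprintf("endpoint minimization at shift %+g failed: %s",
                                       shift, conditionMessage(e)))
    )
    jump <- max(abs(as.numeric(pt$d_star) - d_base))
    if (jump > basin_hop_tol) {
      warning(sprintf("basin hop suspected at shift %+g: constrained minimizer moved %.3g (> %.3g)",
                      shift, jump, basin_hop_tol), call. = FALSE)
    }
    pt
  }

  quantity <- function(pt) {
    d <- as.numeric(pt$d_star)
    if (!is.null(truncate_decimals)) d <- truncate_precision(d, truncate_decimals)
    switch(what,
      minimizer = d,
      observable = observable$value(pt$u, d),
      euclidean = {
        q <- stats::setNames(numeric(length(model$coords)), model$coords)
        q[split$u] <- pt$u; q[split$d] <- d
        as.numeric(build_cartesian(topology, ic_from_vector(unname(q[coordinate_names(topology)]),
                                                            topology$n),
                                   frame = frame))
      }
    )
  }

  if (scheme == "forward") {
    g0 <- quantity(base_point)
    g1 <- quantity(endpoint(delta))
    (g1 - g0) / delta
  } else {
    gm <- quantity(endpoint(-delta / 2))
    gp <- quantity(endpoint(delta / 2))
    (gp - gm) / delta
  }
}

#' Sweep finite-difference step sizes against the exact derivatives
#'
#' Runs [fd_derivative()] for every requested step size and compares with the
#' analytic constraint Jacobian column at the same point.
#'
#' @inheritParams fd_derivative
#' @param deltas positive step sizes (coordinate units, radians for angles).
#' @param targets names of constrained coordinates to report (default: all).
#' @return a tibble of class \code{"fd_report"} with columns \code{target},
#'   \code{delta}, \code{fd_estimate}, \code{analytic_value},
#'   \code{abs_error}, \code{normalized_error}, \code{scheme}; the
#'   per-coordinate normalizers are attached as an attribute.
#' @export
delta_sweep <- function(model, u, i, deltas, d0 = NULL,
                        scheme = c("forward", "central"), targets = NULL,
                        truncate_decimals = NULL, base_point = NULL) {
  scheme <- match.arg(scheme)
  if (length(deltas) == 0) stop("empty delta list")
  if (any(deltas <= 0) || anyDuplicated(deltas)) {
    stop("delta values must be positive and unique")
  }
  if (is.character(i)) i <- match(i, model$split$u)
  if (is.null(base_point)) {
    if (is.null(d0)) stop("either d0 or base_point must be supplied")
    base_point <- minimize_constrained(model, u, d0)
  }
  analytic <- base_point$J[, i]
  d_names <- model$split$d
  if (is.null(targets)) targets <- d_names
  idx <- match(targets, d_names)
  if (anyNA(idx)) stop("unknown target coordinate(s)")

  normalizer <- pmax(abs(analytic[idx]), .Machine$double.eps)
  rows <- purrr::map(sort(deltas), function(dl) {
    fd <- fd_derivative(model, u, i, dl, scheme = scheme,
                        base_point = base_point,
                        truncate_decimals = truncate_decimals)
    tibble::tibble(
      target = targets,
      delta = dl,
      fd_estimate = fd[idx],
      analytic_value = unname(analytic[idx]),
      abs_error = abs(fd[idx] - analytic[idx]),
      scheme = scheme
    )
  })
  out <- dplyr::bind_rows(rows)
  out$normalized_error <- out$abs_error / normalizer[match(out$target, targets)]
  attr(out, "normalizers") <- stats::setNames(normalizer, targets)
  attr(out, "u") <- u
  class(out) <- c("fd_report", class(out))
  out
}

#' Normalized average error between FD and analytic derivatives
#'
#' For each coordinate, the mean over conformations of the absolute
#' difference between the finite-difference and analytic derivative, divided
#' by a per-coordinate normalizer. The normalizer (a single transcription
#' point) defaults to the maximum absolute analytic derivative over the
#' conformations.
#'
#' @param fd_values numeric matrix, conformations x coordinates.
#' @param analytic_values numeric matrix, same shape.
#' @param normalizer optional numeric vector of per-coordinate normalizers;
#'   must be strictly positive.
#' @return tibble with one row per coordinate (\code{coordinate},
#'   \code{normalized_error}, \code{normalizer}) plus an \code{"overall"}
#'   attribute holding the average across coordinates.
#' @export
error_metric <- function(fd_values, analytic_values, normalizer = NULL) {
  fd_values <- as.matrix(fd_values)
  analytic_values <- as.matrix(analytic_values)
  if (!all(dim(fd_values) == dim(analytic_values))) {
    stop("FD and analytic value matrices must have the same shape")
  }
  if (nrow(fd_values) < 1) stop("at least one conformation is required")
  if (is.null(normalizer)) {
    normalizer <- apply(abs(analytic_values), 2, max)
  }
  if (any(normalizer <= 0)) {
    stop("undefined normalization: normalizer must be strictly positive")
  }
  err <- colMeans(abs(fd_values - analytic_values)) / normalizer
  nms <- colnames(fd_values)
  if (is.null(nms)) nms <- paste0("q", seq_along(err))
  out <- tibble::tibble(coordinate = nms,
                        normalized_error = unname(err),
                        normalizer = unname(normalizer))
  attr(out, "overall") <- mean(err)
  out
}

#' Round values to a fixed number of decimal places
#'
#' Decimal rounding, half to even; used to emulate the finite printed
#' precision of coordinate output before finite differencing.
#'
#' @param values numeric vector.
#' @param decimals non-negative integer.
#' @return rounded values.
#' @export
truncate_precision <- function(values, decimals) {
  stopifnot(decimals >= 0)
  round(values, digits = decimals)
}

#' Plot an FD report as error versus step size
#'
#' Log-log curve of the absolute FD error against the step size, one line
#' per target coordinate.
#'
#' @param object an \code{"fd_report"} from [delta_sweep()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fd_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$delta, y = .data$abs_error,
                               colour = .data$target)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Delta), y = "absolute error",
                  colour = "coordinate") +
    ggplot2::theme_minimal()
}
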