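# Analytic ("geometrical/kinematical") derivatives of body-fixed atomic
# positions with respect to internal coordinates. Bond-length changes
# translate the downstream atoms along the bond direction; angle and dihedral
# changes rotate them, so the derivatives are cross products of the rotation
# axis with the lever arm from the fixed point. Everything is evaluated at
# the current geometry; no finite differences anywhere on this path.

#' Rodrigues rotation of a vector about a unit axis
#'
#' \eqn{v' = v\cos\alpha + (n \times v)\sin\alpha + n (n\cdot v)(1-\cos\alpha)}.
#' Valid for free vectors, or for position vectors taken relative to a fixed
#' point on the rotation axis.
#'
#' @param v numeric 3-vector to rotate.
#' @param n unit 3-vector rotation axis (checked to 1e-12).
#' @param angle rotation angle, radians.
#' @return the rotated 3-vector.
#' @export
rodrigues_rotate <- function(v, n, angle) {
  if (abs(norm3(n) - 1) > 1e-12) {
    stop("rotation axis must be a unit vector (|n| = 1 within 1e-12)")
  }
  v * cos(angle) + cross3(n, v) * sin(angle) + n * sum(n * v) * (1 - cos(angle))
}

# Mover sets. moves_under(beta, q) decides whether atom beta's body-fixed
# position depends on internal coordinate q:
#  - b_k:     k in C(beta)
#  - theta_k: k in C(beta), or beta descends from a fig4a mover of k
#  - phi_k:   k in C(beta), or beta descends from a fig4b branch-start mover

#' Does an atom move when an internal coordinate changes?
#'
#' Implements the mover rules: an atom moves under \code{b_k} iff \code{k}
#' is in its chain to the origin; under \code{theta_k} additionally when the
#' atom descends from a special-case mover bonded to atom 2 with angle
#' reference 3; under \code{phi_k} additionally when it descends from a
#' branch-start atom whose phase dihedral references atom \code{k}.
#'
#' @param topology a valid \code{"zmat_topology"}.
#' @param beta atom index.
#' @param q internal coordinate name (e.g. \code{"theta3"}).
#' @return logical scalar.
#' @export
moves_under <- function(topology, beta, q) {
  pc <- parse_coordinate(q)
  k <- pc$atom
  chain <- chain_to_origin(topology, beta)
  if (k %in% chain) return(TRUE)
  if (pc$type == "b") return(FALSE)
  sc <- special_case_movers(topology)
  if (pc$type == "theta") {
    movers <- sc$fig4a[[as.character(k)]]
  } else {
    movers <- sc$fig4b[[as.character(k)]]
  }
  !is.null(movers) && any(movers %in% chain)
}

# Cache-free helper returning special-case movers keyed by owner atom.
special_case_movers <- function(topology) {
  sc <- detect_special_cases(topology)
  split_by <- function(df) {
    if (nrow(df) == 0) return(list())
    split(df$mover, as.character(df$owner))
  }
  list(
    fig4a = split_by(sc[sc$case == "fig4a_angle", ]),
    fig4b = split_by(sc[sc$case == "fig4b_dihedral", ])
  )
}

#' Derivative of an atomic position with respect to a bond length
#'
#' Returns the unit vector from the bond-reference atom \code{a(k)} to atom
#' \code{k} when \code{beta} moves under \code{b_k}, else the exact zero
#' vector: a bond-length change translates all downstream atoms rigidly.
#'
#' @param topology a valid \code{"zmat_topology"}.
#' @param coords body-fixed coordinates consistent with the topology.
#' @param beta atom whose position is differentiated.
#' @param k atom owning the bond length (\code{k >= 2}).
#' @return numeric 3-vector.
#' @export
d_dbond <- function(topology, coords, beta, k) {
  if (!moves_under(topology, beta, paste0("b", k))) return(c(0, 0, 0))
  x <- unclass(coords)
  unit3(x[k, ] - x[topology$bond_ref[k], ],
        sprintf("bond %d-%d", topology$bond_ref[k], k))
}

#' Rotation axis for a bond-angle change
#'
#' Unit normal to the plane of (angle-ref, bond-ref, k), oriented so that a
#' positive rotation of atom \code{k} about it (fixed point at the bond
#' reference) increases the measured bond angle.
#'
#' @inheritParams d_dbond
#' @param k atom owning the bond angle (\code{k >= 3}).
#' @return unit 3-vector.
#' @export
angle_rotation_axis <- function(topology, coords, k) {
  x <- unclass(coords)
  A <- x[topology$bond_ref[k], ]
  B <- x[topology$angle_ref[k], ]
  v <- cross3(B - A, x[k, ] - A)
  nn <- norm3(v)
  if (nn < 1e-10) {
    stop(sprintf("degenerate geometry: collinear reference triplet at atom %d", k))
  }
  v / nn
}

#' Derivative of an atomic position with respect to a bond angle
#'
#' \eqn{n_{\theta_k} \times (x'_\beta - x'_{a(k)})} for movers (the fixed
#' point of the rotation is the bond-reference atom), else the exact zero
#' vector. The bond-reference atom itself does not move.
#'
#' @inheritParams angle_rotation_axis
#' @param beta atom whose position is differentiated.
#' @return numeric 3-vector (length/radian).
#' @export
d_dangle <- function(topology, coords, beta, k) {
  if (!moves_under(topology, beta, paste0("theta", k))) return(c(0, 0, 0))
  x <- unclass(coords)
  n <- angle_rotation_axis(topology, coords, k)
  cross3(n, x[beta, ] - x[topology$bond_ref[k], ])
}

#' Derivative of an atomic position with respect to a dihedral angle
#'
#' The rotation axis is the unit vector from the angle-reference atom to the
#' bond-reference atom of \code{k}; the fixed point is the bond-reference
#' atom. Movers (chain members, and branch-start atoms phased on a principal
#' dihedral together with their descendants) get
#' \eqn{u \times (x'_\beta - x'_{a(k)})}; everything else is exactly zero.
#'
#' @inheritParams d_dbond
#' @param k atom owning the dihedral (\code{k >= 4}).
#' @return numeric 3-vector (length/radian).
#' @export
d_ddihedral <- function(topology, coords, beta, k) {
  if (!moves_under(topology, beta, paste0("phi", k))) return(c(0, 0, 0))
  x <- unclass(coords)
  A <- x[topology$bond_ref[k], ]
  B <- x[topology$angle_ref[k], ]
  u <- unit3(A - B, sprintf("rotation axis of phi%d", k))
  cross3(u, x[beta, ] - A)
}

#' Full geometric Jacobian of body-fixed positions
#'
#' Assembles \eqn{\partial x'_\beta / \partial q_k} for every atom and every
#' internal coordinate from one Cartesian build plus closed-form generator
#' evaluations. Entries outside the mover sets are exact zeros.
#'
#' @param topology a valid \code{"zmat_topology"}.
#' @param internals an \code{"internal_coords"}.
#' @param frame frame convention passed to [build_cartesian()].
#' @return an object of class \code{"geom_jacobian"}: a 3-dimensional array
#'   \code{[atom, xyz, coordinate]} with the coordinate names as dimnames,
#'   plus the geometry it was evaluated at as attributes.
#' @export
geometric_jacobian <- function(topology, internals, frame = "z-xz") {
  t <- topology
  x <- build_cartesian(t, internals, frame = frame)
  qn <- coordinate_names(t)
  J <- array(0, dim = c(t$n, 3, length(qn)),
             dimnames = list(NULL, c("x", "y", "z"), qn))
  for (q in qn) {
    pc <- parse_coordinate(q)
    for (beta in seq_len(t$n)) {
      J[beta, , q] <- switch(pc$type,
        b = d_dbond(t, x, beta, pc$atom),
        theta = d_dangle(t, x, beta, pc$atom),
        phi = d_ddihedral(t, x, beta, pc$atom)
      )
    }
  }
  structure(J, internals = ic_to_vector(internals), frame = frame,
            class = "geom_jacobian")
}

#' @export
print.geom_jacobian <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<geom_jacobian> %d atoms x %d internal coordinates\n",
              d[1], d[3]))
  invisible(x)
}

#' Long-format view of a geometric Jacobian
#'
#' One row per (atom, coordinate) mover pair with the 3-vector entry;
#' exact-zero non-mover entries are dropped.
#'
#' @param x a \code{"geom_jacobian"}.
#' @param ... unused.
#' @return a tibble with columns \code{atom}, \code{coordinate}, \code{dx},
#'   \code{dy}, \code{dz}.
#' @export
as_tibble.geom_jacobian <- function(x, ...) {
  qn <- dimnames(x)[[3]]
  rows <- purrr::map(qn, function(q) {
    mat <- unclass(x)[, , q, drop = FALSE]
    nz <- which(rowSums(abs(mat[, , 1, drop = FALSE])) > 0)
    if (length(nz) == 0) return(NULL)
    tibble::tibble(atom = nz, coordinate = q,
                   dx = mat[nz, 1, 1], dy = mat[nz, 2, 1], dz = mat[nz, 3, 1])
  })
  dplyr::bind_rows(rows)
}

#' Export a geometric Jacobian to CSV or JSON
#'
#' @param x a \code{"geom_jacobian"}.
#' @param path output path; format chosen by extension (.csv or .json).
#' @return the path, invisibly.
#' @export
write_geom_jacobian <- function(x, path) {
  tab <- as_tibble.geom_jacobian(x)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tab, path, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}
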