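# Body-fixed ("primed") frame construction and measurement.
#
# Gauge: atom 1 at the origin; atom 2 on the positive designated axis; atom 3
# in the designated coordinate plane with positive in-plane component. The
# frame convention is read from a single place (frame_rotation) by everything
# in the package.

FRAME_CONVENTIONS <- c("z-xz", "x-xy")

# Proper rotation taking the canonical frame (atom 2 on +z, atom 3 in xz,
# x > 0) to the requested one. Applied as coords %*% t(P).
frame_rotation <- function(convention = c("z-xz", "x-xy")) {
  convention <- match.arg(convention)
  switch(convention,
    "z-xz" = diag(3),
    # atom 2 on +x, atom 3 in the xy-plane with y > 0: cyclic z->x, x->y, y->z
    "x-xy" = matrix(c(0, 0, 1,
                      1, 0, 0,
                      0, 1, 0), 3, 3, byrow = TRUE)
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v, context = "vector") {
  n <- norm3(v)
  if (n < 1e-12) stop(sprintf("degenerate geometry: zero-length %s", context))
  v / n
}

#' Build body-fixed Cartesian coordinates from internal coordinates
#'
#' Places each atom incrementally. Atom 1 sits exactly at the origin, atom 2
#' on the positive designated semi-axis, atom 3 in the designated plane with
#' positive in-plane coordinate (gauge components are exact zeros, not merely
#' small). Atoms \code{k >= 4} are placed by the standard three-reference
#' construction: bond length along the bond reference, bond angle measured at
#' the bond-reference vertex, dihedral about the angle-ref -> bond-ref axis
#' with the right-hand sign convention (cis = 0).
#'
#' @param topology a valid \code{"zmat_topology"}.
#' @param internals an \code{"internal_coords"} with matching atom count.
#' @param frame frame convention, \code{"z-xz"} (default: atom 2 on +z,
#'   atom 3 in the xz-plane) or \code{"x-xy"}.
#' @return an N x 3 matrix of class \code{"primed_coords"} (rows are atoms),
#'   with the element labels as an attribute.
#' @export
build_cartesian <- function(topology, internals, frame = "z-xz") {
  t <- topology
  ic <- internals
  if (ic$n != t$n) stop("topology and internals disagree on atom count")
  n <- t$n
  x <- matrix(0, n, 3)

  if (n >= 2) {
    x[2, ] <- c(0, 0, ic$b["b2"])
  }
  if (n >= 3) {
    a1 <- t$bond_ref[3]; a2 <- t$angle_ref[3]
    b <- ic$b["b3"]; th <- ic$theta["theta3"]
    uab <- (x[a2, ] - x[a1, ]) / norm3(x[a2, ] - x[a1, ])  # +-z exactly
    # in-plane: x-component positive, y-component exactly zero
    x[3, ] <- x[a1, ] + c(b * sin(th), 0, b * cos(th) * uab[3])
  }
  if (n >= 4) {
    for (k in 4:n) {
      A <- x[t$bond_ref[k], ]
      B <- x[t$angle_ref[k], ]
      C <- x[t$dihedral_ref[k], ]
      b <- ic$b[[paste0("b", k)]]
      th <- ic$theta[[paste0("theta", k)]]
      ph <- ic$phi[[paste0("phi", k)]]
      u <- unit3(A - B, sprintf("bond between reference atoms of atom %d", k))
      nref <- cross3(B - C, u)
      nn <- norm3(nref)
      if (nn < 1e-10) {
        stop(sprintf("degenerate geometry: collinear reference triplet for atom %d", k))
      }
      nref <- nref / nn
      m <- cross3(nref, u)
      x[k, ] <- A + b * (-cos(th) * u +
                           sin(th) * (cos(ph) * m + sin(ph) * nref))
    }
  }
  P <- frame_rotation(frame)
  x <- x %*% t(P)
  structure(x, elements = t$elements, frame = frame, class = "primed_coords")
}

#' @export
print.primed_coords <- function(x, ...) {
  cat(sprintf("<primed_coords> %d atoms, frame '%s'\n",
              nrow(x), attr(x, "frame")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

# Signed dihedral of the ordered atom quadruple p1-p2-p3-p4, right-hand
# convention, cis (p4 eclipsing p1) = 0.
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (norm3(n1) < 1e-10 || norm3(n2) < 1e-10) {
    stop("degenerate geometry: collinear atoms in dihedral measurement")
  }
  m1 <- cross3(b2 / norm3(b2), n1)
  atan2(sum(m1 * n2), sum(n1 * n2))
}

angle_at <- function(vertex, p, q) {
  v1 <- p - vertex; v2 <- q - vertex
  n1 <- norm3(v1); n2 <- norm3(v2)
  if (n1 < 1e-12 || n2 < 1e-12) stop("degenerate geometry: coincident atoms")
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2))))
}

#' Measure internal coordinates from Cartesian coordinates
#'
#' Exact inverse of [build_cartesian()] on its image: bond lengths are
#' Euclidean distances, bond angles are measured at the bond-reference vertex
#' and dihedrals with the same right-hand convention the builder uses. The
#' coordinates need not be gauged; the measurement is invariant under rigid
#' motions.
#'
#' @param topology a valid \code{"zmat_topology"}.
#' @param coords an N x 3 coordinate matrix (e.g. a \code{"primed_coords"}).
#' @return an \code{"internal_coords"}.
#' @export
measure_internals <- function(topology, coords) {
  t <- topology
  x <- unclass(coords)
  n <- t$n
  stopifnot(nrow(x) == n)
  b <- numeric(0); th <- numeric(0); ph <- numeric(0)
  if (n >= 2) {
    b <- vapply(2:n, function(k) {
      d <- norm3(x[k, ] - x[t$bond_ref[k], ])
      if (d < 1e-12) {
        stop(sprintf("degenerate geometry: atoms %d and %d coincide",
                     k, t$bond_ref[k]))
      }
      d
    }, numeric(1))
  }
  if (n >= 3) {
    th <- vapply(3:n, function(k) {
      angle_at(x[t$bond_ref[k], ], x[t$angle_ref[k], ], x[k, ])
    }, numeric(1))
  }
  if (n >= 4) {
    ph <- vapply(4:n, function(k) {
      torsion_angle(x[t$dihedral_ref[k], ], x[t$angle_ref[k], ],
                    x[t$bond_ref[k], ], x[k, ])
    }, numeric(1))
  }
  internal_coords(b, th, ph)
}

#' Write coordinates to an XYZ file
#'
#' Standard XYZ: atom count line, comment line, then one
#' \code{element x y z} row per atom.
#'
#' @param coords a \code{"primed_coords"} or N x 3 matrix.
#' @param path output file path.
#' @param comment comment line content.
#' @param elements element labels; defaults to the \code{elements} attribute.
#' @return the path, invisibly.
#' @export
write_xyz <- function(coords, path, comment = "", elements = NULL) {
  x <- unclass(coords)
  if (is.null(elements)) elements <- attr(coords, "elements")
  if (is.null(elements)) elements <- rep("X", nrow(x))
  lines <- c(
    as.character(nrow(x)),
    comment,
    sprintf("%-3s %18.12f %18.12f %18.12f", elements, x[, 1], x[, 2], x[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}
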