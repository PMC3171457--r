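#' Z-matrix topology
#'
#' Builds a validated SASMIC-style Z-matrix topology. Each atom \code{k >= 2}
#' is positioned relative to previously placed atoms: a bond reference
#' \code{a(k) < k}, an angle reference (for \code{k >= 3}) and a dihedral
#' reference (for \code{k >= 4}). Dihedrals are declared \code{"principal"}
#' (rotation about the bond \code{a(k)}--angle-ref) or \code{"phase"}
#' (branch atoms positioned relative to the principal-dihedral atom, or to
#' atom 1 for atoms attached to atom 2).
#'
#' @param elements character vector of element labels, one per atom.
#' @param bond_ref integer vector, \code{bond_ref[k]} = a(k); \code{NA} for atom 1.
#' @param angle_ref integer vector; \code{NA} for atoms 1-2.
#' @param dihedral_ref integer vector; \code{NA} for atoms 1-3.
#' @param dihedral_kind character vector, \code{"principal"} or \code{"phase"}
#'   per atom \code{k >= 4}; \code{NA} otherwise.
#' @param validate if \code{TRUE} (default), stop on any invariant violation.
#' @return an object of class \code{"zmat_topology"}.
#' @seealso [validate_topology()], [chain_to_origin()], [build_cartesian()]
#' @export
zmatrix_topology <- function(elements, bond_ref, angle_ref = NULL,
                             dihedral_ref = NULL, dihedral_kind = NULL,
                             validate = TRUE) {
  n <- length(elements)
  stopifnot(n >= 1)
  pad <- function(x, default = NA) {
    if (is.null(x)) x <- rep(default, n)
    length(x) <- n
    x
  }
  topo <- structure(
    list(
      n = n,
      elements = as.character(elements),
      bond_ref = as.integer(pad(bond_ref)),
      angle_ref = as.integer(pad(angle_ref)),
      dihedral_ref = as.integer(pad(dihedral_ref)),
      dihedral_kind = as.character(pad(dihedral_kind))
    ),
    class = "zmat_topology"
  )
  if (validate) {
    rep_ <- validate_topology(topo)
    if (length(rep_) > 0L) {
      stop("invalid Z-matrix topology:\n  ", paste(rep_, collapse = "\n  "))
    }
  }
  topo
}

#' @export
print.zmat_topology <- function(x, ...) {
  cat(sprintf("<zmat_topology> %d atoms (%s)\n", x$n,
              paste(x$elements, collapse = " ")))
  invisible(x)
}

#' Validate a Z-matrix topology
#'
#' Checks the incremental-construction ordering, distinctness of references,
#' that the bond-reference map forms a tree rooted at atom 1, the
#' one-principal-dihedral-per-bond rule, and that any deviation from the
#' default references (angle ref \code{a(a(k))}, dihedral ref
#' \code{a(a(a(k)))}) matches one of the two recognised special-case patterns
#' (atoms attached to atom 2 using atom 3 as angle reference; branch-start
#' atoms whose phase dihedral references the principal-dihedral atom on the
#' same bond).
#'
#' Violations are returned as data, not raised: an empty character vector
#' means the topology is valid.
#'
#' @param topology a \code{"zmat_topology"} (possibly built with
#'   \code{validate = FALSE}).
#' @return character vector of violation messages (empty if valid).
#' @export
validate_topology <- function(topology) {
  t <- topology
  n <- t$n
  bad <- character(0)
  note <- function(...) bad <<- c(bad, sprintf(...))

  if (n >= 2) {
    for (k in 2:n) {
      refs <- c(t$bond_ref[k],
                if (k >= 3) t$angle_ref[k],
                if (k >= 4) t$dihedral_ref[k])
      if (anyNA(refs)) {
        note("missing reference at atom %d", k)
        next
      }
      if (any(refs >= k)) note("forward reference at atom %d", k)
      if (anyDuplicated(refs)) note("duplicated references at atom %d", k)
      if (any(refs < 1)) note("reference below 1 at atom %d", k)
    }
  }
  if (length(bad) > 0) return(bad)

  # bond refs form a tree rooted at 1 (guaranteed by a(k) < k, but check
  # termination defensively)
  if (n >= 2) {
    for (k in 2:n) {
      ch <- chain_to_origin(t, k)
      if (ch[length(ch)] != 1L || length(ch) > n) {
        note("chain from atom %d does not terminate at atom 1", k)
      }
    }
  }

  if (n >= 4) {
    for (k in 4:n) {
      kind <- t$dihedral_kind[k]
      if (is.na(kind) || !kind %in% c("principal", "phase")) {
        note("atom %d: dihedral kind must be 'principal' or 'phase'", k)
      }
    }
    # one principal dihedral per (unordered) bond
    pr <- which(!is.na(t$dihedral_kind) & t$dihedral_kind == "principal")
    if (length(pr) > 1) {
      keys <- vapply(pr, function(k) {
        paste(sort(c(t$bond_ref[k], t$angle_ref[k])), collapse = "-")
      }, character(1))
      dup <- unique(keys[duplicated(keys)])
      for (d in dup) note("more than one principal dihedral over bond (%s)", d)
    }

    # reference deviations must match a recognised special-case pattern
    for (k in 4:n) {
      a1 <- t$bond_ref[k]
      default_angle <- if (a1 >= 2) t$bond_ref[a1] else NA_integer_
      fig4a <- a1 == 2L && t$angle_ref[k] == 3L && t$dihedral_ref[k] == 1L &&
        identical(t$dihedral_kind[k], "phase") && n >= 3
      if (!fig4a && !identical(t$angle_ref[k], default_angle)) {
        note("atom %d: angle reference %d deviates from default %s without a special-case pattern",
             k, t$angle_ref[k], default_angle)
        next
      }
      if (fig4a) next
      dref <- t$dihedral_ref[k]
      a2 <- t$angle_ref[k]
      default_dih <- if (a2 >= 2) t$bond_ref[a2] else NA_integer_
      if (identical(t$dihedral_kind[k], "principal")) {
        if (!identical(dref, default_dih)) {
          note("atom %d: principal dihedral reference %d is not the chain default %s",
               k, dref, default_dih)
        }
      } else {
        # phase: either the chain default, or the principal atom on the same
        # oriented bond (branch special case)
        fig4b <- dref >= 4 && identical(t$dihedral_kind[dref], "principal") &&
          t$bond_ref[dref] == a1 && t$angle_ref[dref] == a2
        if (!fig4b && !identical(dref, default_dih)) {
          note("atom %d: phase dihedral reference %d matches neither the chain default nor a principal atom on bond (%d,%d)",
               k, dref, a1, a2)
        }
      }
    }
    # atoms positioned by the atom-2/atom-3 special pattern sit at the start
    # of the molecule (terminal substituents of atom 2, typically hydrogens);
    # nothing may be positioned from them, or the rigid-rotation derivative
    # rules would not apply to the descendants
    for (k in 4:n) {
      if (t$bond_ref[k] == 2L && t$angle_ref[k] == 3L) {
        children <- which(t$bond_ref == k)
        for (j in children) {
          note("atom %d: bonded to atom %d, which is positioned by the atom-2 special-case pattern and must be terminal",
               j, k)
        }
      }
    }
  }
  bad
}

#' Positioning chain from an atom to the origin atom
#'
#' Returns \code{C(k) = c(k, a(k), a(a(k)), ..., 1)}, the sequence of bond
#' references linking atom \code{k} to atom 1. This chain governs which atoms
#' move when an internal coordinate changes.
#'
#' @param topology a \code{"zmat_topology"}.
#' @param k atom index in \code{1..N}.
#' @return integer vector, first element \code{k}, last element \code{1}.
#' @export
chain_to_origin <- function(topology, k) {
  n <- topology$n
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > n) {
    stop(sprintf("atom index %s out of range 1..%d", format(k), n))
  }
  k <- as.integer(k)
  chain <- k
  guard <- 0L
  while (k != 1L) {
    k <- topology$bond_ref[k]
    if (is.na(k)) stop("broken bond-reference chain")
    chain <- c(chain, k)
    guard <- guard + 1L
    if (guard > n) stop("bond-reference chain does not terminate")
  }
  chain
}

#' Detect special-case mover pairs
#'
#' Finds every pair (mover atom \code{beta}, coordinate owner \code{k}) in
#' which \code{beta}'s position depends on an internal coordinate of an atom
#' \code{k} that is not in \code{beta}'s chain to the origin:
#' \describe{
#'   \item{\code{fig4a_angle}}{atoms bonded to atom 2 that use atom 3 as angle
#'     reference; they rotate when the bond angle of atom 3 changes.}
#'   \item{\code{fig4b_dihedral}}{branch-start atoms whose phase dihedral
#'     references the atom defining the principal dihedral on the same bond;
#'     they rotate when that principal dihedral changes.}
#' }
#'
#' @param topology a valid \code{"zmat_topology"}.
#' @return a tibble with columns \code{mover}, \code{owner}, \code{case},
#'   ordered by (mover, owner).
#' @export
detect_special_cases <- function(topology) {
  t <- topology
  movers <- integer(0); owners <- integer(0); cases <- character(0)
  if (t$n >= 4) {
    for (k in 4:t$n) {
      if (t$bond_ref[k] == 2L && t$angle_ref[k] == 3L) {
        movers <- c(movers, k); owners <- c(owners, 3L)
        cases <- c(cases, "fig4a_angle")
      }
      dref <- t$dihedral_ref[k]
      if (identical(t$dihedral_kind[k], "phase") && dref >= 4 &&
          identical(t$dihedral_kind[dref], "principal") &&
          t$bond_ref[dref] == t$bond_ref[k] &&
          t$angle_ref[dref] == t$angle_ref[k]) {
        movers <- c(movers, k); owners <- c(owners, dref)
        cases <- c(cases, "fig4b_dihedral")
      }
    }
  }
  out <- tibble::tibble(mover = movers, owner = owners, case = cases)
  dplyr::arrange(out, .data$mover, .data$owner)
}

# ---- internal coordinates ---------------------------------------------------

#' Internal coordinates for a Z-matrix topology
#'
#' Bond lengths \code{b[k]} (atoms 2..N, length units), bond angles
#' \code{theta[k]} (atoms 3..N, radians, strictly inside (0, pi)) and
#' dihedral angles \code{phi[k]} (atoms 4..N, radians, wrapped to (-pi, pi]).
#' For \code{N >= 3} there are exactly \code{3N - 6} values.
#'
#' @param b numeric, named or in atom order 2..N.
#' @param theta numeric, atoms 3..N, radians.
#' @param phi numeric, atoms 4..N, radians.
#' @return an object of class \code{"internal_coords"}.
#' @export
internal_coords <- function(b, theta = numeric(0), phi = numeric(0)) {
  b <- as.numeric(b); theta <- as.numeric(theta); phi <- as.numeric(phi)
  n <- length(b) + 1L
  if (n >= 3 && length(theta) != n - 2L) {
    stop(sprintf("expected %d bond angles, got %d", n - 2L, length(theta)))
  }
  if (n >= 4 && length(phi) != n - 3L) {
    stop(sprintf("expected %d dihedrals, got %d", n - 3L, length(phi)))
  }
  if (any(b <= 0)) stop("bond lengths must be positive")
  if (length(theta) && any(theta <= 0 | theta >= pi)) {
    stop("bond angles must lie strictly inside (0, pi)")
  }
  phi <- wrap_angle(phi)
  names(b) <- if (n >= 2) paste0("b", 2:n) else character(0)
  names(theta) <- if (n >= 3) paste0("theta", 3:n) else character(0)
  names(phi) <- if (n >= 4) paste0("phi", 4:n) else character(0)
  structure(list(b = b, theta = theta, phi = phi, n = n),
            class = "internal_coords")
}

#' @export
print.internal_coords <- function(x, ...) {
  cat(sprintf("<internal_coords> N = %d (3N-6 = %d values)\n",
              x$n, length(x$b) + length(x$theta) + length(x$phi)))
  invisible(x)
}

#' Wrap angles to (-pi, pi]
#'
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi  # boundary maps to +pi
  y
}

#' Flatten internal coordinates to a named vector
#'
#' Canonical ordering: \code{b2..bN, theta3..thetaN, phi4..phiN}.
#'
#' @param ic an \code{"internal_coords"}.
#' @return named numeric vector of length \code{3N - 6} (for N >= 3).
#' @export
ic_to_vector <- function(ic) c(ic$b, ic$theta, ic$phi)

#' Rebuild internal coordinates from a named vector
#'
#' Inverse of [ic_to_vector()]; names are ignored, canonical ordering assumed.
#'
#' @param q numeric vector in canonical ordering.
#' @param n atom count.
#' @return an \code{"internal_coords"}.
#' @export
ic_from_vector <- function(q, n) {
  nb <- n - 1L; na_ <- max(n - 2L, 0L); nd <- max(n - 3L, 0L)
  stopifnot(length(q) == nb + na_ + nd)
  internal_coords(q[seq_len(nb)],
                  q[nb + seq_len(na_)],
                  q[nb + na_ + seq_len(nd)])
}

#' Names of all internal coordinates of a topology
#' @param topology a \code{"zmat_topology"}.
#' @return character vector in canonical ordering.
#' @export
coordinate_names <- function(topology) {
  n <- topology$n
  c(if (n >= 2) paste0("b", 2:n),
    if (n >= 3) paste0("theta", 3:n),
    if (n >= 4) paste0("phi", 4:n))
}

# Parse a coordinate name like "theta5" into list(type, atom).
parse_coordinate <- function(name) {
  m <- regmatches(name, regexec("^(b|theta|phi)([0-9]+)$", name))[[1]]
  if (length(m) != 3L) stop(sprintf("unrecognised coordinate name '%s'", name))
  list(type = m[2], atom = as.integer(m[3]))
}

# ---- coordinate split -------------------------------------------------------

#' Partition of internal coordinates into unconstrained and constrained sets
#'
#' The unconstrained coordinates u parameterize the constrained subspace; the
#' constrained coordinates d are set to the minimizers d* = f(u) of the
#' potential energy at fixed u. Both orderings are fixed and reproducible.
#'
#' @param unconstrained character vector of coordinate names (e.g.
#'   \code{"phi6"}).
#' @param constrained character vector of the remaining coordinate names.
#' @return an object of class \code{"coord_split"} with elements \code{u}
#'   (size M) and \code{d} (size L).
#' @export
coord_split <- function(unconstrained, constrained) {
  u <- as.character(unconstrained); d <- as.character(constrained)
  if (length(intersect(u, d)) > 0) {
    stop("unconstrained and constrained sets overlap: ",
         paste(intersect(u, d), collapse = ", "))
  }
  structure(list(u = u, d = d, M = length(u), L = length(d)),
            class = "coord_split")
}

#' Build a coordinate split from a topology and the unconstrained names
#'
#' All remaining internal coordinates (in canonical order) become constrained.
#'
#' @param topology a \code{"zmat_topology"}.
#' @param unconstrained character vector of unconstrained coordinate names.
#' @return a \code{"coord_split"}.
#' @export
split_for_topology <- function(topology, unconstrained) {
  all_names <- coordinate_names(topology)
  missing <- setdiff(unconstrained, all_names)
  if (length(missing)) {
    stop("unknown coordinate(s): ", paste(missing, collapse = ", "))
  }
  coord_split(unconstrained, setdiff(all_names, unconstrained))
}

#' @export
print.coord_split <- function(x, ...) {
  cat(sprintf("<coord_split> M = %d unconstrained, L = %d constrained\n",
              x$M, x$L))
  invisible(x)
}
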