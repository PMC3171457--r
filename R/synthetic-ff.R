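# Synthetic internal-coordinate force field. All terms are direct functions
# of the internals, so value, gradient and Hessian are closed-form:
#
#   V = sum_bonds  Kb/2 (b - b0(u))^2
#     + sum_angles Kth/2 (theta - th0(u))^2
#     + sum_{constrained dihedrals} Kph/2 wrap(phi - ph0(u))^2
#     + sum_{unconstrained dihedrals} Ku (1 + cos(3 phi))
#     + sum_{adjacent constrained pairs} c_dd sqrt(K_I K_J) z_I z_J
#
# with z_I the deviation from the (u-dependent) equilibrium value. The
# equilibrium values of constrained coordinates are coupled to the nearest
# unconstrained dihedral, e.g. b0(phi_u) = b00 + c_b cos(phi_u), so the
# constrained minimizers genuinely vary with u and the constraint Jacobian
# has the closed form J[I, i] = d e_I / d u_i (the minimizer sits exactly at
# the equilibrium values, for any positive-definite coupling).

#' Parameters of the synthetic internal-coordinate force field
#'
#' Force constants use thermochemical-kcal/mol-flavoured magnitudes: bonds
#' are the stiffest coordinates, angles intermediate, constrained dihedrals
#' softest, mirroring the stiffness ordering of real molecular force fields.
#' Coupling amplitudes perturb equilibrium bond lengths (\eqn{\AA}) and
#' angles (radians) as cosines of the nearest unconstrained dihedral.
#'
#' @param K_b bond force constant (energy/length^2), default 600.
#' @param K_theta angle force constant (energy/rad^2), default 100.
#' @param K_phi constrained-dihedral force constant (energy/rad^2), default 40.
#' @param K_u unconstrained-dihedral barrier coefficient, default 1.5.
#' @param c_b equilibrium bond-length coupling amplitude, default 0.02.
#' @param c_theta equilibrium bond-angle coupling amplitude (rad), default 0.03.
#' @param c_phi equilibrium dihedral coupling amplitude (rad), default 0.05.
#' @param c_dd adjacent constrained-constrained coupling fraction, default
#'   0.15; validated to keep \code{H_dd} positive definite.
#' @return a list of class \code{"synthetic_ff_params"}.
#' @export
synthetic_ff_params <- function(K_b = 600, K_theta = 100, K_phi = 40,
                                K_u = 1.5, c_b = 0.02, c_theta = 0.03,
                                c_phi = 0.05, c_dd = 0.15) {
  stopifnot(K_b > 0, K_theta > 0, K_phi > 0, abs(c_dd) < 0.5)
  structure(list(K_b = K_b, K_theta = K_theta, K_phi = K_phi, K_u = K_u,
                 c_b = c_b, c_theta = c_theta, c_phi = c_phi, c_dd = c_dd),
            class = "synthetic_ff_params")
}

# graph distance between atoms along the bond tree
tree_distance <- function(topology, i, j) {
  ci <- chain_to_origin(topology, i)
  cj <- chain_to_origin(topology, j)
  common <- intersect(ci, cj)[1]  # deepest common ancestor (chains are sorted root-last)
  (match(common, ci) - 1L) + (match(common, cj) - 1L)
}

# For each constrained coordinate, the unconstrained dihedral it couples to:
# nearest owner atom in the bond tree, ties broken by smaller atom index.
coupling_partners <- function(topology, split) {
  u_atoms <- vapply(split$u, function(q) parse_coordinate(q)$atom, integer(1))
  vapply(split$d, function(q) {
    k <- parse_coordinate(q)$atom
    dists <- vapply(u_atoms, function(a) tree_distance(topology, k, a), numeric(1))
    which.min(dists)  # which.min breaks ties by first = smallest index
  }, integer(1))
}

#' Synthetic force field over a topology's internal coordinates
#'
#' Builds an analytic \code{"potential_model"} whose constrained minimizers
#' are the (u-dependent) equilibrium values; the reference internals supply
#' the base equilibrium values (at coupling phase zero).
#'
#' @param topology a valid \code{"zmat_topology"}.
#' @param internals reference \code{"internal_coords"} providing base
#'   equilibrium values.
#' @param split the \code{"coord_split"}; unconstrained entries must be
#'   dihedrals.
#' @param params a \code{"synthetic_ff_params"}.
#' @return a \code{"potential_model"} with attributes \code{eq_fun(u)} (the
#'   closed-form equilibrium values of the constrained coordinates) and
#'   \code{eq_jac(u)} (their analytic derivative, the expected constraint
#'   Jacobian).
#' @export
synthetic_ff <- function(topology, internals, split,
                         params = synthetic_ff_params()) {
  p <- params
  coords <- coordinate_names(topology)
  stopifnot(setequal(c(split$u, split$d), coords))
  if (!all(grepl("^phi", split$u))) {
    stop("unconstrained coordinates must be dihedral angles")
  }
  q0 <- ic_to_vector(internals)

  d_names <- split$d
  L <- split$L; M <- split$M
  type_d <- vapply(d_names, function(q) parse_coordinate(q)$type, character(1))
  K_I <- unname(c(b = p$K_b, theta = p$K_theta, phi = p$K_phi)[type_d])
  amp_I <- unname(c(b = p$c_b, theta = p$c_theta, phi = p$c_phi)[type_d])
  partner <- coupling_partners(topology, split)  # index into split$u
  base <- unname(q0[d_names])

  # equilibrium values and their u-derivative (closed form)
  eq_fun <- function(u) base + amp_I * (cos(u[partner]) - cos(q0[split$u][partner]))
  eq_jac <- function(u) {
    J <- matrix(0, L, M, dimnames = list(d_names, split$u))
    for (I in seq_len(L)) J[I, partner[I]] <- -amp_I[I] * sin(u[partner[I]])
    J
  }

  # constant d-d coupling matrix: adjacent owner atoms
  C_dd <- matrix(0, L, L)
  if (p$c_dd != 0 && L > 1) {
    atoms_d <- vapply(d_names, function(q) parse_coordinate(q)$atom, integer(1))
    for (I in 1:(L - 1)) for (Jx in (I + 1):L) {
      ai <- atoms_d[I]; aj <- atoms_d[Jx]
      adjacent <- ai == aj || topology$bond_ref[ai] == aj ||
        topology$bond_ref[aj] == ai
      if (adjacent) {
        C_dd[I, Jx] <- C_dd[Jx, I] <- p$c_dd * sqrt(K_I[I] * K_I[Jx])
      }
    }
  }
  H_dd_const <- diag(K_I, L) + C_dd
  ev <- eigen(H_dd_const, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("force-field parameters make H_dd indefinite (min eigenvalue %.3e); reduce c_dd",
                 min(ev)))
  }

  # deviation vector z and helpers; dihedral deviations wrapped to (-pi, pi]
  deviation <- function(q) {
    u <- q[split$u]
    z <- q[d_names] - eq_fun(u)
    z[type_d == "phi"] <- wrap_angle(z[type_d == "phi"])
    unname(z)
  }

  value <- function(q) {
    z <- deviation(q)
    u <- unname(q[split$u])
    0.5 * sum(K_I * z^2) + 0.5 * sum(z * (C_dd %*% z)) +
      p$K_u * sum(1 + cos(3 * u))
  }
  gradient <- function(q) {
    z <- deviation(q)
    u <- unname(q[split$u])
    g_d <- K_I * z + as.numeric(C_dd %*% z)           # dV/dd
    E <- eq_jac(u)                                     # dz/du = -E
    g_u <- -as.numeric(crossprod(E, g_d)) - 3 * p$K_u * sin(3 * u)
    g <- stats::setNames(numeric(length(q)), names(q))
    g[d_names] <- g_d
    g[split$u] <- g_u
    unname(g[coords])
  }
  hessian <- function(q) {
    z <- deviation(q)
    u <- unname(q[split$u])
    E <- eq_jac(u)                                    # L x M
    Kz <- H_dd_const                                  # d2V/dd2
    H_du <- -Kz %*% E                                 # d2V/dd du
    g_d <- K_I * z + as.numeric(C_dd %*% z)
    # d2 e_I / du^2 is diagonal in the partner coordinate
    H_uu <- crossprod(E, Kz %*% E) - 9 * p$K_u * diag(cos(3 * u), M)
    for (I in seq_len(L)) {
      ii <- partner[I]
      H_uu[ii, ii] <- H_uu[ii, ii] + g_d[I] * amp_I[I] * cos(u[ii])
    }
    H <- matrix(0, length(coords), length(coords),
                dimnames = list(coords, coords))
    H[d_names, d_names] <- Kz
    H[d_names, split$u] <- H_du
    H[split$u, d_names] <- t(H_du)
    H[split$u, split$u] <- H_uu
    unname(H)
  }

  model <- potential_model(value, gradient, hessian,
                           coords = coords, split = split)
  attr(model, "eq_fun") <- eq_fun
  attr(model, "eq_jac") <- eq_jac
  attr(model, "params") <- p
  model
}
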