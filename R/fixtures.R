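# Bundled molecule fixtures. Topologies and reference geometries are
# chemically plausible stand-ins built in code (no claim to match any
# force-field-minimized structure): a methanol-like 6-atom molecule, an
# N-methyl-acetamide-like 12-atom molecule and a tri-glycine-like 26-atom
# peptide chain. In each, the unconstrained set is exactly the principal
# dihedrals describing rotation around single bonds; every other internal
# coordinate (bond lengths, bond angles, phase dihedrals and principal
# dihedrals over non-single bonds) is flexibly constrained.

deg <- function(x) x * pi / 180

#' Bundled molecule fixtures
#'
#' \describe{
#'   \item{methanol_like}{6 atoms; 1 unconstrained dihedral (hydroxyl
#'     rotation about the C-O bond); the two methyl hydrogens attached to
#'     atom 2 with angle reference 3 exercise the first special-case
#'     pattern.}
#'   \item{nma_like}{12 atoms; 3 unconstrained dihedrals (two methyl
#'     rotations and the central backbone rotation); branch-start atoms
#'     phased on principal dihedrals exercise the second special-case
#'     pattern.}
#'   \item{gly3_like}{26 atoms; 6 unconstrained backbone dihedrals over
#'     single bonds; peptide-like principal dihedrals over non-single bonds
#'     remain constrained.}
#' }
#'
#' @param name one of \code{"methanol_like"}, \code{"nma_like"},
#'   \code{"gly3_like"}.
#' @param ff_params a \code{"synthetic_ff_params"} used when building the
#'   fixture's force field.
#' @return list with elements \code{topology}, \code{internals},
#'   \code{split}, \code{ff_params} and \code{model} (the synthetic force
#'   field over the fixture).
#' @export
fixture_molecule <- function(name = c("methanol_like", "nma_like", "gly3_like"),
                             ff_params = synthetic_ff_params()) {
  name <- match.arg(name)
  fx <- switch(name,
    methanol_like = fixture_methanol_like(),
    nma_like = fixture_nma_like(),
    gly3_like = fixture_gly3_like()
  )
  fx$ff_params <- ff_params
  fx$model <- synthetic_ff(fx$topology, fx$internals, fx$split, ff_params)
  fx$name <- name
  fx
}

fixture_methanol_like <- function() {
  # 1 H(methyl), 2 C, 3 O, 4-5 H(methyl), 6 H(hydroxyl)
  topo <- zmatrix_topology(
    elements = c("H", "C", "O", "H", "H", "H"),
    bond_ref = c(NA, 1, 2, 2, 2, 3),
    angle_ref = c(NA, NA, 1, 3, 3, 2),
    dihedral_ref = c(NA, NA, NA, 1, 1, 1),
    dihedral_kind = c(NA, NA, NA, "phase", "phase", "principal")
  )
  ic <- internal_coords(
    b = c(1.09, 1.42, 1.09, 1.09, 0.96),
    theta = deg(c(109.5, 109.4, 109.4, 108.5)),
    phi = deg(c(120, -120, 180))
  )
  list(topology = topo, internals = ic,
       split = split_for_topology(topo, "phi6"))
}

fixture_nma_like <- function() {
  # 1 H, 2 C(methyl), 3 C(carbonyl), 4 N, 5 O, 6 C(N-methyl), 7 H(N),
  # 8-10 H(methyl on 6), 11-12 H(methyl on 2)
  topo <- zmatrix_topology(
    elements = c("H", "C", "C", "N", "O", "C", "H", "H", "H", "H", "H", "H"),
    bond_ref = c(NA, 1, 2, 3, 3, 4, 4, 6, 6, 6, 2, 2),
    angle_ref = c(NA, NA, 1, 2, 2, 3, 3, 4, 4, 4, 3, 3),
    dihedral_ref = c(NA, NA, NA, 1, 4, 2, 6, 3, 8, 8, 1, 1),
    dihedral_kind = c(NA, NA, NA, "principal", "phase", "principal", "phase",
                      "principal", "phase", "phase", "phase", "phase")
  )
  ic <- internal_coords(
    b = c(1.09, 1.52, 1.35, 1.23, 1.45, 1.01, 1.09, 1.09, 1.09, 1.09, 1.09),
    theta = deg(c(109.5, 115, 121, 122, 119, 110, 110, 110, 110, 110)),
    phi = deg(c(180, 180, 180, 180, 60, 120, -120, 120, -120))
  )
  list(topology = topo, internals = ic,
       split = split_for_topology(topo, c("phi4", "phi6", "phi8")))
}

fixture_gly3_like <- function() {
  # acetyl-(gly)3-like chain: backbone heavy atoms with amide hydrogens,
  # carbonyl oxygens and methyl/alpha hydrogens. Principal dihedrals over
  # backbone single bonds (phi4, phi8, phi11, phi15, phi18, phi22) are
  # unconstrained; peptide-bond principals (phi6, phi13, phi20) stay
  # constrained.
  el <- c("H", "C", "C", "N", "O", "C", "H", "C", "H", "H",
          "N", "O", "C", "H", "C", "H", "H", "N", "O", "C",
          "H", "C", "H", "H", "H", "H")
  bond_ref    <- c(NA, 1, 2, 3, 3, 4, 4, 6, 6, 6,
                   8, 8, 11, 11, 13, 13, 13, 15, 15, 18,
                   18, 20, 20, 20, 2, 2)
  angle_ref   <- c(NA, NA, 1, 2, 2, 3, 3, 4, 4, 4,
                   6, 6, 8, 8, 11, 11, 11, 13, 13, 15,
                   15, 18, 18, 18, 3, 3)
  dihedral_ref <- c(NA, NA, NA, 1, 4, 2, 6, 3, 8, 8,
                    4, 11, 6, 13, 8, 15, 15, 11, 18, 13,
                    20, 15, 22, 22, 1, 1)
  kind <- c(NA, NA, NA, "principal", "phase", "principal", "phase",
            "principal", "phase", "phase",
            "principal", "phase", "principal", "phase",
            "principal", "phase", "phase",
            "principal", "phase", "principal",
            "phase", "principal", "phase", "phase", "phase", "phase")
  topo <- zmatrix_topology(el, bond_ref, angle_ref, dihedral_ref, kind)
  n <- topo$n
  b <- numeric(n - 1); th <- numeric(n - 2); ph <- numeric(n - 3)
  for (k in 2:n) {
    pair <- paste(sort(c(el[k], el[topo$bond_ref[k]])), collapse = "-")
    b[k - 1] <- switch(pair, "C-H" = 1.09, "C-C" = 1.52, "C-N" = 1.40,
                       "C-O" = 1.23, "H-N" = 1.01, 1.45)
  }
  for (k in 3:n) th[k - 2] <- deg(if (el[k] == "O") 121 else 112)
  phs <- c(`4` = 170, `5` = 180, `6` = 175, `7` = 180, `8` = -60, `9` = 120,
           `10` = -120, `11` = 150, `12` = 180, `13` = 178, `14` = 180,
           `15` = -70, `16` = 120, `17` = -120, `18` = 140, `19` = 180,
           `20` = -179, `21` = 180, `22` = -80, `23` = 120, `24` = -120,
           `25` = 120, `26` = -120)
  for (k in 4:n) ph[k - 3] <- deg(phs[[as.character(k)]])
  ic <- internal_coords(b, th, ph)
  un <- c("phi4", "phi8", "phi11", "phi15", "phi18", "phi22")
  list(topology = topo, internals = ic,
       split = split_for_topology(topo, un))
}

# ---- random molecules (for oracle sweeps) -----------------------------------

#' Random valid Z-matrix and internal coordinates
#'
#' Generates a random SASMIC-conforming topology of \code{n} atoms (random
#' bond references, chain-default angle/dihedral references, special-case
#' patterns where an atom attaches to atom 2 or joins an already-principal
#' bond) and random internals with bond lengths in [0.8, 1.8], angles in
#' [40, 140] degrees, dihedrals in (-180, 180].
#'
#' @param n atom count (>= 3).
#' @return list with \code{topology} and \code{internals}; uses the current
#'   RNG state (set a seed for reproducibility).
#' @export
random_zmatrix <- function(n) {
  stopifnot(n >= 3)
  bond_ref <- c(NA, 1L, 2L, rep(NA_integer_, max(0, n - 3)))
  angle_ref <- c(NA, NA, 1L, rep(NA_integer_, max(0, n - 3)))
  dihedral_ref <- rep(NA_integer_, n)
  kind <- rep(NA_character_, n)
  principal_on <- character(0)  # unordered bond keys already carrying a principal

  fig4a_atoms <- integer(0)  # terminal by construction; cannot be bonded to
  if (n >= 4) {
    for (k in 4:n) {
      candidates <- setdiff(2:(k - 1), fig4a_atoms)
      a1 <- if (length(candidates) == 1) candidates else sample(candidates, 1)
      bond_ref[k] <- a1
      if (a1 == 2L) {
        # attach to atom 2: angle ref 3, phase dihedral on atom 1
        angle_ref[k] <- 3L; dihedral_ref[k] <- 1L; kind[k] <- "phase"
        fig4a_atoms <- c(fig4a_atoms, k)
        next
      }
      a2 <- bond_ref[a1]
      angle_ref[k] <- a2
      key <- paste(sort(c(a1, a2)), collapse = "-")
      owner <- which(!is.na(kind) & kind == "principal" &
                       bond_ref == a1 & angle_ref == a2)
      if (!(key %in% principal_on)) {
        kind[k] <- "principal"
        dihedral_ref[k] <- bond_ref[a2]
        principal_on <- c(principal_on, key)
      } else if (length(owner) > 0) {
        kind[k] <- "phase"
        dihedral_ref[k] <- owner[1]
      } else {
        # principal sits on the reversed orientation; use the chain default
        kind[k] <- "phase"
        dihedral_ref[k] <- bond_ref[a2]
      }
    }
  }
  topo <- zmatrix_topology(rep("C", n), bond_ref, angle_ref, dihedral_ref, kind)
  ic <- internal_coords(
    b = stats::runif(n - 1, 0.8, 1.8),
    theta = stats::runif(n - 2, deg(40), deg(140)),
    phi = if (n >= 4) stats::runif(n - 3, -pi, pi) else numeric(0)
  )
  list(topology = topo, internals = ic)
}

# ---- conformation scans -----------------------------------------------------

#' Generate unconstrained-coordinate conformations
#'
#' Grid mode enumerates the Cartesian product of per-coordinate sequences
#' \code{seq(from, to, by)} (degrees), lexicographically with the first
#' coordinate varying slowest. Random mode draws seeded uniform samples over
#' per-coordinate ranges; the sequence is identical across runs for a fixed
#' seed.
#'
#' @param split a \code{"coord_split"} naming the unconstrained coordinates.
#' @param grid named list of \code{c(from, to, by)} triplets in degrees, one
#'   per unconstrained coordinate (grid mode).
#' @param n_samples number of random conformations (random mode).
#' @param seed RNG seed (random mode).
#' @param ranges named list of \code{c(min, max)} in degrees for random mode;
#'   defaults to (-180, 180] for every coordinate.
#' @return tibble with one column per unconstrained coordinate (radians) and
#'   one row per conformation.
#' @export
scan_generator <- function(split, grid = NULL, n_samples = NULL, seed = NULL,
                           ranges = NULL) {
  if (!is.null(grid)) {
    missing <- setdiff(split$u, names(grid))
    if (length(missing)) stop("grid missing coordinates: ",
                              paste(missing, collapse = ", "))
    seqs <- lapply(split$u, function(nm) {
      g <- grid[[nm]]
      if (length(g) != 3 || g[3] <= 0 || g[2] < g[1]) {
        stop(sprintf("bad grid spec for %s", nm))
      }
      deg(seq(g[1], g[2], by = g[3]))
    })
    names(seqs) <- split$u
    out <- rev(expand.grid(rev(seqs), KEEP.OUT.ATTRS = FALSE))
    if (nrow(out) == 0) stop("empty grid")
    return(tibble::as_tibble(out))
  }
  if (is.null(n_samples) || is.null(seed)) {
    stop("provide either a grid or (n_samples, seed)")
  }
  if (is.null(ranges)) {
    ranges <- stats::setNames(rep(list(c(-180, 180)), split$M), split$u)
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    code
  }
  withr_seed({
    cols <- lapply(split$u, function(nm) {
      r <- ranges[[nm]]
      deg(stats::runif(n_samples, r[1], r[2]))
    })
    names(cols) <- split$u
    tibble::as_tibble(cols)
  })
}
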