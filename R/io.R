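# Z-matrix text format (Gaussian-dialect rows, degrees and Angstrom), plus a
# trailing annotation section declaring the unconstrained coordinates and
# per-dihedral kinds:
#
#   # comment
#   H
#   C 1 1.090
#   O 2 1.420 1 109.5
#   H 2 1.090 3 109.4 1  120.0 phase
#   H 2 1.090 3 109.4 1 -120.0 phase
#   H 3 0.960 2 108.5 1  180.0 principal
#
#   unconstrained: phi6
#
# Dihedral kinds may be given per row (7th field) or in the annotation
# section as lines "dihedral_kind: <atom> <principal|phase>".

#' Read a Z-matrix file
#'
#' Parses the topology, internal coordinates (degrees converted to radians at
#' this boundary) and the unconstrained/constrained split annotation, then
#' validates everything. Parse and validation errors carry line numbers.
#'
#' @param path file path.
#' @return list with \code{topology}, \code{internals}, \code{split}.
#' @export
read_zmatrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", raw)
  nonblank <- which(trimws(stripped) != "")
  is_annot <- grepl(":", stripped, fixed = TRUE)

  atom_lines <- nonblank[!is_annot[nonblank]]
  annot_lines <- nonblank[is_annot[nonblank]]
  if (length(atom_lines) == 0) stop("no atom rows found in ", path)

  n <- length(atom_lines)
  el <- character(n)
  bond_ref <- rep(NA_integer_, n); angle_ref <- rep(NA_integer_, n)
  dihedral_ref <- rep(NA_integer_, n); kind <- rep(NA_character_, n)
  b <- numeric(0); th <- numeric(0); ph <- numeric(0)

  for (k in seq_len(n)) {
    ln <- atom_lines[k]
    tok <- strsplit(trimws(stripped[ln]), "[[:space:]]+")[[1]]
    need <- if (k == 1) 1 else if (k == 2) 3 else if (k == 3) 5 else 7
    if (length(tok) < need) {
      stop(sprintf("line %d: atom %d needs %d fields, found %d",
                   ln, k, need, length(tok)))
    }
    el[k] <- tok[1]
    num <- function(j, what) {
      v <- suppressWarnings(as.numeric(tok[j]))
      if (is.na(v)) stop(sprintf("line %d: cannot parse %s '%s'", ln, what, tok[j]))
      v
    }
    if (k >= 2) {
      bond_ref[k] <- as.integer(num(2, "bond reference"))
      b <- c(b, num(3, "bond length"))
    }
    if (k >= 3) {
      angle_ref[k] <- as.integer(num(4, "angle reference"))
      th <- c(th, deg(num(5, "bond angle")))
    }
    if (k >= 4) {
      dihedral_ref[k] <- as.integer(num(6, "dihedral reference"))
      ph <- c(ph, deg(num(7, "dihedral angle")))
      if (length(tok) >= 8) {
        if (!tok[8] %in% c("principal", "phase")) {
          stop(sprintf("line %d: dihedral kind must be principal|phase, found '%s'",
                       ln, tok[8]))
        }
        kind[k] <- tok[8]
      }
    }
  }

  unconstrained <- character(0)
  for (ln in annot_lines) {
    parts <- strsplit(trimws(stripped[ln]), ":", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = ":"))
    if (key == "unconstrained") {
      unconstrained <- c(unconstrained,
                         strsplit(val, "[[:space:],]+")[[1]])
    } else if (key == "dihedral_kind") {
      kv <- strsplit(val, "[[:space:]]+")[[1]]
      if (length(kv) != 2) stop(sprintf("line %d: dihedral_kind needs '<atom> <kind>'", ln))
      kind[as.integer(kv[1])] <- kv[2]
    } else {
      stop(sprintf("line %d: unknown annotation '%s'", ln, key))
    }
  }
  if (length(unconstrained) == 0) {
    stop("missing 'unconstrained:' split annotation in ", path)
  }

  topo <- tryCatch(
    zmatrix_topology(el, bond_ref, angle_ref, dihedral_ref, kind),
    error = function(e) stop("validation failed for ", path, ": ",
                             conditionMessage(e))
  )
  ic <- tryCatch(
    internal_coords(b, th, ph),
    error = function(e) stop("invalid internal coordinates in ", path, ": ",
                             conditionMessage(e))
  )
  list(topology = topo, internals = ic,
       split = split_for_topology(topo, unconstrained))
}

#' Write a Z-matrix file
#'
#' Inverse of [read_zmatrix()]: angles are written in degrees.
#'
#' @param topology a \code{"zmat_topology"}.
#' @param internals an \code{"internal_coords"}.
#' @param split a \code{"coord_split"}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_zmatrix <- function(topology, internals, split, path) {
  t <- topology; ic <- internals
  n <- t$n
  lines <- character(n)
  for (k in seq_len(n)) {
    parts <- t$elements[k]
    if (k >= 2) parts <- c(parts, t$bond_ref[k],
                           sprintf("%.10f", ic$b[[paste0("b", k)]]))
    if (k >= 3) parts <- c(parts, t$angle_ref[k],
                           sprintf("%.10f", ic$theta[[paste0("theta", k)]] * 180 / pi))
    if (k >= 4) parts <- c(parts, t$dihedral_ref[k],
                           sprintf("%.10f", ic$phi[[paste0("phi", k)]] * 180 / pi),
                           t$dihedral_kind[k])
    lines[k] <- paste(parts, collapse = " ")
  }
  lines <- c(lines, "", paste("unconstrained:", paste(split$u, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Run configuration
#'
#' Assembles tolerances, step-size lists, frame convention, truncation and
#' seed settings, with flag-style overrides taking precedence over a YAML
#' config file, which takes precedence over the defaults.
#'
#' @param file optional YAML file path.
#' @param ... named overrides.
#' @return list of class \code{"run_config"}.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list(
    tol = 1e-10,
    max_iter = 500L,
    deltas_deg = 10^seq(-3, 1, length.out = 9),
    scheme = "forward",
    frame = "z-xz",
    truncate_decimals = NULL,
    seed = 1L,
    basin_hop_tol = 0.5
  )
  if (!is.null(file)) {
    fromfile <- yaml::read_yaml(file)
    cfg[names(fromfile)] <- fromfile
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  if (cfg$tol <= 0) stop("tolerance must be positive")
  if (any(cfg$deltas_deg <= 0) || anyDuplicated(cfg$deltas_deg)) {
    stop("delta values must be positive and unique")
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "\n")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}
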