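# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: graph traversal by breadth-first search, rotations
# by matrix exponential, derivatives by central finite differences of the
# Cartesian builder, minimizers by golden-section search.

# BFS path from atom k to atom 1 on the undirected bond graph; for a tree
# this is the unique path and must agree with chain_to_origin.
bfs_path_to_origin <- function(topology, k) {
  n <- topology$n
  adj <- vector("list", n)
  for (j in seq_len(n)[-1]) {
    a <- topology$bond_ref[j]
    adj[[j]] <- c(adj[[j]], a)
    adj[[a]] <- c(adj[[a]], j)
  }
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n); seen[k] <- TRUE
  queue <- k
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == 1L) break
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; prev[w] <- v; queue <- c(queue, w)
    }
  }
  path <- 1L
  while (path[1] != k) path <- c(prev[path[1]], path)
  path  # k, ..., 1
}

# rotation matrix about unit axis n by angle, via the matrix exponential of
# the skew generator (series evaluated by scaling and squaring through expm
# is unavailable; use eigen-free closed series on the skew matrix powers)
rotation_matrix_expm <- function(n, angle) {
  S <- matrix(c(0, -n[3], n[2],
                n[3], 0, -n[1],
                -n[2], n[1], 0), 3, 3, byrow = TRUE)
  A <- S * angle
  # converge the exponential series explicitly
  out <- diag(3); term <- diag(3)
  for (j in 1:60) {
    term <- term %*% A / j
    out <- out + term
    if (max(abs(term)) < 1e-18) break
  }
  out
}

# central FD of build_cartesian with respect to one internal coordinate
fd_cartesian <- function(topology, internals, q, h = 1e-6) {
  q0 <- ic_to_vector(internals)
  qp <- q0; qp[q] <- qp[q] + h
  qm <- q0; qm[q] <- qm[q] - h
  n <- topology$n
  (unclass(build_cartesian(topology, ic_from_vector(unname(qp), n))) -
     unclass(build_cartesian(topology, ic_from_vector(unname(qm), n)))) / (2 * h)
}

# Richardson-extrapolated central FD (cancels the Delta^2 truncation term)
richardson <- function(est, delta) (4 * est(delta / 2) - est(delta)) / 3

# golden-section minimizer of V over a single constrained coordinate at
# fixed u (independent of the package's Newton path)
golden_minimize_1d <- function(model, u, lower, upper) {
  stats::optimize(function(d) model$value(c(x = u, y = d)),
                  lower = lower, upper = upper, tol = 1e-12)$minimum
}

expect_max_abs <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}

norm3_test <- function(v) sqrt(sum(v * v))

deg_test <- function(x) x * pi / 180
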