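# Fixtures: the 2D toy model, the synthetic force field, the bundled
# molecules and the conformation-scan generators.

test_that("toy-model derivatives are internally consistent", {
  model <- toy2d_model()
  q <- c(x = 0.8, y = 1.05)
  H <- model$hessian(q)
  expect_identical(H[1, 2], H[2, 1])
  # analytic Hessian vs FD of the analytic gradient
  h <- 1e-5
  for (i in 1:2) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    fd <- (model$gradient(qp) - model$gradient(qm)) / (2 * h)
    expect_max_abs(fd, H[, i], 1e-7)
  }
  # gradient vs FD of the value
  for (i in 1:2) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    expect_equal((model$value(qp) - model$value(qm)) / (2 * h),
                 model$gradient(q)[i], tolerance = 1e-7)
  }
  # closed-form entries: H_yy = k + 12 q y^2, H_xy = 2 c x
  p <- toy2d_params()
  expect_equal(H[2, 2], p$k + 12 * p$q * q[["y"]]^2)
  expect_equal(H[1, 2], 2 * p$c * q[["x"]])
})

test_that("the toy stationarity equation holds at the minimizer", {
  model <- toy2d_model()
  p <- toy2d_params()
  for (x0 in c(-1.5, 0.2, 1.9)) {
    pt <- minimize_constrained(model, x0, 1)
    y <- unname(pt$d_star)
    # c x^2 + k (y - y0) + 4 q y^3 = 0
    expect_lt(abs(p$c * x0^2 + p$k * (y - p$y0) + 4 * p$q * y^3), 1e-9)
    # Jacobian assembled from the closed-form Hessian entries
    expect_equal(unname(pt$J[1, 1]),
                 -(2 * p$c * x0) / (p$k + 12 * p$q * y^2), tolerance = 1e-12)
  }
})

test_that("the distance observable has the 3-4-5 anchor and exact partials", {
  obs <- toy2d_observable()
  expect_equal(obs$value(3, 4), 5)
  expect_equal(obs$grad_u(3, 4), 0.6)
  expect_equal(obs$grad_d(3, 4), 0.8)
  h <- 1e-6
  expect_equal((obs$value(3 + h, 4) - obs$value(3 - h, 4)) / (2 * h),
               obs$grad_u(3, 4), tolerance = 1e-9)
  expect_equal((obs$value(3, 4 + h) - obs$value(3, 4 - h)) / (2 * h),
               obs$grad_d(3, 4), tolerance = 1e-9)
})

test_that("zero couplings give the hard-constraint limit J = 0", {
  fx <- fixture_molecule("methanol_like",
                         ff_params = synthetic_ff_params(c_b = 0, c_theta = 0,
                                                         c_phi = 0, c_dd = 0))
  q0 <- ic_to_vector(fx$internals)
  for (shift in c(0, 0.8, -1.2)) {
    pt <- minimize_constrained(fx$model, q0[fx$split$u] + shift, q0[fx$split$d])
    expect_true(all(pt$J == 0))
  }
})

test_that("a single harmonic bond recovers its equilibrium and stiffness", {
  # 3-atom system, constrain only b3; minimizer must sit at b0(phi-free) and
  # H_dd must equal the bond force constant
  topo <- zmatrix_topology(c("C", "C", "O"), c(NA, 1, 2), c(NA, NA, 1))
  ic <- internal_coords(b = c(1.5, 1.4), theta = 1.9)
  sp <- split_for_topology(topo, character(0))
  expect_identical(sp$L, 3L)
  # direct quadratic check through the engine instead: one bond coordinate
  K_b <- 600
  spb <- coord_split("u1", "d1")
  bond <- potential_model(
    value = function(q) 0.5 * K_b * (q[["d1"]] - 1.4)^2 + 0.1 * q[["u1"]]^2,
    gradient = function(q) c(0.2 * q[["u1"]], K_b * (q[["d1"]] - 1.4)),
    hessian = function(q) diag(c(0.2, K_b)),
    coords = c("u1", "d1"), split = spb
  )
  pt <- minimize_constrained(bond, 0.5, 1.0)
  expect_equal(unname(pt$d_star), 1.4, tolerance = 1e-12)
  expect_equal(unname(pt$H_dd[1, 1]), K_b)
})

test_that("engine Jacobian equals the closed-form coupling derivative", {
  fx <- fixture_molecule("methanol_like")
  q0 <- ic_to_vector(fx$internals)
  grid <- scan_generator(fx$split, grid = list(phi6 = c(-180, 180, 20)))
  expect_identical(nrow(grid), 19L)
  worst <- 0
  for (r in seq_len(nrow(grid))) {
    u <- as.numeric(grid[r, ])
    pt <- minimize_constrained(fx$model, u, q0[fx$split$d])
    Jexp <- attr(fx$model, "eq_jac")(u)
    worst <- max(worst, max(abs(pt$J - Jexp)))
  }
  expect_lt(worst, 1e-8)
})

test_that("minimizers trace the coupled equilibrium functions", {
  fx <- fixture_molecule("methanol_like")
  q0 <- ic_to_vector(fx$internals)
  for (shift in c(0.5, 1.7, -2.4)) {
    u <- unname(q0[fx$split$u]) + shift
    pt <- minimize_constrained(fx$model, u, q0[fx$split$d])
    expect_max_abs(as.numeric(pt$d_star), attr(fx$model, "eq_fun")(u), 1e-8)
  }
})

test_that("indefinite force-field parameterizations are rejected", {
  fx <- fixture_molecule("methanol_like")
  expect_error(
    synthetic_ff(fx$topology, fx$internals, fx$split,
                 synthetic_ff_params(c_dd = 0.49)),
    "indefinite")
})

test_that("fixture contracts: sizes, splits, validation, convergence", {
  fx <- fixture_molecule("methanol_like")
  expect_identical(fx$topology$n, 6L)
  expect_identical(fx$split$M + fx$split$L, 12L)
  expect_identical(fx$split$M, 1L)

  nma <- fixture_molecule("nma_like")
  expect_identical(nma$topology$n, 12L)
  expect_identical(nma$split$M, 3L)
  expect_length(validate_topology(nma$topology), 0)
  pr <- which(nma$topology$dihedral_kind == "principal")
  bonds <- vapply(pr, function(k) {
    paste(sort(c(nma$topology$bond_ref[k], nma$topology$angle_ref[k])),
          collapse = "-")
  }, character(1))
  expect_identical(anyDuplicated(bonds), 0L)

  gly <- fixture_molecule("gly3_like")
  expect_gte(gly$topology$n, 20L)
  expect_gte(gly$split$M, 4L)
  sc <- detect_special_cases(gly$topology)
  expect_true(all(c("fig4a_angle", "fig4b_dihedral") %in% sc$case))

  # seeded random starting conformations all converge to certified minima
  q0 <- ic_to_vector(gly$internals)
  set.seed(42)
  for (r in 1:25) {
    u <- stats::runif(gly$split$M, -pi, pi)
    pt <- minimize_constrained(gly$model, u, q0[gly$split$d])
    expect_lt(pt$grad_d_residual_norm, 1e-10)
    expect_gt(pt$min_eig_H_dd, 0)
  }
  expect_error(fixture_molecule("unknown"), "arg")
})

test_that("H_dd stays positive definite across scanned conformations", {
  for (nm in c("methanol_like", "nma_like", "gly3_like")) {
    fx <- fixture_molecule(nm)
    q0 <- ic_to_vector(fx$internals)
    confs <- scan_generator(fx$split, n_samples = 8, seed = 3)
    for (r in seq_len(nrow(confs))) {
      pt <- minimize_constrained(fx$model, as.numeric(confs[r, ]),
                                 q0[fx$split$d])
      expect_gt(pt$min_eig_H_dd, 0)
    }
  }
})

test_that("scan grids enumerate deterministically with exact counts", {
  fx <- fixture_molecule("methanol_like")
  g <- scan_generator(fx$split, grid = list(phi6 = c(-180, 180, 20)))
  expect_identical(nrow(g), 19L)
  expect_equal(g$phi6[1], -pi)
  expect_equal(g$phi6[19], pi)
  # step equal to the full range: endpoints only
  g2 <- scan_generator(fx$split, grid = list(phi6 = c(-180, 180, 360)))
  expect_identical(nrow(g2), 2L)
  # multi-coordinate grid: cardinality is the product, first coordinate slowest
  nma <- fixture_molecule("nma_like")
  g3 <- scan_generator(nma$split, grid = list(phi4 = c(0, 120, 60),
                                              phi6 = c(0, 90, 90),
                                              phi8 = c(0, 0, 10)))
  expect_identical(nrow(g3), 6L)
  expect_identical(g3$phi4, rep(deg_test(c(0, 60, 120)), each = 2))
  # seeded random mode reproduces exactly
  s1 <- scan_generator(nma$split, n_samples = 50, seed = 9)
  s2 <- scan_generator(nma$split, n_samples = 50, seed = 9)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 50L)
  expect_error(scan_generator(nma$split, grid = list(phi4 = c(0, -10, 5))),
               "bad grid|missing")
})
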