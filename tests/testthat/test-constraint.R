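# Constraint engine: minimization-defined constraints, the Hessian sub-block
# solve for the Jacobian, and the chain rules into observables and Cartesian
# coordinates.

quadratic_2d <- function() {
  # V = (2u^2 + 2ud + 3d^2)/2 ; closed-form minimizer d*(u) = -u/3
  K <- matrix(c(2, 1, 1, 3), 2, 2)
  quadratic_model(K, 1, 1)
}

test_that("closed-form quadratic minimum and Jacobian are recovered", {
  mod <- quadratic_2d()
  pt <- minimize_constrained(mod, 1, 0)
  expect_equal(unname(pt$d_star), -1 / 3, tolerance = 1e-12)
  expect_lt(pt$grad_d_residual_norm, 1e-10)
  expect_equal(unname(pt$J[1, 1]), -1 / 3, tolerance = 1e-12)
  # linear observable O = c * d composes through the chain rule
  obs <- observable(function(u, d) 5 * d,
                    function(u, d) 0,
                    function(u, d) 5)
  expect_equal(observable_total_derivative(obs, pt), 5 * (-1 / 3),
               tolerance = 1e-12)
})

test_that("quadratic models give exact, u-independent Jacobians", {
  set.seed(41)
  for (rep_i in 1:100) {
    M <- sample(1:3, 1); L <- sample(1:4, 1)
    A <- matrix(stats::rnorm((M + L)^2), M + L)
    K <- crossprod(A) + diag(M + L) * 0.3
    mod <- quadratic_model(K, M, L)
    di <- M + seq_len(L)
    Jref <- -solve(K[di, di], K[di, seq_len(M), drop = FALSE])
    u1 <- stats::rnorm(M); u2 <- stats::rnorm(M)
    p1 <- minimize_constrained(mod, u1, rep(0, L))
    p2 <- minimize_constrained(mod, u2, rep(1, L))
    expect_max_abs(p1$J, Jref, 1e-10)
    expect_max_abs(p1$J, p2$J, 1e-10)
  }
})

test_that("decoupled blocks give a zero Jacobian (hard-constraint limit)", {
  K <- diag(c(2, 5, 7))
  mod <- quadratic_model(K, 1, 2)
  pt <- minimize_constrained(mod, 0.8, c(0.3, -0.2))
  expect_true(all(pt$J == 0))
  # with J = 0 the observable derivative reduces to the plain u-partial
  obs <- observable(function(u, d) sin(u) + sum(d^2),
                    function(u, d) cos(u),
                    function(u, d) 2 * d)
  expect_equal(observable_total_derivative(obs, pt), cos(0.8))
})

test_that("saddle points and indefinite blocks are rejected", {
  sp <- coord_split("u1", "d1")
  # V = u^2 - d^2: stationary in d at d = 0 but a maximum
  mod <- potential_model(
    value = function(q) q[["u1"]]^2 - q[["d1"]]^2,
    gradient = function(q) c(2 * q[["u1"]], -2 * q[["d1"]]),
    hessian = function(q) diag(c(2, -2)),
    coords = c("u1", "d1"), split = sp
  )
  expect_error(minimize_constrained(mod, 0.5, 0), "not a minimum|regularize")
  expect_error(constrained_jacobian(list(H_dd = matrix(-2), H_du = matrix(1))),
               "not positive definite")
})

test_that("toy-system stationarity matches the golden-section oracle", {
  model <- toy2d_model()
  for (x0 in seq(-2, 2, length.out = 7)) {
    pt <- minimize_constrained(model, x0, 1)
    expect_lt(pt$grad_d_residual_norm, 1e-10)
    d_oracle <- golden_minimize_1d(model, x0, 0, 2)
    expect_equal(unname(pt$d_star), d_oracle, tolerance = 1e-7)
    expect_gt(pt$min_eig_H_dd, 0)
  }
})

test_that("minimization respects the warm-start basin in a double well", {
  sp <- coord_split("u1", "d1")
  dw <- potential_model(
    value = function(q) (q[["d1"]]^2 - 1)^2 + 0.3 * q[["u1"]] * q[["d1"]],
    gradient = function(q) c(0.3 * q[["d1"]],
                             4 * q[["d1"]] * (q[["d1"]]^2 - 1) + 0.3 * q[["u1"]]),
    hessian = function(q) matrix(c(0, 0.3, 0.3, 12 * q[["d1"]]^2 - 4), 2, 2),
    coords = c("u1", "d1"), split = sp
  )
  ptR <- minimize_constrained(dw, 0.1, 0.9)
  ptL <- minimize_constrained(dw, 0.1, -0.9)
  # dense-grid oracle for the two wells
  grid <- seq(-1.5, 1.5, by = 1e-4)
  vals <- vapply(grid, function(d) dw$value(c(u1 = 0.1, d1 = d)), numeric(1))
  right <- grid[grid > 0][which.min(vals[grid > 0])]
  left <- grid[grid < 0][which.min(vals[grid < 0])]
  expect_equal(unname(ptR$d_star), right, tolerance = 1e-3)
  expect_equal(unname(ptL$d_star), left, tolerance = 1e-3)
})

test_that("toy observable derivative matches FD of the restricted function", {
  model <- toy2d_model()
  obs <- toy2d_observable()
  for (x0 in c(-1.7, -0.4, 0.9, 1.8)) {
    pt <- minimize_constrained(model, x0, 1)
    exact <- observable_total_derivative(obs, pt)
    # (x + f f')/r assembly from the package's own pieces
    f <- unname(pt$d_star); fp <- unname(pt$J[1, 1])
    r <- sqrt(x0^2 + f^2)
    expect_equal(exact, (x0 + f * fp) / r, tolerance = 1e-12)
    fd <- richardson(function(dl) {
      fd_derivative(model, x0, 1, dl, scheme = "central",
                    what = "observable", observable = obs, base_point = pt)
    }, 1e-3)
    expect_equal(exact, fd, tolerance = 1e-6)
  }
})

test_that("Jacobian matches Richardson-extrapolated FD on the toy curve", {
  model <- toy2d_model()
  for (x0 in seq(-2, 2, length.out = 11)) {
    pt <- minimize_constrained(model, x0, 1)
    fd <- richardson(function(dl) {
      fd_derivative(model, x0, 1, dl, scheme = "central", base_point = pt)
    }, 1e-3)
    if (abs(pt$J[1, 1]) > 1e-12) {
      expect_equal(unname(pt$J[1, 1]), fd, tolerance = 1e-6)
    } else {
      expect_lt(abs(fd), 1e-9)
    }
  }
})

test_that("first-order prediction and constraint identity hold to O(eps^2)", {
  targets <- list(
    list(model = toy2d_model(), u = 0.9, d0 = 1),
    list(model = fixture_molecule("methanol_like")$model, u = NULL, d0 = NULL)
  )
  fx <- fixture_molecule("methanol_like")
  q0 <- ic_to_vector(fx$internals)
  targets[[2]]$u <- unname(q0[fx$split$u]) + 0.6
  targets[[2]]$d0 <- unname(q0[fx$split$d])
  for (tg in targets) {
    pt <- minimize_constrained(tg$model, tg$u, tg$d0)
    f0 <- as.numeric(pt$d_star)
    set.seed(5)
    w <- stats::rnorm(length(tg$u)); w <- w / sqrt(sum(w^2))
    eps <- 0.08
    resid <- numeric(5)
    for (j in 1:5) {
      e <- eps / 2^(j - 1)
      pt1 <- minimize_constrained(tg$model, tg$u + e * w, f0)
      resid[j] <- sqrt(sum((as.numeric(pt1$d_star) - f0 -
                              e * as.numeric(pt$J %*% w))^2))
      # residual of the stationarity condition at the predicted d is O(eps^2)
      d_pred <- f0 + e * as.numeric(pt$J %*% w)
      q <- stats::setNames(numeric(length(tg$model$coords)), tg$model$coords)
      q[tg$model$split$u] <- tg$u + e * w
      q[tg$model$split$d] <- d_pred
      g_d <- tg$model$gradient(q)[match(tg$model$split$d, tg$model$coords)]
      expect_lt(max(abs(g_d)), 10 * max(1, max(abs(pt$H_dd))) * e^2)
    }
    ratios <- resid[-5] / resid[-1]
    expect_true(all(ratios > 3.5 & ratios < 4.5))
  }
})

test_that("Hessian blocks extract exactly and fallback matches analytic", {
  K <- matrix(c(4, 1, 0.5, 1, 6, 0.2, 0.5, 0.2, 9), 3, 3)
  mod <- quadratic_model(K, 1, 2)
  bl <- hessian_blocks(mod, 0.3, c(0.1, -0.4))
  expect_equal(unname(bl$H_dd), K[2:3, 2:3])
  expect_equal(unname(bl$H_du), K[2:3, 1, drop = FALSE])

  # numeric-fallback Hessian (central FD of the analytic gradient) agrees
  fx <- fixture_molecule("methanol_like")
  m <- fx$model
  sp <- m$split
  fallback <- potential_model(m$value, m$gradient, hessian = NULL,
                              coords = m$coords, split = sp)
  expect_identical(fallback$derivative_mode, "numeric-fallback")
  q0 <- ic_to_vector(fx$internals)
  H1 <- hessian_blocks(m, q0[sp$u], q0[sp$d])
  H2 <- hessian_blocks(fallback, q0[sp$u], q0[sp$d])
  expect_max_abs(H1$H_dd, H2$H_dd, 1e-6 * max(abs(H1$H_dd)))
  expect_max_abs(H1$H_du, H2$H_du, 1e-6 * max(1, max(abs(H1$H_du))))
})

test_that("Cartesian derivatives along the constrained subspace pass the FD oracle", {
  fx <- fixture_molecule("methanol_like")
  q0 <- ic_to_vector(fx$internals)
  u <- unname(q0[fx$split$u]) + 0.9
  pt <- minimize_constrained(fx$model, u, q0[fx$split$d])
  q <- q0; q[fx$split$u] <- u; q[names(pt$d_star)] <- pt$d_star
  ic_min <- ic_from_vector(unname(q), fx$topology$n)
  geo <- geometric_jacobian(fx$topology, ic_min)
  dx <- euclidean_constrained_derivatives(fx$topology, fx$split, pt, geo)
  expect_true(all(dx[1, , ] == 0))
  fd <- richardson(function(dl) {
    fd_derivative(fx$model, u, 1, dl, scheme = "central", what = "euclidean",
                  topology = fx$topology, split = fx$split, base_point = pt)
  }, 1e-4)
  scale <- max(abs(fd))
  expect_lt(max(abs(fd - as.numeric(dx[, , 1]))), 1e-5 * scale)

  # stale-geometry guard
  geo_stale <- geometric_jacobian(fx$topology, fx$internals)
  expect_error(
    euclidean_constrained_derivatives(fx$topology, fx$split, pt, geo_stale),
    "stale geometry")
})

test_that("tidy and glance summarise a constrained point", {
  fx <- fixture_molecule("methanol_like")
  q0 <- ic_to_vector(fx$internals)
  pt <- minimize_constrained(fx$model, q0[fx$split$u], q0[fx$split$d])
  td <- tidy(pt)
  expect_identical(nrow(td), fx$split$L * fx$split$M)
  expect_identical(unique(td$unconstrained), fx$split$u)
  gl <- glance(pt)
  expect_identical(nrow(gl), 1L)
  expect_gt(gl$min_eig_H_dd, 0)
})
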