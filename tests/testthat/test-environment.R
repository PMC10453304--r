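p5 <- lorenz96_params(n_dims = 5, forcing = 8)

test_that("Lorenz-96 derivative matches direct substitution and symmetry", {
  # all-F equilibrium: (F - F) * F - F + F = 0 in every component
  expect_equal(lorenz96_derivative(rep(8, 5), p5), rep(0, 5))
  expect_equal(lorenz96_derivative(rep(-3, 7), lorenz96_params(7, -3)),
               rep(0, 7))

  # hand substitution for component 1: (x2 - x4) * x5 - x1 + F
  d <- lorenz96_derivative(c(1, 2, 3, 4, 5), p5)
  expect_equal(d[1], (2 - 4) * 5 - 1 + 8)
  # remaining components against the independent vectorised form
  expect_equal(d, l96_rhs(p5)(c(1, 2, 3, 4, 5)))

  # cyclic rotation of the state rotates the derivative the same way
  x <- c(0.3, -1.2, 4.5, 2.2, -0.7)
  rot <- function(v) v[c(2:5, 1)]
  expect_equal(lorenz96_derivative(rot(x), p5),
               rot(lorenz96_derivative(x, p5)))

  expect_error(lorenz96_derivative(1:4, p5), "length")
  expect_error(lorenz96_derivative(c(1, NA, 3, 4, 5), p5), "finite")
})

test_that("parameter validation rejects degenerate systems", {
  expect_error(lorenz96_params(3, 8), "n_dims")
  expect_error(lorenz96_params(5, Inf), "finite")
})

test_that("equilibrium is preserved and sample counting is exact", {
  tr <- lorenz96_simulate(p5, rep(8, 5), duration = 10, dt = 0.01)
  expect_equal(nrow(tr$values), 1000L)
  expect_lt(max(abs(tr$values - 8)), 1e-10)

  tr1 <- lorenz96_simulate(p5, rep(8, 5) + 0.1, duration = 1, dt = 0.01)
  expect_identical(dim(tr1$values), c(100L, 5L))
})

test_that("RK4 trajectory matches an independent adaptive integrator", {
  # chaos amplifies the O(dt^5) local error by e^(lambda t), so the
  # attainable agreement depends on both dt and the horizon: ~5e-3 at the
  # production step over one time unit, ~5e-4 over five time units at
  # dt = 0.002
  p <- lorenz96_params(5, 8.75)
  init <- random_initial_state(p, 7)
  times <- seq(0.01, 5, by = 0.01)
  ref <- ode_oracle(l96_rhs(p), init, times)
  tr <- lorenz96_simulate(p, init, duration = 5, dt = 0.01)
  expect_lt(max(abs(tr$values[1:100, ] - ref[1:100, ])), 1e-2)
  tr_fine <- lorenz96_simulate(p, init, duration = 5, dt = 0.002)
  expect_lt(max(abs(tr_fine$values[seq(5, 2500, by = 5), ] - ref)), 2e-3)
})

test_that("halving the step shows 4th-order convergence", {
  p <- lorenz96_params(5, 8.75)
  init <- random_initial_state(p, 3)
  ref <- ode_oracle(l96_rhs(p), init, 1)[1, ]
  err <- vapply(c(0.02, 0.01), function(h) {
    tr <- lorenz96_simulate(p, init, duration = 1, dt = h)
    max(abs(tr$values[nrow(tr$values), ] - ref))
  }, numeric(1))
  expect_gt(err[1] / err[2], 10)   # ~16x for an order-4 scheme
  expect_lt(err[1] / err[2], 25)
})

test_that("rotating the initial state rotates the whole trajectory", {
  p <- lorenz96_params(5, 9)
  x0 <- random_initial_state(p, 11)
  rot <- function(v) v[c(2:5, 1)]
  tr <- lorenz96_simulate(p, x0, duration = 1, dt = 0.01)
  tr_rot <- lorenz96_simulate(p, rot(x0), duration = 1, dt = 0.01)
  expect_lt(max(abs(tr_rot$values - tr$values[, c(2:5, 1)])), 1e-8)
})

test_that("simulation is seed-reproducible and flags divergence", {
  p <- lorenz96_params(5, 8.75)
  a <- lorenz96_simulate(p, random_initial_state(p, 5), 2, 0.01, washout = 1)
  b <- lorenz96_simulate(p, random_initial_state(p, 5), 2, 0.01, washout = 1)
  expect_identical(a$values, b$values)
  # absurd step size blows the integration up; the error names the step
  expect_error(lorenz96_simulate(p, random_initial_state(p, 5),
                                 duration = 50, dt = 1),
               "diverged.*step")
})

test_that("washout drops the transient before the record starts", {
  p <- lorenz96_params(5, 8.75)
  x0 <- random_initial_state(p, 2)
  whole <- lorenz96_simulate(p, x0, duration = 3, dt = 0.01)
  tail_only <- lorenz96_simulate(p, x0, duration = 1, dt = 0.01, washout = 2)
  expect_equal(tail_only$values, whole$values[201:300, ], tolerance = 1e-12)
  expect_equal(tail_only$t0, 2)
})

test_that("random initial states are seeded perturbations of equilibrium", {
  p <- lorenz96_params(5, 8.75)
  expect_identical(random_initial_state(p, 42), random_initial_state(p, 42))
  expect_false(all(random_initial_state(p, 1) == random_initial_state(p, 2)))
  for (s in 1:20) {
    x <- random_initial_state(p, s)
    expect_true(all(x >= 8.25 & x <= 9.25))
  }
})

test_that("rescale map sends the training range to [-1, 1] and inverts", {
  vals <- matrix(0, 10, 2)
  vals[, 1] <- c(2, 3, 6, 4, 5, 2.5, 3.7, 5.9, 4.4, 2.2)
  traj <- list(values = vals)
  m <- fit_rescale(traj, 1, c(1, 10))
  expect_equal(m$center, 4)
  expect_equal(m$half_range, 2)
  expect_equal(rescale_apply(m, c(2, 6, 4)), c(-1, 1, 0))
  # test-period values outside the training range extrapolate past [-1, 1]
  expect_gt(rescale_apply(m, 7), 1)
  x <- seq(-3, 9, length.out = 50)
  expect_lt(max(abs(rescale_invert(m, rescale_apply(m, x)) - x)), 1e-12)

  expect_error(fit_rescale(traj, 2, c(1, 10)), "degenerate")
  expect_error(fit_rescale(traj, 1, c(8, 4)), "interval")
})

test_that("trajectory CSV round-trips at full precision", {
  p <- lorenz96_params(5, 8.75)
  tr <- lorenz96_simulate(p, random_initial_state(p, 9), 1, 0.01)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "t,x1,x2,x3,x4,x5")
  back <- read_trajectory_csv(path)
  expect_equal(back$values, tr$values, ignore_attr = TRUE)
  expect_equal(back$t, tr$t0 + (1:100) * 0.01)
})
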