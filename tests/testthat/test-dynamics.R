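test_that("boundary projections give the four normal feet and distances", {
  g <- cell_geometry(40, 250, 3)
  p <- boundary_projections(c(0, 0), g)
  expect_equal(unname(p$distances), c(40, 40, 250, 250))
  p <- boundary_projections(c(10, -200), g)
  expect_equal(p$distances, c(L = 50, R = 30, U = 450, D = 50))
  expect_equal(unname(p$points["L", ]), c(-40, -200))
  expect_equal(boundary_projections(c(40, 0), g)$distances[["R"]], 0)
  expect_warning(boundary_projections(c(45, 0), g), "outside")
})

test_that("initial conditions honour their modes and seeds", {
  g <- cell_geometry(40, 200, 3)
  eq <- initial_conditions(g, "equally_spaced_axis")
  expect_equal(eq, cbind(c(0, 0, 0), c(-100, 0, 100)))
  r1 <- initial_conditions(g, "random", seed = 7)
  r2 <- initial_conditions(g, "random", seed = 7)
  expect_identical(r1, r2)
  expect_false(identical(r1, initial_conditions(g, "random", seed = 8)))
  expect_true(all(abs(r1[, 1]) <= 40 - 7 & abs(r1[, 2]) <= 200 - 7))
  X <- cbind(c(1, 2), c(3, 4))
  expect_identical(initial_conditions(g, "provided", positions = X), X)
})

test_that("net velocities obey symmetry and Newton-pair antisymmetry", {
  g <- cell_geometry(40, 250, 1)
  v <- net_velocities(matrix(0, 1, 2), m2_model(), g)
  expect_equal(v, matrix(0, 1, 2))
  # two nuclei 40 um apart, boundaries off: f(40) = 1, opposite directions
  g2 <- cell_geometry(40, 250, 2)
  v2 <- net_velocities(rbind(c(0, -20), c(0, 20)), interior_only_model(), g2)
  expect_equal(v2, rbind(c(0, -1), c(0, 1)))
  # three collinear equally spaced: middle nucleus force-free
  g3 <- cell_geometry(40, 250, 3)
  v3 <- net_velocities(rbind(c(0, -50), c(0, 0), c(0, 50)),
                       interior_only_model(), g3)
  expect_equal(v3[2, ], c(0, 0))
  expect_error(net_velocities(rbind(c(0, 0), c(0, 0)), m2_model(), g2),
               "coincident")
})

test_that("internuclear contributions conserve momentum", {
  # boundary magnitudes zero and all nuclei > r from walls: total force zero
  set.seed(42)
  g <- cell_geometry(40, 250, 8)
  for (model in list(interior_only_model(1, -1), interior_only_model(-1, 1),
                     interior_only_model(1, 0, cutoff = 50))) {
    X <- cbind(runif(8, -30, 30), runif(8, -200, 200))
    v <- net_velocities(X, model, g)
    expect_equal(colSums(v), c(0, 0), tolerance = 1e-10)
  }
})

test_that("relaxation centres a single nucleus and respects reflections", {
  g <- cell_geometry(40, 250, 1)
  eq <- relax_to_equilibrium(matrix(c(5, 10), 1, 2), m2_model(), g)
  expect_true(eq$converged)
  expect_lt(eq$max_residual, 1e-4)
  expect_equal(eq$final, matrix(0, 1, 2), tolerance = 0.5)
  # multi-start: same centre from elsewhere
  eq2 <- relax_to_equilibrium(matrix(c(-20, 100), 1, 2), m2_model(), g)
  expect_equal(eq2$final, eq$final, tolerance = 0.5)
  # x -> -x equivariance of the equilibrium
  g9 <- cell_geometry(25, 250, 9)
  X0 <- initial_conditions(g9, "random", seed = 5)
  Xr <- X0 * cbind(rep(-1, 9), rep(1, 9))
  e1 <- relax_to_equilibrium(X0, m2_model(), g9)
  e2 <- relax_to_equilibrium(Xr, m2_model(), g9)
  expect_true(e1$converged && e2$converged)
  expect_equal(e2$final, e1$final * cbind(rep(-1, 9), rep(1, 9)),
               tolerance = 0.05)
})

test_that("pure repulsion without boundary forces drives nuclei apart", {
  g <- cell_geometry(40, 250, 5)
  X0 <- initial_conditions(g, "random", seed = 2)
  spread <- function(X) max(dist(X))
  model <- interior_only_model()
  prev <- spread(X0)
  for (tm in c(2, 8, 30)) {
    eq <- relax_to_equilibrium(X0, model, g, tol = 1e-12, t_max = tm,
                               max_steps = 50000)
    expect_gte(spread(eq$final), prev - 1e-9)
    prev <- spread(eq$final)
  }
  expect_gt(prev, spread(X0))
})

test_that("relaxed equilibria agree with direct root-finding (small N)", {
  skip_if_not_installed("pracma")
  g <- cell_geometry(30, 60, 3)
  model <- m2_model()
  eq <- relax_to_equilibrium(initial_conditions(g, "random", seed = 11),
                             model, g, tol = 1e-6)
  expect_true(eq$converged)
  fun <- function(z) as.numeric(net_velocities(matrix(z, ncol = 2), model, g))
  root <- pracma::fsolve(fun, as.numeric(eq$final) * 1.02)$x
  expect_equal(as.numeric(eq$final), root, tolerance = 1e-4)
})

test_that("configuration CSV round-trips", {
  cfgs <- list(a = cbind(c(1, 2), c(3, 4)), b = cbind(0.5, -0.5))
  path <- tempfile(fileext = ".csv")
  write_configurations(cfgs, path)
  back <- read_configurations(path)
  expect_equal(back$a, cfgs$a)
  expect_equal(back$b, cfgs$b)
})
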