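test_that("strip force balance is odd with a fixed point at the centre", {
  m2 <- m2_model(2)
  expect_equal(strip_rhs(0, m2, 40, 60), 0)
  xs <- seq(-50, 50, by = 10)
  expect_equal(strip_rhs(xs, m2, 40, 60), -strip_rhs(-xs, m2, 40, 60))
  expect_equal(strip_rhs(20, m2, 40, 60), 0, tolerance = 1e-12)
  m1 <- m1_model(2)
  expect_equal(strip_rhs(0, m1, 30, 60), 0)
})

test_that("single-file stability thresholds match the two model families", {
  # family 2: SF stable iff b < r* lambda, r* = sqrt(M_S/2)
  m2 <- m2_model(2)
  expect_equal(sf_is_stable(m2, 40, 10)$r_star, 1)
  expect_true(sf_is_stable(m2, 40, 39)$stable)
  expect_false(sf_is_stable(m2, 40, 41)$stable)
  # family 1: lambda* = d_ref sqrt(2/M_S), width plays no role
  m1 <- m1_model(2)
  expect_equal(sf_is_stable(m1, 50, 10)$lambda_star, 40)
  for (b in c(10, 60, 200)) {
    expect_true(sf_is_stable(m1, 41, b)$stable)
    expect_false(sf_is_stable(m1, 39, b)$stable)
  }
  expect_error(sf_is_stable(model_spec(force_law(1, -1),
                                       force_law(1, -1, 2, cutoff = 30),
                                       force_law(1, -1)), 40, 60),
               "differentiable")
})

test_that("stability verdict agrees with the numeric slope of the strip ODE", {
  # general-exponent check against a finite-difference derivative at x = 0
  set.seed(21)
  for (aN in c(-1, 0, 1)) for (aS in c(-1, 0, 1)) for (sS in c(-1, 1)) {
    model <- model_spec(force_law(1, aN), force_law(sS, aS, 1.7),
                        force_law(1, -1))
    lambda <- runif(1, 25, 60); b <- runif(1, 15, 70)
    slope <- (strip_rhs(1e-5, model, lambda, b) -
                strip_rhs(-1e-5, model, lambda, b)) / 2e-5
    verdict <- sf_is_stable(model, lambda, b)$stable
    if (abs(slope) > 1e-8) expect_equal(verdict, slope < 0)
  }
})

test_that("pitchfork offsets match the worked values and the root oracle", {
  expect_equal(df_equilibrium(m1_model(2), 30, 60), sqrt(1600 - 900) / 2,
               tolerance = 1e-12)
  expect_equal(df_equilibrium(m2_model(2), 40, 60), 20, tolerance = 1e-12)
  # bifurcation point: offset vanishes continuously
  expect_equal(df_equilibrium(m1_model(2), 40, 60), 0)
  expect_equal(df_equilibrium(m2_model(2), 40, 40 - 1e-9), 0)
  # closed form vs numeric root across random parameter draws
  set.seed(7)
  for (k in 1:20) {
    MS <- runif(1, 0.5, 6)
    m1 <- m1_model(MS); m2 <- m2_model(MS)
    lam_star <- 40 * sqrt(2 / MS)
    lam <- runif(1, 0.3, 0.95) * lam_star
    b <- runif(1, 1.3, 2.5) * sqrt(MS / 2) * lam
    x1c <- df_equilibrium(m1, lam, b)
    # M1 offsets are width-independent but must stay inside the strip
    if (x1c < b) {
      expect_equal(x1c, df_equilibrium(m1, lam, b, method = "numeric"),
                   tolerance = 1e-6)
    }
    lam2 <- runif(1, 25, 60)
    b2 <- runif(1, 1.05, 1.8) * sqrt(MS / 2) * lam2
    x2c <- df_equilibrium(m2, lam2, b2)
    expect_equal(x2c, df_equilibrium(m2, lam2, b2, method = "numeric"),
                 tolerance = 1e-6)
  }
})

test_that("stability is exchanged at the pitchfork", {
  m2 <- m2_model(2)
  eps <- 1e-5
  slope0 <- function(lambda, b) (strip_rhs(eps, m2, lambda, b) -
                                   strip_rhs(-eps, m2, lambda, b)) / (2 * eps)
  expect_lt(slope0(40, 35), 0)       # below threshold: SF attracting
  expect_gt(slope0(40, 55), 0)       # above: SF repelling
  xb <- df_equilibrium(m2, 40, 55)
  slope_xb <- (strip_rhs(xb + eps, m2, 40, 55) -
                 strip_rhs(xb - eps, m2, 40, 55)) / (2 * eps)
  expect_lt(slope_xb, 0)             # the forked branches are stable
})

test_that("shape forces follow the file geometry", {
  sf <- shape_forces(m2_model(2), 50, 30, "SF")
  expect_equal(unname(sf), c(2 * 2 * (30 / 40)^-1, 2 * (50 / 40)^-1))
  # attractive side forces pull: f_x < 0 in the single file of family 1
  sf1 <- shape_forces(m1_model(2), 45, 30, "SF")
  expect_lt(sf1[["f_x"]], 0)
  expect_gt(sf1[["f_y"]], 0)
  # long-range variant adds a nonnegative axial push
  d_short <- shape_forces(m2_model(2), 40, 60, "DF", "short")
  d_long <- shape_forces(m2_model(2), 40, 60, "DF", "long")
  expect_gte(d_long[["f_y"]], d_short[["f_y"]])
  expect_equal(d_long[["f_x"]], d_short[["f_x"]])
  expect_error(shape_forces(m2_model(2), 40, 30, "DF"), "stable")
  expect_error(shape_forces(m2_model(2), 40, 60, "SF"), "unstable")
})

test_that("aspect-ratio model matches its closed form and validity bounds", {
  expect_equal(aspect_ratio_predicted(3, 3, 35), 1)
  expect_equal(aspect_ratio_predicted(5.333333, 1.6, 35),
               (35 - 1.6)^2 / (35 - 5.333333)^2)
  expect_gt(aspect_ratio_predicted(6, 1.6, 35),
            aspect_ratio_predicted(5, 1.6, 35))
  expect_error(aspect_ratio_predicted(36, 1.6, 35), "kappa")
})

test_that("stiffness fitting recovers kappa from model-generated ratios", {
  model <- m2_model()
  cells <- do.call(rbind, lapply(sample_population(vl3_params(), 12, seed = 2),
                                 function(g) data.frame(
                                   half_width = g$half_width,
                                   half_length = g$half_length,
                                   n_nuclei = g$n_nuclei)))
  cells$ar <- vapply(seq_len(nrow(cells)), function(i)
    myonuc:::predict_cell_ar(cell_geometry(cells$half_width[i],
                                           cells$half_length[i],
                                           cells$n_nuclei[i]),
                             model, 35), numeric(1))
  fit <- fit_kappa(cells, model)
  expect_equal(fit$kappa, 35, tolerance = 1e-3)
  expect_lt(fit$error, 1e-6)
  expect_equal(nrow(fit$surface), 200)
  # 5% multiplicative noise: recovery within 10%
  set.seed(31)
  noisy <- cells
  noisy$ar <- noisy$ar * rlnorm(nrow(noisy), 0, 0.05)
  fit2 <- fit_kappa(noisy, model)
  expect_lt(abs(fit2$kappa - 35) / 35, 0.1)
})

test_that("bifurcation diagram tabulates the SF/DF boundary", {
  d <- bifurcation_diagram(m2_model(2), lambda_range = c(30, 40, 50),
                           b_range = c(20, 45))
  expect_equal(nrow(d), 6)
  expect_true(all((d$x_bar > 0) == !d$stable_SF))
  expect_true(all(d$stable_SF == (d$b < sqrt(2 / 2) * d$lambda)))
})
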