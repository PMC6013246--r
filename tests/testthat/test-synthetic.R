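test_that("population sampling reproduces the requested moments", {
  p0 <- population_params(500, 0, 80, 0, 15, 0)
  cells <- sample_population(p0, 5, seed = 1)
  for (g in cells) {
    expect_equal(2 * g$half_length, 500)
    expect_equal(2 * g$half_width, 80)
    expect_equal(g$n_nuclei, 15L)
  }
  expect_identical(sample_population(vl3_params(), 10, seed = 4),
                   sample_population(vl3_params(), 10, seed = 4))
  big <- sample_population(vl3_params(), 1000, seed = 2)
  widths <- vapply(big, function(g) 2 * g$half_width, numeric(1))
  se <- 17.5 / sqrt(1000)
  expect_lt(abs(mean(widths) - 80.4), 3 * se)
  counts <- vapply(big, `[[`, integer(1), "n_nuclei")
  expect_true(all(counts >= 2))
  expect_lt(abs(mean(counts) - 15.3), 3 * 2.9 / sqrt(1000) + 0.5)
})

test_that("coupled sampling correlates count with width", {
  cells <- sample_population(vl4_params(), 150, seed = 9,
                             count_width_coupling = TRUE)
  widths <- vapply(cells, `[[`, numeric(1), "half_width")
  counts <- vapply(cells, `[[`, integer(1), "n_nuclei")
  expect_gt(cor(widths, counts), 0.4)
})

test_that("nucleus placement respects margins, seeds and equilibria", {
  g <- cell_geometry(25, 250, 9)
  X <- place_nuclei(g, "uniform_random", seed = 5)
  expect_true(all(abs(X[, 1]) <= 25 - 7 & abs(X[, 2]) <= 250 - 7))
  expect_identical(X, place_nuclei(g, "uniform_random", seed = 5))
  model <- calibrated_model("M2")
  Xeq <- place_nuclei(g, "model_equilibrium", model, jitter_sd = 0, seed = 1)
  v <- net_velocities(Xeq, model, g)
  expect_lt(max(sqrt(rowSums(v^2))), 1e-4)
  # jitter displaces but stays inside the cell
  Xj <- place_nuclei(g, "model_equilibrium", model, jitter_sd = 2, seed = 1)
  expect_false(identical(Xeq, Xj))
  expect_lt(max(abs(Xeq - Xj)), 10)
  expect_true(all(abs(Xj[, 1]) <= 25 & abs(Xj[, 2]) <= 250))
})

test_that("uniform placements match the random NND baseline", {
  g <- cell_geometry(25, 250, 9)
  nnd <- vapply(1:150, function(k) mean(nearest_neighbor_distances(
    place_nuclei(g, "uniform_random", seed = 100 + k))), numeric(1))
  base <- random_nnd_baseline(g, n_real = 150, seed = 7)
  base_mean <- sum(base$mean * base$mid) / sum(base$mean)
  expect_lt(abs(mean(nnd) - base_mean) / base_mean, 0.15)
})

test_that("equilibrium placements are SF in narrow and DF in wide cells", {
  model <- calibrated_model("M2")
  narrow <- cell_geometry(25, 250, 9)
  wide <- cell_geometry(42, 250, 15)
  Xn <- place_nuclei(narrow, "model_equilibrium", model, jitter_sd = 0, seed = 2)
  Xw <- place_nuclei(wide, "model_equilibrium", model, jitter_sd = 0, seed = 2)
  expect_equal(classify_pattern(Xn, narrow)$label, "SF")
  expect_equal(classify_pattern(Xw, wide)$label, "DF")
  # equilibrium ensembles are far from random: the pooled mean NND sits
  # above the random-placement band for the same set of geometries
  geoms <- sample_population(vl4_params(), 15, seed = 6)
  eq_nnd <- mean(vapply(seq_along(geoms), function(i)
    mean(nearest_neighbor_distances(
      place_nuclei(geoms[[i]], "model_equilibrium", model, jitter_sd = 2,
                   seed = 30 + i))), numeric(1)))
  pooled <- vapply(1:100, function(k)
    mean(vapply(seq_along(geoms), function(i)
      mean(nearest_neighbor_distances(
        place_nuclei(geoms[[i]], "uniform_random", seed = 1000 * k + i))),
      numeric(1))), numeric(1))
  expect_gt(eq_nnd, mean(pooled) + 2 * sd(pooled))
})

test_that("synthetic ellipse tables invert the shape model", {
  model <- calibrated_model("M2")
  g <- cell_geometry(42, 250, 15)
  X <- place_nuclei(g, "model_equilibrium", model, jitter_sd = 0, seed = 3)
  e <- attach_shapes(X, g, model, kappa = 35)
  expect_equal(nrow(e), 15)
  # constant area, aspect ratio above 1 for a wide repulsive-side cell
  expect_equal(e$major * e$minor, rep((2 * 7)^2, 15))
  expect_true(all(e$ar > 1))
  expect_equal(aspect_ratio_from_ellipse(e$major[1], e$minor[1], e$angle[1]),
               e$ar[1])
  en <- attach_shapes(X, g, model, kappa = 35, noise_sd = 0.05, seed = 4)
  expect_false(any(en$ar == e$ar))
})
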