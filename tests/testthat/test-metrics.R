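test_that("nearest-neighbour distances match direct enumeration", {
  X <- cbind(0, c(0, 40, 100))
  expect_equal(nearest_neighbor_distances(X), c(40, 40, 60))
  set.seed(1)
  Y <- cbind(runif(6, -20, 20), runif(6, -100, 100))
  perm <- sample(6)
  expect_equal(sort(nearest_neighbor_distances(Y)),
               sort(nearest_neighbor_distances(Y[perm, ])))
  expect_error(nearest_neighbor_distances(Y[1, , drop = FALSE]), "at least 2")
})

test_that("crowded random placements have smaller mean NND", {
  g9 <- cell_geometry(25, 250, 9)
  g15 <- cell_geometry(25, 250, 15)
  mean_nnd <- function(g, seed) {
    mean(vapply(seq_len(150), function(k) {
      mean(nearest_neighbor_distances(
        place_nuclei(g, "uniform_random", seed = seed + k)))
    }, numeric(1)))
  }
  expect_gt(mean_nnd(g9, 1000), mean_nnd(g15, 5000))
})

test_that("random NND baseline is reproducible and well-formed", {
  g <- cell_geometry(25, 250, 9)
  b1 <- random_nnd_baseline(g, n_real = 50, seed = 3)
  b2 <- random_nnd_baseline(g, n_real = 50, seed = 3)
  expect_identical(b1, b2)
  expect_equal(sum(b1$mean), 9)          # every nucleus lands in some bin
  expect_true(all(b1$sd >= 0))
  # the mean curve stabilises as realisations accumulate
  ba <- random_nnd_baseline(g, n_real = 400, seed = 4)
  bb <- random_nnd_baseline(g, n_real = 400, seed = 5)
  expect_lt(max(abs(ba$mean - bb$mean)), 0.5)
  expect_error(random_nnd_baseline(cell_geometry(25, 250, 1)), "fewer than 2")
})

test_that("pattern classification implements the 60%/50% peak rules", {
  g <- cell_geometry(35, 250, 10)
  sf <- cbind(rep(0, 10), seq(-200, 200, length.out = 10))
  expect_equal(classify_pattern(sf, g)$label, "SF")
  df <- cbind(rep(c(-17.5, 17.5), 5), seq(-200, 200, length.out = 10))
  expect_equal(classify_pattern(df, g)$label, "DF")
  # 5 + 3 in two peak bins of 14 nuclei = 57% < 60% -> neither
  b <- g$half_width
  relx <- c(rep(-0.5, 5), rep(0.5, 3), -0.9, -0.2, 0.05, 0.2, 0.3, 0.9)
  X <- cbind(relx * b, seq(-200, 200, length.out = 14))
  expect_equal(classify_pattern(X, g)$label, "neither")
  # two adjacent loaded bins are one broad file, not DF
  adj <- cbind(c(rep(0.05, 5), rep(0.35, 5)) * b,
               seq(-200, 200, length.out = 10))
  expect_false(classify_pattern(adj, g)$label == "DF")
  # invariances: mirror and uniform rescaling
  for (X0 in list(sf, df, X)) {
    lab <- classify_pattern(X0, g)$label
    expect_equal(classify_pattern(X0 %*% diag(c(-1, 1)), g)$label, lab)
    g2 <- cell_geometry(g$half_width * 3, g$half_length * 3, nrow(X0))
    expect_equal(classify_pattern(X0 * 3, g2)$label, lab)
  }
})

test_that("positional histograms pool cell-normalised coordinates", {
  g <- cell_geometry(40, 250, 1)
  h <- positional_histograms(list(list(geom = g, cfg = matrix(0, 1, 2))),
                             n_bins = 5)
  expect_equal(h$x, c(0, 0, 1, 0, 0))
  expect_equal(h$y, c(0, 0, 1, 0, 0))
  set.seed(9)
  cells <- list(list(geom = g, cfg = cbind(runif(5, -40, 40),
                                           runif(5, -250, 250))))
  mirrored <- list(list(geom = g, cfg = cells[[1]]$cfg %*% diag(c(-1, 1))))
  expect_equal(positional_histograms(mirrored)$x,
               rev(positional_histograms(cells)$x))
  expect_equal(positional_histograms(mirrored)$y,
               positional_histograms(cells)$y)
})

test_that("mean absolute x summarises file offset", {
  g <- cell_geometry(40, 250, 4)
  expect_equal(mean_abs_x(cbind(0, c(-1, 0, 1, 2))), 0)
  expect_equal(mean_abs_x(cbind(c(-12, 12, -12, 12), 0)), 12)
})

test_that("correlation histograms carry the zigzag signatures", {
  l <- 250
  g <- cell_geometry(35, l, 11)
  ys <- seq(-175, 175, by = 35)             # 11 positions, inside pole trim
  sf_cells <- list(list(geom = g, cfg = cbind(0, ys)))
  zig <- list(list(geom = g, cfg = cbind(17.5 * (-1)^(seq_along(ys)), ys)))
  # pairwise (aligned) files: both rows at the same y grid
  y2 <- seq(-160, 160, by = 40)
  paired <- list(list(geom = cell_geometry(35, l, 18),
                      cfg = rbind(cbind(-17.5, y2), cbind(17.5, y2))))
  at <- function(h, offs) sum(h$counts[h$bin_centers %in% offs])
  sfh <- zigzag_correlations(sf_cells)$auto_SF
  expect_gt(at(sfh, -3:3), 0.9 * sum(sfh$counts))   # integer peaks
  zz <- zigzag_correlations(zig)
  expect_equal(classify_pattern(zig[[1]]$cfg, g)$label, "DF")
  expect_gt(at(zz$cross_DF, -3:3), 0.9 * sum(zz$cross_DF$counts))
  pp <- zigzag_correlations(paired)
  half <- c(-2.5, -1.5, -0.5, 0.5, 1.5, 2.5)
  expect_gt(at(pp$cross_DF, half), 0.9 * sum(pp$cross_DF$counts))
  # rows individually equispaced in both fixtures: integer auto peaks
  expect_gt(at(zz$auto_DF_row, -3:3), 0.9 * sum(zz$auto_DF_row$counts))
  expect_null(zigzag_correlations(sf_cells)$cross_DF)
})

test_that("oriented aspect ratio flips across the pi/4 boundary", {
  expect_equal(aspect_ratio_from_ellipse(10, 5, pi / 2), 2)
  expect_equal(aspect_ratio_from_ellipse(10, 5, 0), 0.5)
  expect_equal(aspect_ratio_from_ellipse(6, 6, 1.1), 1)
  expect_equal(aspect_ratio_from_ellipse(10, 5, pi / 2 - pi / 4), 2)
  expect_error(aspect_ratio_from_ellipse(4, 5, 0))
})

test_that("ellipse tables store degrees on disk, radians in memory", {
  e <- data.frame(cell_id = "c1", nucleus_id = 1:2, cx = c(0, 1),
                  cy = c(2, 3), major = c(10, 12), minor = c(5, 6),
                  angle = c(pi / 2, pi / 4))
  path <- tempfile(fileext = ".csv")
  write_ellipses(e, path)
  disk <- utils::read.csv(path)
  expect_equal(disk$angle_deg, c(90, 45))
  expect_equal(read_ellipses(path)$angle, e$angle)
})
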