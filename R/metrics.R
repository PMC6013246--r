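#' Nearest-neighbour distances between nuclear centroids
#'
#' @param cfg N x 2 position matrix (N >= 2).
#' @return vector of N distances, microns, in nucleus order.
#' @export
nearest_neighbor_distances <- function(cfg) {
  X <- as_positions(cfg)
  if (nrow(X) < 2) stop("nearest-neighbour distances need at least 2 nuclei")
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  unname(apply(D, 1, min))
}

#' Monte-Carlo baseline NND histogram for random nuclear placement
#'
#' Places `n_nuclei` centroids i.i.d. uniformly in the rectangle, `n_real`
#' times, and histograms the nearest-neighbour distances per realisation; the
#' per-bin mean and SD across realisations are the "random positioning"
#' reference curve against which measured or simulated patterns are compared.
#'
#' @param geom a [cell_geometry()] (needs at least 2 nuclei).
#' @param n_real number of Monte-Carlo realisations.
#' @param seed RNG seed.
#' @param breaks histogram breaks, microns (default 10 um bins over 0-150;
#'   larger NNDs are pooled into the last bin).
#' @return list with `breaks`, `mid`, per-bin `mean` and `sd` counts.
#' @export
random_nnd_baseline <- function(geom, n_real = 1000, seed = 0L,
                                breaks = seq(0, 150, by = 10)) {
  stopifnot(n_real >= 1)
  if (geom$n_nuclei < 2) stop("baseline undefined for fewer than 2 nuclei")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  b <- geom$half_width; l <- geom$half_length; n <- geom$n_nuclei
  counts <- matrix(0, n_real, length(breaks) - 1)
  for (k in seq_len(n_real)) {
    X <- cbind(stats::runif(n, -b, b), stats::runif(n, -l, l))
    nnd <- pmin(nearest_neighbor_distances(X), max(breaks) - 1e-9)
    counts[k, ] <- graphics::hist(nnd, breaks = breaks, plot = FALSE)$counts
  }
  list(breaks = breaks, mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
       mean = colMeans(counts), sd = apply(counts, 2, stats::sd))
}

#' Classify a nuclear pattern as single file, double file, or neither
#'
#' Relative x-positions x/b are histogrammed in 7 equal bins spanning
#' \[-1, 1\]. Single file (SF): one peak bin holds at least 60% of the nuclei.
#' Double file (DF): the two highest, non-adjacent bins jointly hold at least
#' 60% and their counts differ by less than 50% (relative to the larger).
#' Otherwise "neither".
#'
#' @param cfg N x 2 position matrix (N >= 2).
#' @param geom a [cell_geometry()].
#' @return list with `label` ("SF"/"DF"/"neither"), the 7 bin `counts` and the
#'   `peak_bins` indices used by the rule.
#' @export
classify_pattern <- function(cfg, geom) {
  X <- as_positions(cfg)
  n <- nrow(X)
  if (n < 2) stop("pattern classification needs at least 2 nuclei")
  relx <- pmin(pmax(X[, 1] / geom$half_width, -1), 1)
  brk <- seq(-1, 1, length.out = 8)
  cnt <- graphics::hist(relx, breaks = brk, plot = FALSE, include.lowest = TRUE)$counts
  ord <- order(cnt, decreasing = TRUE)
  label <- "neither"; peaks <- integer(0)
  if (cnt[ord[1]] >= 0.6 * n) {
    label <- "SF"; peaks <- ord[1]
  } else {
    top2 <- ord[1:2]
    n1 <- cnt[top2[1]]; n2 <- cnt[top2[2]]
    if (abs(diff(top2)) > 1 &&           # one broad file must not count twice
        n1 + n2 >= 0.6 * n &&
        abs(n1 - n2) / max(n1, n2) < 0.5) {
      label <- "DF"; peaks <- sort(top2)
    }
  }
  list(label = label, counts = cnt, peak_bins = peaks)
}

#' Pooled positional histograms in cell-normalised coordinates
#'
#' Half-width and half-length are normalised to 1 and the relative x- and
#' y-positions of all nuclei across cells are pooled.
#'
#' @param cells list of `list(geom = , cfg = )` pairs.
#' @param n_bins number of equal bins over \[-1, 1\].
#' @return list with `breaks`, and density-normalised `x` and `y` counts.
#' @export
positional_histograms <- function(cells, n_bins = 10) {
  stopifnot(length(cells) >= 1)
  relx <- rely <- numeric(0)
  for (cell in cells) {
    X <- as_positions(cell$cfg)
    relx <- c(relx, X[, 1] / cell$geom$half_width)
    rely <- c(rely, X[, 2] / cell$geom$half_length)
  }
  brk <- seq(-1, 1, length.out = n_bins + 1)
  clip <- function(v) pmin(pmax(v, -1), 1)
  hx <- graphics::hist(clip(relx), breaks = brk, plot = FALSE, include.lowest = TRUE)
  hy <- graphics::hist(clip(rely), breaks = brk, plot = FALSE, include.lowest = TRUE)
  list(breaks = brk, mid = hx$mids,
       x = hx$counts / length(relx), y = hy$counts / length(rely))
}

#' Mean absolute nuclear x-position
#'
#' The per-cell decentering summary whose dependence on cell width separates
#' the model classes: 0 for a perfect single file, the file offset for a
#' symmetric double file.
#'
#' @param cfg N x 2 position matrix.
#' @param geom unused; kept for a uniform metric signature.
#' @return microns.
#' @export
mean_abs_x <- function(cfg, geom = NULL) {
  mean(abs(as_positions(cfg)[, 1]))
}

#' Zigzag auto- and cross-correlation histograms
#'
#' Cells are first classified SF/DF; nuclei within 10% of the cell height of
#' either pole are discarded. Within each file the remaining y-positions are
#' rescaled so the mean spacing is 1 and shifted so the middle-most nucleus
#' sits at 0 (auto-correlation: pooled histogram of these positions; equally
#' spaced files peak at integers). For DF cells the rows are the nuclei left
#' and right of the midline; the cross-correlation pools the offsets between
#' one row's positions and the midpoints of consecutive nuclei of the other
#' row, in units of the mean row spacing: a perfect zigzag peaks at integers,
#' aligned ("pairwise") rows at half-integers.
#'
#' @param cells list of `list(geom = , cfg = )` pairs.
#' @param bin histogram bin width in normalised spacing units (default 0.25).
#' @param span histogram half-range in spacing units.
#' @return list of correlation results (`auto_SF`, `auto_DF_row`, `cross_DF`),
#'   each with `bin_centers` and `counts`, or `NULL` when no cell of the
#'   required pattern is present.
#' @export
zigzag_correlations <- function(cells, bin = 0.25, span = 3) {
  auto_sf <- auto_df <- cross_df <- numeric(0)
  for (cell in cells) {
    X <- as_positions(cell$cfg)
    geom <- cell$geom
    lab <- classify_pattern(X, geom)$label
    if (lab == "neither") next
    keep <- abs(X[, 2]) <= geom$half_length - 0.2 * geom$half_length
    X <- X[keep, , drop = FALSE]
    if (nrow(X) < 3) next
    if (lab == "SF") {
      auto_sf <- c(auto_sf, normalize_file(X[, 2]))
    } else {
      left <- X[X[, 1] < 0, 2]; right <- X[X[, 1] >= 0, 2]
      if (length(left) >= 2) auto_df <- c(auto_df, normalize_file(left))
      if (length(right) >= 2) auto_df <- c(auto_df, normalize_file(right))
      if (length(left) >= 2 && length(right) >= 2) {
        s_left <- diff(range(left)) / (length(left) - 1)
        s_right <- diff(range(right)) / (length(right) - 1)
        s <- mean(c(s_left, s_right))
        if (s > 0) {
          mid_r <- midpoints(right)
          mid_l <- midpoints(left)
          cross_df <- c(cross_df, as.numeric(outer(left, mid_r, "-")) / s,
                        as.numeric(outer(right, mid_l, "-")) / s)
        }
      }
    }
  }
  hist_or_null <- function(v, kind) {
    if (!length(v)) return(NULL)
    brk <- seq(-span - bin / 2, span + bin / 2, by = bin)
    v <- v[v >= min(brk) & v <= max(brk)]
    h <- graphics::hist(v, breaks = brk, plot = FALSE, include.lowest = TRUE)
    list(kind = kind, bin_centers = h$mids, counts = h$counts)
  }
  list(auto_SF = hist_or_null(auto_sf, "auto_SF"),
       auto_DF_row = hist_or_null(auto_df, "auto_DF_row"),
       cross_DF = hist_or_null(cross_df, "cross_DF"))
}

# rescale a file's y-positions to unit mean spacing, middle-most nucleus at 0
normalize_file <- function(y) {
  rng <- range(y)
  if (diff(rng) == 0) return(rep(0, length(y)))
  yn <- y * (length(y) - 1) / diff(rng)
  center <- yn[which.min(abs(yn - mean(range(yn))))]
  yn - center
}

midpoints <- function(y) {
  y <- sort(y)
  (y[-1] + y[-length(y)]) / 2
}

#' Oriented aspect ratio of a nuclear ellipse
#'
#' Major/minor axis ratio if the major axis lies along the cell's long axis
#' (orientation within pi/4 of pi/2), its reciprocal otherwise, so values > 1
#' mean elongation along the cell.
#'
#' @param major,minor axis lengths, `major >= minor > 0`.
#' @param orientation angle of the major axis in \[0, pi).
#' @return dimensionless oriented aspect ratio.
#' @export
aspect_ratio_from_ellipse <- function(major, minor, orientation) {
  stopifnot(all(major >= minor), all(minor > 0))
  ifelse(abs(orientation - pi / 2) <= pi / 4, major / minor, minor / major)
}

#' Read or write nuclear ellipse tables as CSV
#'
#' Columns `cell_id`, `nucleus_id`, `cx`, `cy`, `major`, `minor`, `angle_deg`;
#' angles are stored in degrees on disk and converted to radians on read
#' (column `angle`).
#'
#' @param ellipses data frame with an `angle` column in radians.
#' @param path CSV path.
#' @name ellipse_io
#' @export
write_ellipses <- function(ellipses, path) {
  stopifnot(all(c("cell_id", "nucleus_id", "cx", "cy", "major", "minor",
                  "angle") %in% names(ellipses)))
  out <- ellipses
  out$angle_deg <- out$angle * 180 / pi
  out$angle <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ellipse_io
#' @export
read_ellipses <- function(path) {
  d <- utils::read.csv(path)
  d$angle <- d$angle_deg * pi / 180
  d$angle_deg <- NULL
  d
}
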