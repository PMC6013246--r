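#' Population parameters for synthetic cell geometries
#'
#' Means and SDs (microns) of cell length and width and of the nucleus count,
#' plus the positional jitter applied on top of model equilibria.
#' `vl3_params()` and `vl4_params()` carry the measured values for the wide
#' VL3 (length 499.2 +/- 57.7, width 80.4 +/- 17.5, count 15.3 +/- 2.9) and
#' narrow VL4 (491.8 +/- 57.1, 51.7 +/- 11.3, 9.3 +/- 1.6) muscles.
#'
#' @param length_mean,length_sd,width_mean,width_sd,count_mean,count_sd
#'   population moments.
#' @param jitter_sd SD (um) of the Gaussian jitter around equilibria.
#' @param nuclear_radius microns.
#' @return a `population_params` object.
#' @export
population_params <- function(length_mean, length_sd, width_mean, width_sd,
                              count_mean, count_sd, jitter_sd = 2,
                              nuclear_radius = 7) {
  stopifnot(length_sd >= 0, width_sd >= 0, count_sd >= 0, jitter_sd >= 0)
  structure(list(length_mean = length_mean, length_sd = length_sd,
                 width_mean = width_mean, width_sd = width_sd,
                 count_mean = count_mean, count_sd = count_sd,
                 jitter_sd = jitter_sd, nuclear_radius = nuclear_radius),
            class = "population_params")
}

#' @rdname population_params
#' @export
vl3_params <- function() population_params(499.2, 57.7, 80.4, 17.5, 15.3, 2.9)

#' @rdname population_params
#' @export
vl4_params <- function() population_params(491.8, 57.1, 51.7, 11.3, 9.3, 1.6)

# normal truncated at +/- 3 SD and at positivity, by rejection
rtruncnorm3 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v > 0 && abs(v - mean) <= 3 * sd) break
    }
    out[i] <- v
  }
  out
}

#' Sample a population of cell geometries
#'
#' Lengths and widths are drawn from normals truncated at 3 SD (and at
#' positivity); nucleus counts are rounded to the nearest integer >= 2. With
#' `count_width_coupling` the count shares a latent Gaussian factor with the
#' width (correlation ~0.7), mimicking the observed count-area correlation;
#' by default the two are independent.
#'
#' @param p a [population_params()].
#' @param n_cells number of cells.
#' @param seed RNG seed.
#' @param count_width_coupling logical.
#' @return list of [cell_geometry()] objects.
#' @export
sample_population <- function(p, n_cells, seed = 0L,
                              count_width_coupling = FALSE) {
  stopifnot(inherits(p, "population_params"), n_cells >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  len <- rtruncnorm3(n_cells, p$length_mean, p$length_sd)
  wid <- rtruncnorm3(n_cells, p$width_mean, p$width_sd)
  if (count_width_coupling && p$width_sd > 0) {
    rho <- 0.7
    zw <- (wid - p$width_mean) / p$width_sd
    cnt <- p$count_mean + p$count_sd *
      (rho * zw + sqrt(1 - rho^2) * stats::rnorm(n_cells))
  } else {
    cnt <- stats::rnorm(n_cells, p$count_mean, p$count_sd)
  }
  cnt <- pmax(2L, as.integer(round(cnt)))
  lapply(seq_len(n_cells), function(i)
    cell_geometry(wid[i] / 2, len[i] / 2, cnt[i], p$nuclear_radius))
}

#' Place nuclei in a cell
#'
#' `uniform_random`: i.i.d. uniform positions with an interior margin of one
#' nuclear radius. `model_equilibrium`: relax a random start under `model` to
#' equilibrium, then add i.i.d. Gaussian jitter of SD `jitter_sd`, clipped to
#' the rectangle; non-convergent starts are resampled up to `max_retries`
#' times before erroring.
#'
#' @param geom a [cell_geometry()].
#' @param mode placement mode.
#' @param model a [model_spec()] (required for `model_equilibrium`).
#' @param jitter_sd Gaussian jitter SD, microns.
#' @param seed RNG seed.
#' @param max_retries resampling budget for non-convergent starts.
#' @return N x 2 position matrix.
#' @export
place_nuclei <- function(geom, mode = c("uniform_random", "model_equilibrium"),
                         model = NULL, jitter_sd = 0, seed = 0L,
                         max_retries = 5L) {
  mode <- match.arg(mode)
  b <- geom$half_width; l <- geom$half_length; r <- geom$nuclear_radius
  if (mode == "uniform_random") {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    return(cbind(stats::runif(geom$n_nuclei, -b + r, b - r),
                 stats::runif(geom$n_nuclei, -l + r, l - r)))
  }
  if (is.null(model)) stop("model_equilibrium placement needs a model")
  for (k in 0:max_retries) {
    X0 <- initial_conditions(geom, "random", seed = seed + k)
    eq <- relax_to_equilibrium(X0, model, geom)
    if (eq$converged) {
      X <- eq$final
      if (jitter_sd > 0) {
        old <- local_seed(seed + 1000L)
        on.exit(restore_seed(old), add = TRUE)
        X <- X + matrix(stats::rnorm(length(X), 0, jitter_sd), ncol = 2)
        X[, 1] <- pmin(pmax(X[, 1], -b), b)
        X[, 2] <- pmin(pmax(X[, 2], -l), l)
      }
      return(X)
    }
  }
  stop("no convergent equilibrium found after ", max_retries + 1, " starts")
}

#' Generate a synthetic multi-cell dataset at model equilibria
#'
#' Convenience wrapper: samples geometries from one or more populations and
#' places nuclei at (jittered) equilibria of `model`.
#'
#' @param params list of [population_params()] (cells split evenly among them).
#' @param n_cells total number of cells.
#' @param model a [model_spec()].
#' @param jitter_sd jitter SD, microns.
#' @param seed RNG seed.
#' @return list of `list(geom = , cfg = )` pairs.
#' @export
synthesize_cells <- function(params, n_cells, model, jitter_sd = 2,
                             seed = 0L) {
  if (inherits(params, "population_params")) params <- list(params)
  per <- diff(round(seq(0, n_cells, length.out = length(params) + 1)))
  geoms <- list()
  for (j in seq_along(params)) {
    geoms <- c(geoms, sample_population(params[[j]], per[j],
                                        seed = seed + 100L * j))
  }
  lapply(seq_along(geoms), function(i) {
    list(geom = geoms[[i]],
         cfg = place_nuclei(geoms[[i]], "model_equilibrium", model,
                            jitter_sd = jitter_sd, seed = seed + 17L * i))
  })
}

#' Attach model-predicted ellipse shapes to a configuration
#'
#' Every nucleus of the cell receives the strip-model aspect ratio predicted
#' for its cell geometry (optionally with multiplicative lognormal noise), at
#' fixed area pi * r^2 so axis lengths follow from the ratio alone; the major
#' axis lies along the cell axis for ratios > 1 and across it otherwise.
#'
#' @param cfg N x 2 position matrix.
#' @param geom a [cell_geometry()].
#' @param model a [model_spec()].
#' @param kappa nuclear stiffness used in the shape model.
#' @param noise_sd sdlog of the multiplicative lognormal noise (0 = none).
#' @param seed RNG seed.
#' @param variant `"long"` or `"short"` neighbour range for the shape forces.
#' @return data frame with `nucleus_id`, `cx`, `cy`, `major`, `minor`,
#'   `angle` (radians) and the sampled `ar`.
#' @export
attach_shapes <- function(cfg, geom, model, kappa, noise_sd = 0, seed = 0L,
                          variant = "long") {
  X <- as_positions(cfg)
  ar0 <- predict_cell_ar(geom, model, kappa, variant)
  n <- nrow(X)
  ar <- rep(unname(ar0), n)
  if (noise_sd > 0) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    ar <- ar * stats::rlnorm(n, 0, noise_sd)
  }
  r <- geom$nuclear_radius
  oriented <- pmax(ar, 1 / ar)          # axis ratio of the drawn ellipse
  data.frame(nucleus_id = seq_len(n), cx = X[, 1], cy = X[, 2],
             major = 2 * r * sqrt(oriented), minor = 2 * r / sqrt(oriented),
             angle = ifelse(ar >= 1, pi / 2, 0), ar = ar)
}
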