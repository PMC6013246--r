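#' Rectangular cell geometry
#'
#' The cell is idealised as a rectangle of half-width `b` (short axis, x) and
#' half-length `l` (long axis, y), centred at the origin, holding `n_nuclei`
#' nuclei of radius `nuclear_radius`.
#'
#' @param half_width,half_length positive, microns; `half_width < half_length`.
#' @param n_nuclei integer >= 1.
#' @param nuclear_radius microns (default 7).
#' @return A `cell_geometry` object.
#' @export
cell_geometry <- function(half_width, half_length, n_nuclei, nuclear_radius = 7) {
  stopifnot(half_width > 0, half_length > 0, n_nuclei >= 1, nuclear_radius > 0)
  structure(list(half_width = as.numeric(half_width),
                 half_length = as.numeric(half_length),
                 n_nuclei = as.integer(n_nuclei),
                 nuclear_radius = as.numeric(nuclear_radius)),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("<cell_geometry> %g x %g um (2b x 2l), N = %d, r = %g um\n",
              2 * x$half_width, 2 * x$half_length, x$n_nuclei, x$nuclear_radius))
  invisible(x)
}

as_positions <- function(cfg) {
  m <- as.matrix(cfg)
  stopifnot(ncol(m) == 2, is.numeric(m))
  unname(m)
}

#' Normal projections of a point onto the four cell boundary segments
#'
#' @param p a length-2 point `(x, y)` inside the rectangle.
#' @param geom a [cell_geometry()].
#' @return list with matrix `points` (rows L, R, U, D) and named `distances`;
#'   distances are clamped at 0 (with a warning) for points outside.
#' @export
boundary_projections <- function(p, geom) {
  b <- geom$half_width; l <- geom$half_length
  x <- p[1]; y <- p[2]
  d <- c(L = b + x, R = b - x, U = l - y, D = l + y)
  if (any(d < 0)) {
    warning("point lies outside the cell rectangle; distances clamped at 0")
    d <- pmax(d, 0)
  }
  pts <- rbind(L = c(-b, y), R = c(b, y), U = c(x, l), D = c(x, -l))
  list(points = pts, distances = d)
}

#' Net velocities of all nuclei under a model
#'
#' Overdamped force balance: the velocity of nucleus i is the sum of pairwise
#' internuclear forces, side and pole boundary forces (acting along the normal
#' to each boundary segment) and the size-exclusion terms, with unit vectors
#' pointing from the source toward the nucleus (drag coefficient normalised to
#' 1, so velocities are microns per model time unit).
#'
#' @param cfg an N x 2 matrix of positions (microns, cell-centred).
#' @param model a [model_spec()].
#' @param geom a [cell_geometry()].
#' @return N x 2 matrix of velocities.
#' @export
net_velocities <- function(cfg, model, geom) {
  X <- as_positions(cfg)
  if (nrow(X) > 1) {
    dmin <- min(stats::dist(X))
    if (dmin < 1e-8) stop("coincident nuclei: size exclusion diverges")
  }
  cpp_net_velocities(X, as_param_vector(model), geom$half_width,
                     geom$half_length)
}

#' Relax a configuration to mechanical equilibrium
#'
#' Integrates the overdamped dynamics with an adaptive embedded Euler/Heun
#' scheme until every nucleus's velocity 2-norm falls below `tol`, the model
#' time budget `t_max` is exhausted, or `max_steps` accepted/rejected steps
#' have been taken. Steps that would carry a nucleus across the boundary are
#' rejected and retried with a smaller step, never clamped.
#'
#' @param cfg0 initial N x 2 position matrix.
#' @param model a [model_spec()].
#' @param geom a [cell_geometry()].
#' @param tol convergence tolerance on the per-nucleus velocity 2-norm.
#' @param t_max model-time budget.
#' @param max_steps integrator step budget.
#' @param err_tol per-step position error control, microns.
#' @param stall_check,stall_factor stall detection: every `stall_check`
#'   accepted steps the residual must have dropped below `stall_factor` times
#'   its previous checkpoint value. Stalled runs (stiff boundary layers from
#'   size exclusion or tapered cutoffs keep the explicit scheme at its
#'   stability limit) are finished by damped Levenberg-Marquardt root-finding
#'   on the force balance, seeded by the relaxation endpoint; `converged` is
#'   only reported when the final residual genuinely satisfies `tol`.
#' @return An `equilibrium_result`: `final` positions, `converged`,
#'   `max_residual`, `elapsed_model_time`, `steps`, and whether the
#'   equilibrium was `polished` by the root-finder.
#' @export
relax_to_equilibrium <- function(cfg0, model, geom, tol = 1e-4, t_max = 1e6,
                                 max_steps = 200000L, err_tol = 1e-3,
                                 stall_check = 1000L, stall_factor = 0.9) {
  X0 <- as_positions(cfg0)
  stopifnot(nrow(X0) == geom$n_nuclei)
  if (any(abs(X0[, 1]) > geom$half_width | abs(X0[, 2]) > geom$half_length))
    stop("initial configuration has nuclei outside the cell rectangle")
  res <- cpp_relax(X0, as_param_vector(model), geom$half_width,
                   geom$half_length, tol, t_max, as.integer(max_steps),
                   err_tol, as.integer(stall_check), stall_factor)
  structure(list(final = res$positions, converged = res$converged,
                 max_residual = res$max_residual,
                 elapsed_model_time = res$elapsed, steps = res$steps,
                 polished = res$polished),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("<equilibrium_result> %s, max residual %.3g after t = %.3g (%d steps)\n",
              if (x$converged) "converged" else "NOT converged",
              x$max_residual, x$elapsed_model_time, x$steps))
  invisible(x)
}

#' Initial nuclear configurations
#'
#' `random`: positions i.i.d. uniform in the rectangle with an interior margin
#' of one nuclear radius. `equally_spaced_axis`: nuclei on the long axis
#' (x = 0) at spacing 2l/(N+1). `provided`: echoes `positions` unchanged.
#'
#' @param geom a [cell_geometry()].
#' @param mode one of `"random"`, `"equally_spaced_axis"`, `"provided"`.
#' @param seed RNG seed used for `"random"` (default 0).
#' @param positions matrix for `"provided"`.
#' @return N x 2 position matrix.
#' @export
initial_conditions <- function(geom, mode = c("random", "equally_spaced_axis",
                                              "provided"),
                               seed = 0L, positions = NULL) {
  mode <- match.arg(mode)
  n <- geom$n_nuclei
  b <- geom$half_width; l <- geom$half_length; r <- geom$nuclear_radius
  switch(mode,
    random = {
      old <- local_seed(seed)
      on.exit(restore_seed(old), add = TRUE)
      cbind(stats::runif(n, -b + r, b - r), stats::runif(n, -l + r, l - r))
    },
    equally_spaced_axis = {
      lambda <- 2 * l / (n + 1)
      cbind(rep(0, n), -l + lambda * seq_len(n))
    },
    provided = {
      if (is.null(positions)) stop("mode 'provided' needs positions")
      as_positions(positions)
    })
}

# seed handling: make every stochastic entry point reproducible without
# clobbering the caller's RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read or write nuclear configurations as CSV
#'
#' Long format with columns `cell_id`, `nucleus_id`, `x`, `y` (microns), the
#' schema shared by measured, synthetic and simulated data.
#'
#' @param cfgs named list of N x 2 position matrices (names become `cell_id`).
#' @param path CSV file path.
#' @name configuration_io
#' @export
write_configurations <- function(cfgs, path) {
  stopifnot(is.list(cfgs), !is.null(names(cfgs)))
  rows <- do.call(rbind, lapply(names(cfgs), function(id) {
    X <- as_positions(cfgs[[id]])
    data.frame(cell_id = id, nucleus_id = seq_len(nrow(X)),
               x = X[, 1], y = X[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname configuration_io
#' @export
read_configurations <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("cell_id", "nucleus_id", "x", "y") %in% names(d)))
  out <- lapply(split(d, d$cell_id), function(g) {
    g <- g[order(g$nucleus_id), ]
    cbind(g$x, g$y)
  })
  out[unique(as.character(d$cell_id))]
}
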