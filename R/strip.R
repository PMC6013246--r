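#' Reduced zigzag strip model
#'
#' In an infinitely long strip of half-width `b` with nuclei evenly spaced at
#' `lambda` along the long axis and alternating offsets +/- x across the
#' midline, the many-body dynamics reduce to one scalar ODE for the offset x of
#' a reference nucleus:
#' \deqn{dx/dt = 4 f(d(x)) x / d(x) + g_S(b + x) - g_S(b - x),}
#' with \eqn{d(x) = \sqrt{4x^2 + \lambda^2}} the distance to the two nearest
#' neighbours. Cutoffs are ignored here (infinite-reach laws, as in the
#' calibration-step parameterisation).
#'
#' @param x offset(s) from the midline, microns, `|x| < b`.
#' @param model a [model_spec()] supplying `f` and `g_S`.
#' @param lambda axial spacing 2l/(N+1), microns.
#' @param b strip half-width, microns.
#' @return the offset velocity dx/dt (vectorised over `x`).
#' @export
strip_rhs <- function(x, model, lambda, b) {
  stopifnot(lambda > 0, b > 0, all(abs(x) < b))
  fN <- uncut(model$internuclear)
  gS <- uncut(model$side)
  d <- sqrt(4 * x^2 + lambda^2)
  4 * evaluate_force(d, fN) * x / d +
    evaluate_force(b + x, gS) - evaluate_force(b - x, gS)
}

uncut <- function(law) {
  force_law(law$sign, law$exponent, law$magnitude, Inf, law$ref_distance)
}

# d/dd of a cutoff-free power law
law_derivative <- function(law, d) {
  law$sign * law$magnitude * law$exponent * d^(law$exponent - 1) /
    law$ref_distance^law$exponent
}

#' Stability of the single-file state in the strip model
#'
#' The centred single file (x = 0) is linearly stable iff
#' \eqn{2 f(\lambda)/\lambda < -g_S'(b)}. For the two calibrated families the
#' threshold has closed form: with repulsive-decreasing internuclear forces and
#' attractive, linearly increasing side forces (model family 1) the critical
#' spacing is \eqn{\lambda^* = d_{ref}\sqrt{2/M_S}} (SF stable iff
#' \eqn{\lambda > \lambda^*}, independent of b); with repulsive-decreasing side
#' forces (model family 2) the critical width-to-spacing ratio is
#' \eqn{r^* = \sqrt{M_S/2}} (SF stable iff \eqn{b < r^* \lambda}).
#'
#' @inheritParams strip_rhs
#' @return list: `stable`, the inequality sides `lhs`/`rhs`, the `family`
#'   ("M1", "M2" or "other") and the closed-form `lambda_star` or `r_star`
#'   where applicable.
#' @export
sf_is_stable <- function(model, lambda, b) {
  stopifnot(lambda > 0, b > 0)
  if (is.finite(model$side$cutoff) && model$side$cutoff <= b)
    stop("side law not differentiable at the wall distance (cutoff <= b)")
  fN <- uncut(model$internuclear)
  gS <- uncut(model$side)
  lhs <- 2 * evaluate_force(lambda, fN) / lambda
  rhs <- -law_derivative(gS, b)
  fam <- strip_family(model)
  MS <- model$side$magnitude
  dref <- model$internuclear$ref_distance
  out <- list(stable = lhs < rhs, lhs = lhs, rhs = rhs, family = fam,
              lambda_star = NA_real_, r_star = NA_real_)
  if (fam == "M1") out$lambda_star <- dref * sqrt(2 / MS)
  if (fam == "M2") out$r_star <- sqrt(MS / 2)
  out
}

strip_family <- function(model) {
  sN <- model$internuclear$sign; aN <- model$internuclear$exponent
  sS <- model$side$sign; aS <- model$side$exponent
  if (sN == 1 && aN == -1 && sS == -1 && aS == 1) "M1"
  else if (sN == 1 && aN == -1 && sS == 1 && aS == -1) "M2"
  else "other"
}

#' Double-file equilibrium offset of the strip model
#'
#' The stable nonzero root of [strip_rhs()], i.e. the file offset after the
#' pitchfork bifurcation; 0 while the single file is stable. For the two
#' calibrated families the closed forms are
#' \eqn{\bar x = \frac{1}{2}\sqrt{\lambda^{*2} - \lambda^2}} (family 1,
#' \eqn{\lambda < \lambda^*}) and
#' \eqn{\bar x = \sqrt{(b^2 - (r^*\lambda)^2) / (2 M_S + 1)}} (family 2,
#' \eqn{b > r^*\lambda}); other models fall back to a numeric root.
#'
#' @inheritParams strip_rhs
#' @param method `"auto"` (closed form where available), `"closed"` or
#'   `"numeric"` (bisection on [strip_rhs()]).
#' @return nonnegative offset, microns.
#' @export
df_equilibrium <- function(model, lambda, b, method = c("auto", "closed",
                                                        "numeric")) {
  method <- match.arg(method)
  st <- sf_is_stable(model, lambda, b)
  if (st$stable) return(0)
  fam <- st$family
  if (method != "numeric" && fam != "other") {
    MS <- model$side$magnitude
    xb <- if (fam == "M1") {
      0.5 * sqrt(st$lambda_star^2 - lambda^2)
    } else {
      sqrt((b^2 - (st$r_star * lambda)^2) / (2 * MS + 1))
    }
    return(xb)
  }
  if (method == "closed")
    stop("no closed form for this model family; use method = 'numeric'")
  strip_root(model, lambda, b)
}

# positive root of strip_rhs by sign-change bracketing + uniroot
strip_root <- function(model, lambda, b) {
  f <- function(x) strip_rhs(x, model, lambda, b)
  xs <- seq(1e-6 * b, b * (1 - 1e-9), length.out = 400)
  vals <- f(xs)
  sgn <- sign(vals)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip)) {
    stop("no interior root of the strip force balance found")
  }
  i <- flip[1]
  stats::uniroot(f, lower = xs[i], upper = xs[i + 1], tol = 1e-12)$root
}

#' Anisotropic net forces squeezing a nucleus in the strip model
#'
#' Forces pressing on a nucleus from the sides (`f_x`) and along the cell axis
#' (`f_y`), positive for pushing: in the single file `f_x = 2 g_S(b)`,
#' `f_y = 2 f(lambda)`; in the double file, with offset `x̄` and neighbour
#' distance `d(x̄)`, `f_x = g_S(b - x̄) + g_S(b + x̄) + 4 f(d) x̄/d` and
#' `f_y = 2 f(d) lambda/d`, plus `2 f(2 lambda)` from the second neighbours in
#' the long-range variant.
#'
#' @inheritParams strip_rhs
#' @param pattern `"SF"` or `"DF"` (DF requires the single file to be unstable).
#' @param variant `"short"` (nearest neighbours only) or `"long"` (adds the
#'   second neighbours directly above and below).
#' @return named vector `c(f_x = , f_y = )`, internuclear-force units.
#' @export
shape_forces <- function(model, lambda, b, pattern = c("SF", "DF"),
                         variant = c("short", "long")) {
  pattern <- match.arg(pattern)
  variant <- match.arg(variant)
  fN <- uncut(model$internuclear)
  gS <- uncut(model$side)
  st <- sf_is_stable(model, lambda, b)
  if (pattern == "SF") {
    if (!st$stable) stop("single file is unstable for these parameters")
    fx <- 2 * evaluate_force(b, gS)
    fy <- 2 * evaluate_force(lambda, fN)
  } else {
    if (st$stable) stop("double file does not exist: single file is stable")
    xb <- df_equilibrium(model, lambda, b)
    d <- sqrt(4 * xb^2 + lambda^2)
    fx <- evaluate_force(b - xb, gS) + evaluate_force(b + xb, gS) +
      4 * evaluate_force(d, fN) * xb / d
    fy <- 2 * evaluate_force(d, fN) * lambda / d
    if (variant == "long") fy <- fy + 2 * evaluate_force(2 * lambda, fN)
  }
  c(f_x = unname(fx), f_y = unname(fy))
}

#' Predicted nuclear aspect ratio under anisotropic stress
#'
#' A deformable, area-preserving nucleus of stiffness `kappa` squeezed by
#' forces `f_x`, `f_y` takes oriented aspect ratio
#' \eqn{(\kappa - f_y)^2 / (\kappa - f_x)^2}.
#'
#' @param f_x,f_y pushing forces (negative = pulling).
#' @param kappa resistance to deformation, force units; must exceed both
#'   forces.
#' @return dimensionless aspect ratio (> 1: elongated along the cell axis).
#' @export
aspect_ratio_predicted <- function(f_x, f_y, kappa) {
  if (any(kappa <= f_x) || any(kappa <= f_y))
    stop("aspect-ratio model invalid: kappa must exceed f_x and f_y")
  (kappa - f_y)^2 / (kappa - f_x)^2
}

# per-cell strip-model aspect ratio prediction
predict_cell_ar <- function(geom, model, kappa, variant = "long") {
  lambda <- 2 * geom$half_length / (geom$n_nuclei + 1)
  b <- geom$half_width
  pattern <- if (sf_is_stable(model, lambda, b)$stable) "SF" else "DF"
  fv <- shape_forces(model, lambda, b, pattern, variant)
  aspect_ratio_predicted(fv["f_x"], fv["f_y"], kappa)
}

#' Fit the nuclear stiffness to observed aspect ratios
#'
#' Finds the stiffness `kappa` minimising the mean absolute error between the
#' strip-model aspect-ratio prediction and per-cell observed aspect ratios.
#'
#' @param cells data frame with columns `half_width`, `half_length`,
#'   `n_nuclei` and observed `ar`.
#' @param model a [model_spec()].
#' @param variant `"short"` or `"long"` second-neighbour handling.
#' @param kappa_max upper search bound.
#' @param surface_n grid size of the reported error surface.
#' @return list: `kappa`, `error` (MAE at the optimum), and the error
#'   `surface` (data frame kappa/error).
#' @export
fit_kappa <- function(cells, model, variant = c("long", "short"),
                      kappa_max = 500, surface_n = 200) {
  variant <- match.arg(variant)
  stopifnot(all(c("half_width", "half_length", "n_nuclei", "ar") %in%
                  names(cells)), nrow(cells) >= 1)
  geoms <- lapply(seq_len(nrow(cells)), function(i)
    cell_geometry(cells$half_width[i], cells$half_length[i],
                  cells$n_nuclei[i]))
  forces <- t(vapply(geoms, function(g) {
    lambda <- 2 * g$half_length / (g$n_nuclei + 1)
    pattern <- if (sf_is_stable(model, lambda, g$half_width)$stable) "SF" else "DF"
    shape_forces(model, lambda, g$half_width, pattern, variant)
  }, numeric(2)))
  kappa_min <- max(forces) + 1e-6
  if (kappa_min >= kappa_max) stop("kappa_max below the largest squeezing force")
  mae <- function(kappa) {
    pred <- (kappa - forces[, "f_y"])^2 / (kappa - forces[, "f_x"])^2
    mean(abs(pred - cells$ar))
  }
  grid <- seq(kappa_min, kappa_max, length.out = surface_n)
  surf <- data.frame(kappa = grid, error = vapply(grid, mae, numeric(1)))
  if (stats::sd(surf$error) < 1e-12)
    warning("error surface is flat: aspect-ratio predictions are degenerate")
  i <- which.min(surf$error)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(surface_n, i + 1)]
  opt <- stats::optimize(mae, lower = lo, upper = hi, tol = 1e-8)
  list(kappa = opt$minimum, error = opt$objective, surface = surf)
}
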