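#' Power-law force between a nucleus and another object
#'
#' Each interaction in the model family is a signed power law
#' \eqn{f(d) = \sigma M (d/d_{ref})^{\alpha} H(c - d)}: \code{sign}
#' (\eqn{\sigma = +1} repulsive, \eqn{-1} attractive), \code{exponent}
#' (\eqn{\alpha}; decreasing with distance for negative values), relative
#' \code{magnitude} (\eqn{M}, in units of the internuclear amplitude), a
#' finite-reach \code{cutoff} (\eqn{c}, microns; \code{Inf} reaches across the
#' cell) and the reference distance \code{ref_distance} (\eqn{d_{ref}}, the
#' typical 40 micron internuclear spacing used to nondimensionalise distance).
#'
#' @param sign +1 (repulsive) or -1 (attractive).
#' @param exponent real exponent; the model screens use -1, 0, +1.
#' @param magnitude nonnegative amplitude relative to the internuclear force.
#' @param cutoff positive reach in microns, possibly `Inf`.
#' @param ref_distance positive reference distance in microns.
#' @return A `force_law` object.
#' @examples
#' f <- force_law(+1, -1)            # repulsive, decreasing with distance
#' evaluate_force(40, f)             # 1 at the reference distance
#' @export
force_law <- function(sign, exponent, magnitude = 1, cutoff = Inf,
                      ref_distance = 40) {
  stopifnot(sign %in% c(-1, 1), is.numeric(exponent), length(exponent) == 1L,
            magnitude >= 0, cutoff > 0, ref_distance > 0)
  structure(list(sign = as.numeric(sign), exponent = as.numeric(exponent),
                 magnitude = as.numeric(magnitude), cutoff = as.numeric(cutoff),
                 ref_distance = as.numeric(ref_distance)),
            class = "force_law")
}

#' @export
print.force_law <- function(x, ...) {
  cat(sprintf("<force_law> %s, %s with distance: M = %g, alpha = %g, cutoff = %g um\n",
              if (x$sign > 0) "repulsive" else "attractive",
              if (x$exponent < 0) "decreasing" else if (x$exponent > 0) "increasing" else "constant",
              x$magnitude, x$exponent, x$cutoff))
  invisible(x)
}

#' Evaluate a power-law force at a distance
#'
#' Positive values are repulsive (directed away from the source). Beyond the
#' cutoff (and exactly at it) the force is 0; a finite reach ends with a
#' linear taper over the final 2 microns below the cutoff, so forces are
#' continuous and force-balance equilibria are well defined (a sharp cutoff
#' leaves nuclei chattering on the discontinuity with no equilibrium).
#'
#' @param d distance(s) in microns, strictly positive.
#' @param law a [force_law()].
#' @return signed force, in internuclear-force units (vectorised over `d`).
#' @export
evaluate_force <- function(d, law) {
  stopifnot(inherits(law, "force_law"))
  if (any(d <= 0)) stop("force laws are defined for strictly positive distances")
  vapply(d, cpp_power_law, numeric(1), sign = law$sign, alpha = law$exponent,
         M = law$magnitude, cutoff = law$cutoff, dref = law$ref_distance)
}

#' Size-exclusion force between centroids
#'
#' Short-range divergent repulsion \eqn{Q (1/d^2 - 1/D^2) H(D - d)} keeping
#' nuclei (effective diameter \eqn{D = 2r}) from overlapping each other, and
#' (with \eqn{D = r}) from overlapping the cell boundary.
#'
#' @param d centroid separation, microns (> 0).
#' @param effective_diameter contact distance `D`, microns.
#' @param strength exclusion amplitude `Q`.
#' @return nonnegative repulsive force (vectorised over `d`).
#' @export
size_exclusion_force <- function(d, effective_diameter, strength = 2000) {
  if (any(d <= 0)) stop("size exclusion is defined for strictly positive distances")
  vapply(d, cpp_size_exclusion, numeric(1), diam = effective_diameter,
         Q = strength)
}

#' Assemble a full positioning model
#'
#' A model combines an internuclear law `f`, a nucleus-side law `g_S` and a
#' nucleus-pole law `g_P`, plus the size-exclusion constants. The internuclear
#' amplitude is the force unit and must be 1.
#'
#' @param internuclear,side,pole [force_law()] objects.
#' @param exclusion_strength size-exclusion amplitude `Q_SE`.
#' @param nuclear_radius nuclear radius `r`, microns.
#' @return A `model_spec` object.
#' @examples
#' m2 <- model_spec(force_law(1, -1), force_law(1, -1, 2.2),
#'                  force_law(1, -1, 3.2))
#' class_key(m2)
#' @export
model_spec <- function(internuclear, side, pole,
                       exclusion_strength = 2000, nuclear_radius = 7) {
  stopifnot(inherits(internuclear, "force_law"), inherits(side, "force_law"),
            inherits(pole, "force_law"), exclusion_strength >= 0,
            nuclear_radius > 0)
  if (internuclear$magnitude != 1)
    stop("the internuclear amplitude is the force unit and must equal 1")
  structure(list(internuclear = internuclear, side = side, pole = pole,
                 exclusion_strength = as.numeric(exclusion_strength),
                 nuclear_radius = as.numeric(nuclear_radius)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> class", class_key(x), "\n")
  cat("  internuclear: "); print(x$internuclear)
  cat("  side:         "); print(x$side)
  cat("  pole:         "); print(x$pole)
  cat(sprintf("  Q_SE = %g, r = %g um\n", x$exclusion_strength, x$nuclear_radius))
  invisible(x)
}

#' Model-class key
#'
#' A model class is identified by the sign and exponent of the internuclear and
#' side laws only; pole-law and cutoff variations stay within one class.
#'
#' @param model a [model_spec()].
#' @return a single string `"sN,aN|sS,aS"`.
#' @export
class_key <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  make_class_key(model$internuclear$sign, model$internuclear$exponent,
                 model$side$sign, model$side$exponent)
}

make_class_key <- function(sign_N, alpha_N, sign_S, alpha_S) {
  sprintf("%+d,%+d|%+d,%+d", as.integer(sign_N), as.integer(alpha_N),
          as.integer(sign_S), as.integer(alpha_S))
}

#' Enumerate the model and model-class spaces
#'
#' The screen restricts signs to {-1, +1} and exponents to {-1, 0, +1}, giving
#' 2^3 x 3^3 = 216 models and 2^2 x 3^2 = 36 classes.
#'
#' @param signs,exponents values taken by each law's sign and exponent.
#' @return A data frame with one row per model (columns `sign_N`, `alpha_N`,
#'   `sign_S`, `alpha_S`, `sign_P`, `alpha_P`, `class`) or per class.
#' @export
enumerate_models <- function(signs = c(-1, 1), exponents = c(-1, 0, 1)) {
  g <- expand.grid(alpha_P = exponents, sign_P = signs,
                   alpha_S = exponents, sign_S = signs,
                   alpha_N = exponents, sign_N = signs,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("sign_N", "alpha_N", "sign_S", "alpha_S", "sign_P", "alpha_P")]
  g$class <- make_class_key(g$sign_N, g$alpha_N, g$sign_S, g$alpha_S)
  rownames(g) <- NULL
  g
}

#' @rdname enumerate_models
#' @export
enumerate_classes <- function(signs = c(-1, 1), exponents = c(-1, 0, 1)) {
  g <- expand.grid(alpha_S = exponents, sign_S = signs,
                   alpha_N = exponents, sign_N = signs,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("sign_N", "alpha_N", "sign_S", "alpha_S")]
  g$class <- make_class_key(g$sign_N, g$alpha_N, g$sign_S, g$alpha_S)
  rownames(g) <- NULL
  g
}

# flat parameter vector consumed by the C++ kernels
as_param_vector <- function(model) {
  with(model, c(internuclear$sign, internuclear$exponent, internuclear$magnitude,
                internuclear$cutoff,
                side$sign, side$exponent, side$magnitude, side$cutoff,
                pole$sign, pole$exponent, pole$magnitude, pole$cutoff,
                internuclear$ref_distance, exclusion_strength, nuclear_radius))
}

#' Flat-config serialisation of a model
#'
#' Models round-trip losslessly through a flat key-value dialect
#' (`sign_N`, `alpha_N`, ..., `M_S`, `M_P`, `c_N`, `c_S`, `c_P`, `d_ref`,
#' `Q_SE`, `r`) suitable for YAML/JSON configs; infinite cutoffs are written as
#' the string `"Inf"`.
#'
#' @param model a [model_spec()].
#' @param config a named list as produced by `model_to_config()`.
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @name model_config
#' @export
model_to_config <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  list(sign_N = model$internuclear$sign, alpha_N = model$internuclear$exponent,
       sign_S = model$side$sign, alpha_S = model$side$exponent,
       sign_P = model$pole$sign, alpha_P = model$pole$exponent,
       M_S = model$side$magnitude, M_P = model$pole$magnitude,
       c_N = model$internuclear$cutoff, c_S = model$side$cutoff,
       c_P = model$pole$cutoff, d_ref = model$internuclear$ref_distance,
       Q_SE = model$exclusion_strength, r = model$nuclear_radius)
}

#' @rdname model_config
#' @export
model_from_config <- function(config) {
  need <- c("sign_N", "alpha_N", "sign_S", "alpha_S", "sign_P", "alpha_P",
            "M_S", "M_P", "c_N", "c_S", "c_P", "d_ref", "Q_SE", "r")
  missing <- setdiff(need, names(config))
  if (length(missing)) stop("config misses keys: ", paste(missing, collapse = ", "))
  num <- function(v) if (identical(v, "Inf")) Inf else as.numeric(v)
  cf <- lapply(config[need], num)
  model_spec(
    internuclear = force_law(cf$sign_N, cf$alpha_N, 1, cf$c_N, cf$d_ref),
    side = force_law(cf$sign_S, cf$alpha_S, cf$M_S, cf$c_S, cf$d_ref),
    pole = force_law(cf$sign_P, cf$alpha_P, cf$M_P, cf$c_P, cf$d_ref),
    exclusion_strength = cf$Q_SE, nuclear_radius = cf$r)
}

#' @rdname model_config
#' @export
write_model_config <- function(model, path) {
  cf <- model_to_config(model)
  cf <- lapply(cf, function(v) if (is.infinite(v)) "Inf" else v)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(cf, path)
  } else {
    jsonlite::write_json(cf, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname model_config
#' @export
read_model_config <- function(path) {
  cf <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
        else jsonlite::read_json(path, simplifyVector = TRUE)
  model_from_config(cf)
}
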