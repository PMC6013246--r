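#' SF/DF bifurcation diagram of the strip model
#'
#' Tabulates the single-file stability and the double-file equilibrium offset
#' over a grid of axial spacings and half-widths — the phase diagram of the
#' single-to-double-file transition.
#'
#' @param model a [model_spec()].
#' @param lambda_range,b_range numeric vectors of spacings / half-widths (um).
#' @return data frame with `lambda`, `b`, `stable_SF`, `x_bar`.
#' @export
bifurcation_diagram <- function(model, lambda_range = seq(20, 80, by = 5),
                                b_range = seq(10, 60, by = 5)) {
  grid <- expand.grid(lambda = lambda_range, b = b_range)
  grid$stable_SF <- vapply(seq_len(nrow(grid)), function(i)
    sf_is_stable(model, grid$lambda[i], grid$b[i])$stable, logical(1))
  grid$x_bar <- vapply(seq_len(nrow(grid)), function(i)
    df_equilibrium(model, grid$lambda[i], grid$b[i]), numeric(1))
  grid
}

pipeline_stage_keys <- list(
  synth = c("n_cells", "populations", "jitter_sd", "model"),
  metrics = c("nnd", "classify", "correlate", "n_real"),
  screen = c("filter1", "filter2", "reduced"),
  calibrate = c("model_class", "n_grid"),
  analytics = c("model", "lambda_min", "lambda_max", "b_min", "b_max", "grid_n"))

validate_config <- function(config) {
  top_ok <- c("seed", "out_dir", "stages")
  bad <- setdiff(names(config), top_ok)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (is.null(config$seed)) stop("config must set an explicit seed")
  if (is.null(config$stages) || !length(config$stages))
    stop("config lists no stages")
  for (s in names(config$stages)) {
    if (!s %in% names(pipeline_stage_keys)) stop("unknown stage: ", s)
    bad <- setdiff(names(config$stages[[s]]), pipeline_stage_keys[[s]])
    if (length(bad))
      stop("unknown keys in stage '", s, "': ", paste(bad, collapse = ", "))
  }
  invisible(config)
}

resolve_population <- function(name) {
  switch(name, vl3 = vl3_params(), vl4 = vl4_params(),
         stop("unknown population: ", name))
}

#' Run the analysis pipeline from a config
#'
#' Executes the configured stages in dependency order (synthesise, metrics,
#' screen, calibrate, analytics), writing each stage's tables as CSV/JSON into
#' `out_dir` together with a structured log (`log.json`) carrying per-stage
#' wall time, the seed, the package version and a hash of the config. Reruns
#' with the same config and seed reproduce the same outputs. Unknown config
#' keys are rejected.
#'
#' @param config a named list, or path to a YAML/JSON config file.
#' @param out_dir output directory (created if missing); overrides the
#'   config's `out_dir`.
#' @param seed overrides the config's seed.
#' @return invisibly, the path to `out_dir`.
#' @examples
#' \donttest{
#' cfg <- system.file("extdata", "demo_config.yaml", package = "myonuc")
#' run_pipeline(cfg, out_dir = tempfile("demo"))
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  out_dir <- out_dir %||% config$out_dir %||% stop("no out_dir given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- substr(paste(
    format(sum(utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE)) *
                 seq_along(utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE)))) %% 1e9),
    collapse = ""), 1, 12)
  log <- list(seed = config$seed, config_hash = cfg_hash,
              version = as.character(utils::packageVersion("myonuc")),
              stages = list())
  seed <- as.integer(config$seed)
  stages <- config$stages
  cells <- NULL

  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    force(expr)
    log$stages[[name]] <<- list(wall_time_s = proc.time()[["elapsed"]] - t0)
  }

  if (!is.null(stages$synth)) timed("synth", {
    st <- stages$synth
    model <- if (is.null(st$model)) calibrated_model("M2")
             else model_from_config(st$model)
    pops <- lapply(st$populations %||% c("vl3", "vl4"), resolve_population)
    cells <- synthesize_cells(pops, st$n_cells %||% 10, model,
                              jitter_sd = st$jitter_sd %||% 2, seed = seed)
    cfgs <- lapply(cells, `[[`, "cfg")
    names(cfgs) <- sprintf("cell%03d", seq_along(cfgs))
    write_configurations(cfgs, file.path(out_dir, "centroids.csv"))
    geo <- do.call(rbind, lapply(cells, function(cc)
      data.frame(half_width = cc$geom$half_width,
                 half_length = cc$geom$half_length,
                 n_nuclei = cc$geom$n_nuclei)))
    geo$cell_id <- names(cfgs)
    utils::write.csv(geo, file.path(out_dir, "cells.csv"), row.names = FALSE)
  })

  if (!is.null(stages$metrics)) timed("metrics", {
    if (is.null(cells)) stop("metrics stage needs the synth stage")
    st <- stages$metrics
    if (isTRUE(st$classify %||% TRUE)) {
      labs <- vapply(cells, function(cc)
        classify_pattern(cc$cfg, cc$geom)$label, character(1))
      utils::write.csv(data.frame(cell_id = seq_along(labs), label = labs),
                       file.path(out_dir, "patterns.csv"), row.names = FALSE)
    }
    if (isTRUE(st$nnd %||% TRUE)) {
      nnd <- unlist(lapply(cells, function(cc)
        nearest_neighbor_distances(cc$cfg)))
      base <- random_nnd_baseline(cells[[1]]$geom,
                                  n_real = st$n_real %||% 200, seed = seed)
      jsonlite::write_json(
        list(mean_nnd = mean(nnd), baseline_mean_nnd =
               sum(base$mean * base$mid) / sum(base$mean)),
        file.path(out_dir, "nnd.json"), auto_unbox = TRUE, digits = NA)
    }
    if (isTRUE(st$correlate %||% FALSE)) {
      corr <- zigzag_correlations(cells)
      keep <- Filter(Negate(is.null), corr)
      rows <- do.call(rbind, lapply(keep, function(h)
        data.frame(kind = h$kind, offset = h$bin_centers, count = h$counts)))
      utils::write.csv(rows, file.path(out_dir, "correlations.csv"),
                       row.names = FALSE)
    }
    hist_xy <- positional_histograms(cells)
    utils::write.csv(data.frame(mid = hist_xy$mid, x = hist_xy$x,
                                y = hist_xy$y),
                     file.path(out_dir, "position_histograms.csv"),
                     row.names = FALSE)
  })

  if (!is.null(stages$screen)) timed("screen", {
    st <- stages$screen
    reduced <- st$reduced %||% TRUE
    if (isTRUE(st$filter1 %||% TRUE)) {
      f1 <- run_filter1(reduced = reduced, seed = seed)
      utils::write.csv(f1$records, file.path(out_dir, "filter1_records.csv"),
                       row.names = FALSE)
      jsonlite::write_json(as.list(f1$survivors),
                           file.path(out_dir, "filter1_survivors.json"))
    }
    if (isTRUE(st$filter2 %||% FALSE)) {
      f2 <- run_filter2(reduced = reduced, seed = seed)
      utils::write.csv(f2$class_summary, file.path(out_dir, "filter2_summary.csv"),
                       row.names = FALSE)
    }
  })

  if (!is.null(stages$calibrate)) timed("calibrate", {
    if (is.null(cells)) stop("calibrate stage needs the synth stage")
    st <- stages$calibrate
    cal <- calibrate(cells, model_class = st$model_class %||% "M2",
                     n_grid = st$n_grid %||% 13)
    utils::write.csv(cal$surface, file.path(out_dir, "calibration_surface.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(M_S = cal$M_S, M_P = cal$M_P, error = cal$error),
                         file.path(out_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  if (!is.null(stages$analytics)) timed("analytics", {
    st <- stages$analytics
    model <- calibrated_model(st$model %||% "M2")
    n <- st$grid_n %||% 13
    diag <- bifurcation_diagram(
      model, seq(st$lambda_min %||% 20, st$lambda_max %||% 80, length.out = n),
      seq(st$b_min %||% 10, st$b_max %||% 60, length.out = n))
    utils::write.csv(diag, file.path(out_dir, "bifurcation.csv"),
                     row.names = FALSE)
  })

  jsonlite::write_json(log, file.path(out_dir, "log.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrated positioning models
#'
#' The two surviving model families with the magnitudes obtained by
#' calibration: repulsive-decreasing internuclear and pole forces (M_P = 3.2)
#' and either attractive, linearly increasing side forces ("M1", M_S = 2.2) or
#' repulsive-decreasing side forces ("M2", M_S = 2.2), all with infinite
#' reach.
#'
#' @param which `"M1"` or `"M2"`.
#' @param M_S,M_P override the calibrated magnitudes.
#' @return a [model_spec()].
#' @export
calibrated_model <- function(which = c("M2", "M1"), M_S = 2.2, M_P = 3.2) {
  which <- match.arg(which)
  side <- if (which == "M1") force_law(-1, 1, M_S) else force_law(1, -1, M_S)
  model_spec(force_law(1, -1), side, force_law(1, -1, M_P))
}
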