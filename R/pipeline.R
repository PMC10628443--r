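#' Pipeline configuration
#'
#' Single configuration object for the end-to-end pipeline: simulator
#' settings plus the knobs of every downstream stage. Can be built from a
#' YAML file with per-stage sections (`simulate`, `extract`, `fit`) or
#' from arguments; explicit arguments override file values.
#'
#' @param file Optional path to a YAML config file.
#' @param simulate Named list passed to [simulation_config()].
#' @param extract Named list of [extract_flux()] knobs (`guard`, `smooth`,
#'   `min_coverage`, `midday`).
#' @param fit Named list of [bilinear()] knobs (`grid`, `min_seg`).
#' @param seed Integer seed for the whole run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, simulate = list(),
                            extract = list(), fit = list(), seed = NULL) {
  cfg <- list(simulate = list(), extract = list(), fit = list(),
              seed = NULL)
  if (!is.null(file)) {
    if (!file.exists(file)) stopf("config file '%s' does not exist", file)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(file))
  }
  cfg$simulate <- utils::modifyList(cfg$simulate, simulate)
  cfg$extract <- utils::modifyList(cfg$extract, extract)
  cfg$fit <- utils::modifyList(cfg$fit, fit)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(cfg$seed)) cfg$seed <- check_count(cfg$seed, "seed", lower = 0)
  # validate eagerly: a bad simulator setting must fail before any stage runs
  sim_args <- cfg$simulate
  if (!is.null(sim_args$phase_lengths))
    sim_args$phase_lengths <- unlist(sim_args$phase_lengths)
  cfg$sim_config <- do.call(simulation_config,
                            c(sim_args, list(rng_seed = cfg$seed)))
  ex_defaults <- list(guard = 6, smooth = 5, min_coverage = 0.8,
                      midday = c(15, 17))
  cfg$extract <- utils::modifyList(ex_defaults, cfg$extract)
  fit_defaults <- list(grid = 200, min_seg = 2)
  cfg$fit <- utils::modifyList(fit_defaults, cfg$fit)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> extract -> fit -> metrics -> report and writes all
#' artifacts under `out_dir`: the simulated raw data (`data/`), the tidy
#' per-plant flux table (`flux.csv`), per-cultivar bilinear fits
#' (`fits.json`), per-plant response metrics (`metrics.csv`), a cultivar
#' summary (`summary.json`), a markdown report (`report.md`) and a
#' manifest (`manifest.json`) recording seed, package version and the
#' configuration, so a rerun with the same config and seed reproduces the
#' outputs bit for bit. A failing stage aborts with the stage named;
#' artifacts of completed stages are retained.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param profiles Cultivar profiles to simulate (default
#'   [barley_profiles()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main in-memory artifacts
#'   (`experiment`, `fluxes`, `fits`, `metrics`, `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "pipeline_out",
                         profiles = barley_profiles(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  say("stage simulate")
  ex <- stage("simulate", {
    e <- simulate_experiment(config$sim_config, profiles)
    write_experiment(e, file.path(out_dir, "data"))
    e
  })

  say("stage extract")
  fluxes <- stage("extract", {
    fx <- lapply(ex$weights, function(ws)
      extract_flux(ws, events = ex$irrigation, forcing = ex$forcing,
                   pot_volume = config$sim_config$pot_volume,
                   guard = config$extract$guard,
                   smooth = config$extract$smooth,
                   min_coverage = config$extract$min_coverage,
                   midday = config$extract$midday,
                   step_min = config$sim_config$step_min))
    tab <- do.call(rbind, lapply(fx, function(f)
      cbind(plant_id = f$plant_id, f$daily)))
    write.csv(tab, file.path(out_dir, "flux.csv"), row.names = FALSE)
    fx
  })

  say("stage fit")
  fits <- stage("fit", {
    dd <- phase_dates(ex$phases, "drought")
    out <- lapply(unique(ex$design$cultivar), function(cv) {
      ids <- ex$design$plant_id[ex$design$cultivar == cv &
                                  ex$design$treatment == "drought"]
      pts <- do.call(rbind, lapply(fluxes[ids], function(f) {
        d <- f$daily[f$daily$date %in% dd & f$daily$valid &
                       !is.na(f$daily$midday_tr_g_min) &
                       !is.na(f$daily$swc_midday), ]
        data.frame(swc = d$swc_midday, tr_rate = d$midday_tr_g_min)
      }))
      if (is.null(pts) || nrow(pts) < 5L)
        return(list(cultivar = cv, status = "insufficient points",
                    n = if (is.null(pts)) 0L else nrow(pts)))
      fit <- bilinear(tr_rate ~ swc, pts, grid = config$fit$grid,
                      min_seg = config$fit$min_seg)
      rec <- list(cultivar = cv, status = fit$status,
                  tr_max = fit$tr_max, theta_crit = fit$theta_crit,
                  slope = fit$slope, r2 = fit$r_squared, n = fit$n_points)
      if (fit$status == "ok") {
        fit <- terminal_drought_point(fit, pts)
        ar <- trapezoid_area(fit)
        rec$swc_term <- fit$terminal[["swc"]]
        rec$tr_term <- fit$terminal[["tr"]]
        rec$area <- ar$analytic
        cums <- vapply(ids, function(id) {
          w <- drought_window(fluxes[[id]], fit$theta_crit, ex$phases)
          if (w$status != "ok" || !(w$from < w$to)) return(NA_real_)
          as.numeric(cumulative_transpiration_between(fluxes[[id]], w$from,
                                                      w$to))
        }, 0)
        rec$cum_transpiration <- if (all(is.na(cums))) NA_real_ else
          mean(cums, na.rm = TRUE)
      }
      rec
    })
    names(out) <- unique(ex$design$cultivar)
    jsonlite::write_json(out, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  say("stage metrics")
  metrics <- stage("metrics", {
    m <- response_metrics(fluxes, ex$design, ex$phases, ex$harvest)
    cls_in <- do.call(rbind, lapply(fits, function(f) {
      if (is.null(f$tr_max)) return(NULL)
      data.frame(cultivar = f$cultivar, tr_max = f$tr_max, slope = f$slope)
    }))
    if (!is.null(cls_in) && nrow(cls_in) >= 2L) {
      cls <- classify_water_use(cls_in)
      m$water_use_class <- cls$water_use_class[match(m$cultivar,
                                                     cls$cultivar)]
    } else {
      m$water_use_class <- NA_character_
    }
    write.csv(m, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    m
  })

  say("stage report")
  summ <- stage("report", {
    agg <- function(v, g) tapply(v, g, function(x)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
    g <- interaction(metrics$cultivar, metrics$treatment, drop = TRUE)
    summ <- list(
      groups = levels(g),
      mean_daily_tr = as.list(agg(metrics$dtr_drought, g)),
      mean_rtr_drought = as.list(agg(metrics$rtr_drought, g)),
      mean_recovery_rate = as.list(agg(metrics$recovery_rate, g)),
      mean_wue_grain = as.list(agg(metrics$wue_grain_g_kg, g)))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    lines <- c("# Water-relations pipeline report", "",
               sprintf("- plants: %d; cultivars: %s", nrow(ex$design),
                       paste(unique(ex$design$cultivar), collapse = ", ")),
               "", "## Bilinear fits (drought-phase midday points)", "",
               "| cultivar | status | TRmax | theta_crit | slope | R2 | area |",
               "|---|---|---|---|---|---|---|")
    for (f in fits) {
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %s | %s | %s | %s |", f$cultivar, f$status,
        if (is.null(f$tr_max)) "-" else sprintf("%.3f", f$tr_max),
        if (is.null(f$theta_crit)) "-" else sprintf("%.3f", f$theta_crit),
        if (is.null(f$slope)) "-" else sprintf("%.3f", f$slope),
        if (is.null(f$r2) || is.na(f$r2)) "-" else sprintf("%.3f", f$r2),
        if (is.null(f$area)) "-" else sprintf("%.4f", f$area)))
    }
    writeLines(lines, file.path(out_dir, "report.md"))
    summ
  })

  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(list(simulate = unclass(config$sim_config),
                            extract = config$extract, fit = config$fit),
                       cfg_json, auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = config$seed,
                   package = as.character(utils::packageVersion("droughtflux")),
                   r_version = R.version.string,
                   config_md5 = unname(md5sum(cfg_json)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("pipeline complete: ", out_dir)
  invisible(list(experiment = ex, fluxes = fluxes, fits = fits,
                 metrics = metrics, summary = summ, dir = out_dir))
}
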