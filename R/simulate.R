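#' Simulate a gravimetric feedback deficit-irrigation experiment
#'
#' Generates a complete synthetic lysimeter-array run with known ground
#' truth. Each plant is a water-balance state: at every measurement step the
#' pot loses the cultivar's transpiration demand (piecewise-linear in soil
#' water content, VPD-scaled, photoperiod-gated; demand is capped by the
#' water available above the wilting floor) and gains discrete nocturnal
#' irrigation pulses. Well-watered (control) plants are refilled to pot
#' capacity every evening; drought-phase plants instead receive
#' `deficit_fraction` (default 80%) of their own previous-day transpiration
#' in the early-morning pulse window, so the soil dries gradually under the
#' plant's own feedback. The recovery phase starts with a refill to capacity
#' and a stress-carryover factor that increases linearly at the cultivar's
#' configured `recovery_rate`; post-recovery irrigation is slightly reduced.
#' Soil evaporation is exactly zero (covered soil), so all weight loss is
#' transpiration. Measurement noise is i.i.d. Gaussian on each weight
#' record and does not feed back into the water state, so water
#' conservation holds exactly at `noise_sd = 0`.
#'
#' @param config A [simulation_config()].
#' @param profiles A list of [cultivar_profile] objects (or a single one).
#'
#' @return An object of class `gravimetric_experiment`: a list with
#'   elements `weights` (named list of [weight_series] objects),
#'   `irrigation` (data frame `time`, `plant_id`, `dose_g`), `forcing`
#'   (the [generate_forcing()] series), `design` (plant/cultivar/treatment
#'   table), `phases` (a [phase_calendar()]), `harvest` (per-plant harvest
#'   table), `truth` (ground-truth record: profiles, tare, pot volume,
#'   per-plant daily true transpiration and day-start soil water content,
#'   cumulative transpiration), and `config`.
#' @examples
#' cfg <- simulation_config(n_control = 1, n_drought = 1,
#'                          phase_lengths = c(pre_drought = 1, drought = 2,
#'                                            recovery = 1, post_recovery = 1),
#'                          noise_sd = 0, rng_seed = 1)
#' ex <- simulate_experiment(cfg, barley_profiles()["CHAN"])
#' head(ex$truth$daily)
#' @export
simulate_experiment <- function(config = simulation_config(),
                                profiles = barley_profiles()) {
  stopifnot(inherits(config, "simulation_config"))
  if (inherits(profiles, "cultivar_profile")) profiles <- list(profiles)
  if (!length(profiles)) stopf("at least one cultivar profile is required")
  if (!all(vapply(profiles, inherits, TRUE, "cultivar_profile")))
    stopf("'profiles' must be cultivar_profile objects")

  V <- config$pot_volume
  capW <- config$pot_capacity * V
  floorW <- config$wilt_swc * V
  photo_min <- hm_to_min(config$photoperiod[2L]) -
    hm_to_min(config$photoperiod[1L])
  fmax <- (config$vpd_mean + config$vpd_amplitude) / config$vpd_mean
  for (p in profiles) {
    peak_daily <- p$tr_max * fmax *
      (photo_min + config$night_fraction * (1440 - photo_min))
    if (peak_daily > capW - floorW)
      stopf("cultivar '%s': peak daily demand (%.0f g) exceeds the water available above the wilting floor (%.0f g); the nightly refill cannot sustain it",
            p$name, peak_daily, capW - floorW)
  }

  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  forcing <- generate_forcing(config)

  design <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      plant_id = c(sprintf("%s-C%d", p$name, seq_len(config$n_control)),
                   sprintf("%s-D%d", p$name, seq_len(config$n_drought))),
      cultivar = p$name,
      treatment = rep(c("control", "drought"),
                      c(config$n_control, config$n_drought)),
      row.names = NULL)
  }))
  P <- nrow(design)
  prof_of <- match(design$cultivar, vapply(profiles, `[[`, "", "name"))
  trm <- vapply(profiles, `[[`, 0, "tr_max")[prof_of]
  thc <- vapply(profiles, `[[`, 0, "theta_crit")[prof_of]
  slp <- vapply(profiles, `[[`, 0, "decline_slope")[prof_of]
  rrate <- vapply(profiles, `[[`, 0, "recovery_rate")[prof_of]
  is_drought <- design$treatment == "drought"

  per_day <- 1440L %/% config$step_min
  n_days <- sum(config$phase_lengths)
  phases <- phase_calendar(config$start_date, config$phase_lengths)
  dates <- seq(as.Date(config$start_date), by = "day", length.out = n_days)
  ph <- phase_of(phases, dates)
  rec_start <- which(ph == "recovery")[1L]

  N <- nrow(forcing)
  times <- forcing$time
  vpd <- forcing$vpd
  light <- forcing$light_on
  mod <- minute_of_day(times)
  dayi <- c(rep(seq_len(n_days), each = per_day), n_days + 1L)
  dt <- config$step_min
  nf <- config$night_fraction
  vref <- config$vpd_mean
  np <- config$n_pulses
  evening_set <- 60 * (21L + seq_len(np) - 1L)
  early_set <- 60 * (1L + seq_len(np))

  # evening refill fraction per day x plant
  frac_evening <- matrix(0, n_days, P)
  for (d in seq_len(n_days)) {
    frac_evening[d, ] <- switch(ph[d],
      pre_drought = 1,
      drought = ifelse(is_drought, 0, 1),
      recovery = 1,
      post_recovery = config$post_recovery_fraction)
  }

  W <- rep(capW, P)
  Wmat <- matrix(NA_real_, N, P)
  dailyT <- matrix(0, n_days, P, dimnames = list(NULL, design$plant_id))
  factor_row <- rep(1, P)
  r0 <- NULL
  ev_time <- list(); ev_plant <- list(); ev_dose <- list(); ev_k <- 0L

  ctrl_mean_by_cultivar <- function(v) {
    means <- tapply(v[!is_drought], design$cultivar[!is_drought], mean)
    as.numeric(means[design$cultivar])
  }

  for (i in seq_len(N - 1L)) {
    Wmat[i, ] <- W
    d <- dayi[i]
    m <- mod[i]
    if (m == 0 && d >= rec_start) {
      if (is.null(r0)) {
        ld <- rec_start - 1L
        r0 <- ifelse(is_drought,
                     dailyT[ld, ] / ctrl_mean_by_cultivar(dailyT[ld, ]), 1)
      }
      # stress carryover: recovery starts below the end-of-drought relative
      # transpiration (stomatal reopening takes days), then climbs linearly
      factor_row <- ifelse(is_drought,
                           pmin(1, config$recovery_depression * r0 +
                                  rrate * (d - rec_start + 1L)), 1)
    }
    dose <- NULL
    if (m %in% evening_set) {
      k <- np - match(m, evening_set) + 1L
      frac <- frac_evening[d, ]
      if (any(frac > 0)) {
        dose <- frac * pmax(0, capW - W) / k
      }
    } else if (m %in% early_set) {
      j <- match(m, early_set)
      if (ph[d] == "drought") {
        tot <- config$deficit_fraction * dailyT[d - 1L, ]
        dosev <- tot * j / np - tot * (j - 1L) / np
        dose <- ifelse(is_drought, dosev, 0)
      } else if (d == rec_start) {
        # re-irrigation at recovery onset: refill before the photoperiod
        dose <- ifelse(is_drought, pmax(0, capW - W) / (np - j + 1L), 0)
      }
    }
    swc <- W / V
    base <- pmax(0, trm - slp * pmax(0, thc - swc))
    rate <- base * (vpd[i] / vref) * (if (light[i]) 1 else nf) * factor_row
    tr <- pmin(rate * dt, pmax(0, W - floorW))
    W <- W - tr
    if (!is.null(dose)) {
      sel <- dose > 0
      if (any(sel)) {
        ev_k <- ev_k + 1L
        ev_time[[ev_k]] <- rep(times[i] + 90, sum(sel))
        ev_plant[[ev_k]] <- design$plant_id[sel]
        ev_dose[[ev_k]] <- dose[sel]
        W <- W + dose
      }
    }
    dailyT[d, ] <- dailyT[d, ] + tr
  }
  Wmat[N, ] <- W

  irrigation <- if (ev_k > 0L) {
    data.frame(time = do.call(c, ev_time),
               plant_id = unlist(ev_plant),
               dose_g = unlist(ev_dose), row.names = NULL)
  } else {
    data.frame(time = as_utc(character()), plant_id = character(),
               dose_g = numeric())
  }

  Wrec <- config$tare + Wmat
  if (config$noise_sd > 0)
    Wrec <- Wrec + matrix(rnorm(N * P, 0, config$noise_sd), N, P)

  weights <- lapply(seq_len(P), function(p) {
    weight_series(design$plant_id[p],
                  data.frame(time = times, weight_g = Wrec[, p]),
                  tare = config$tare)
  })
  names(weights) <- design$plant_id

  day_start_idx <- (seq_len(n_days) - 1L) * per_day + 1L
  truth_daily <- data.frame(
    plant_id = rep(design$plant_id, each = n_days),
    date = rep(dates, P),
    transpiration_g = as.vector(dailyT),
    swc_start = as.vector(Wmat[day_start_idx, , drop = FALSE] / V),
    row.names = NULL)

  cum_t <- colSums(dailyT)
  ctrl_cum <- ctrl_mean_by_cultivar(cum_t)
  rel_deficit <- pmax(0, 1 - cum_t / ctrl_cum)
  hi <- vapply(profiles, `[[`, 0, "harvest_index")[prof_of]
  bpot <- vapply(profiles, `[[`, 0, "biomass_potential")[prof_of]
  biomass <- pmax(0, bpot * (1 - config$drought_penalty * rel_deficit) *
                    (1 + rnorm(P, 0, config$harvest_cv)))
  grain <- hi * biomass
  tkw <- 48 * (1 + rnorm(P, 0, config$harvest_cv / 2))
  seeds_per_spike <- 12 * (1 + rnorm(P, 0, config$harvest_cv))
  harvest <- data.frame(
    plant_id = design$plant_id, cultivar = design$cultivar,
    treatment = design$treatment, biomass_g = biomass, grain_g = grain,
    tkw_g = tkw, seeds_per_spike = seeds_per_spike,
    spikes_per_pot = grain / (tkw / 1000) / seeds_per_spike,
    row.names = NULL)

  structure(list(
    weights = weights, irrigation = irrigation, forcing = forcing,
    design = design, phases = phases, harvest = harvest,
    truth = list(profiles = profiles, tare = config$tare,
                 pot_volume = V, daily = truth_daily,
                 cumulative = cum_t, recovery_r0 = if (!is.null(r0))
                   stats::setNames(r0, design$plant_id)),
    config = config), class = "gravimetric_experiment")
}

#' @export
print.gravimetric_experiment <- function(x, ...) {
  cat(sprintf(
    "Gravimetric experiment: %d plants (%d cultivars), %d days, %d weight records/plant,\n  %d irrigation events, weight noise sd %.2f g\n",
    nrow(x$design), length(unique(x$design$cultivar)),
    sum(x$config$phase_lengths), nrow(x$weights[[1L]]$data),
    nrow(x$irrigation), x$config$noise_sd))
  invisible(x)
}

#' Write a simulated experiment to delimited text files
#'
#' Writes one weight CSV per plant (`weights/<plant_id>.csv` with ISO-8601
#' timestamps), plus `irrigation.csv`, `forcing.csv`, `design.csv`,
#' `phases.csv`, `harvest.csv` and the ground truth as `truth.json`.
#'
#' @param x A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_experiment <- function(x, dir) {
  stopifnot(inherits(x, "gravimetric_experiment"))
  dir.create(file.path(dir, "weights"), recursive = TRUE,
             showWarnings = FALSE)
  fmt_t <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  for (ws in x$weights) {
    write.csv(data.frame(time = fmt_t(ws$data$time),
                         weight_g = ws$data$weight_g),
              file.path(dir, "weights", paste0(ws$plant_id, ".csv")),
              row.names = FALSE)
  }
  irr <- x$irrigation
  irr$time <- fmt_t(irr$time)
  write.csv(irr, file.path(dir, "irrigation.csv"), row.names = FALSE)
  fo <- as.data.frame(x$forcing)
  fo$time <- fmt_t(fo$time)
  write.csv(fo, file.path(dir, "forcing.csv"), row.names = FALSE)
  write.csv(x$design, file.path(dir, "design.csv"), row.names = FALSE)
  write.csv(as.data.frame(x$phases), file.path(dir, "phases.csv"),
            row.names = FALSE)
  write.csv(x$harvest, file.path(dir, "harvest.csv"), row.names = FALSE)
  tr <- x$truth
  tr$daily$date <- as.character(tr$daily$date)
  tr$profiles <- lapply(tr$profiles, unclass)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
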