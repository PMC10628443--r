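#' Configuration of a synthetic gravimetric drought experiment
#'
#' Collects the design and physical constants of a simulated lysimeter-array
#' run. Defaults reproduce the reference experiment: 3-L pots holding
#' 1,250 g of potting mix with a pot capacity (water-holding capacity after
#' free drainage) of 0.70 volumetric, four well-watered and five
#' drought-stressed replicates per cultivar, phases of 7 (pre-drought),
#' 12 (drought), 10 (recovery) and 10 (post-recovery) days, drought imposed
#' as feedback deficit irrigation delivering 80% of each plant's own
#' previous-day transpiration, a 05:30-18:00 photoperiod and VPD
#' fluctuating between 0.8 and 2.4 kPa around a mean of 1.7 kPa.
#'
#' @param n_control,n_drought Replicates per cultivar in each treatment.
#' @param phase_lengths Named lengths (days) of the four phases, in order
#'   pre_drought, drought, recovery, post_recovery; each >= 1.
#' @param pot_capacity Volumetric soil water content at free drainage.
#' @param soil_mass Dry potting-mix mass, g.
#' @param pot_volume Pot volume, cm^3 (water density 1 g/cm^3).
#' @param deficit_fraction Fraction of previous-day transpiration returned
#'   as irrigation during the drought phase; in (0, 1].
#' @param noise_sd Standard deviation of i.i.d. Gaussian weight-record
#'   noise, g.
#' @param vpd_mean,vpd_amplitude Mean and diurnal amplitude of the VPD
#'   sinusoid, kPa.
#' @param vpd_noise_sd Standard deviation of Gaussian VPD noise, kPa.
#' @param vpd_peak_hour Hour of day at which VPD peaks.
#' @param vpd_range Admissible VPD range (values are clipped to it), kPa.
#' @param photoperiod Character vector `c(start, end)` of the light period,
#'   "HH:MM".
#' @param night_fraction Nighttime transpiration demand as a fraction of
#'   the VPD-scaled daytime demand.
#' @param n_pulses Number of discrete nocturnal irrigation pulses (1-3).
#' @param wilt_swc Volumetric soil water content below which no further
#'   water can be extracted.
#' @param recovery_depression Post-rewatering depression: the fraction of
#'   the end-of-drought relative transpiration at which the recovery ramp
#'   starts. Re-watered plants do not resume their end-of-drought relative
#'   transpiration immediately (stomatal reopening and hydraulic repair
#'   take days), so relative transpiration drops at recovery onset and
#'   then climbs linearly at the cultivar's `recovery_rate`.
#' @param post_recovery_fraction Fraction of the refill-to-capacity dose
#'   delivered during the post-recovery phase (slightly reduced irrigation
#'   for maturing plants).
#' @param tare Dry system weight (pot + soil + sensors + plant), g; emitted
#'   in the ground truth so that extraction is exactly invertible.
#' @param start_date First day of the run (character or Date).
#' @param step_min Measurement interval, minutes.
#' @param drought_penalty Proportionality constant linking the relative
#'   cumulative-transpiration deficit to biomass loss in harvest synthesis.
#' @param harvest_cv Coefficient of variation of harvest noise.
#' @param rng_seed Integer seed; `NULL` leaves the RNG state untouched.
#'
#' @return An object of class `simulation_config`.
#' @seealso [simulate_experiment()], [generate_forcing()]
#' @export
simulation_config <- function(n_control = 4, n_drought = 5,
                              phase_lengths = c(pre_drought = 7, drought = 12,
                                                recovery = 10,
                                                post_recovery = 10),
                              pot_capacity = 0.70, soil_mass = 1250,
                              pot_volume = 3000, deficit_fraction = 0.80,
                              noise_sd = 0.5, vpd_mean = 1.7,
                              vpd_amplitude = 0.7, vpd_noise_sd = 0.05,
                              vpd_peak_hour = 14, vpd_range = c(0.8, 2.4),
                              photoperiod = c("05:30", "18:00"),
                              night_fraction = 0.05, n_pulses = 3,
                              wilt_swc = 0.05, recovery_depression = 0.7,
                              post_recovery_fraction = 0.9,
                              tare = 2000, start_date = "2023-01-27",
                              step_min = 3, drought_penalty = 0.5,
                              harvest_cv = 0.05, rng_seed = NULL) {
  n_control <- check_count(n_control, "n_control")
  n_drought <- check_count(n_drought, "n_drought")
  if (length(phase_lengths) != 4L)
    stopf("'phase_lengths' must give the four phase durations")
  if (is.null(names(phase_lengths)) || !all(nzchar(names(phase_lengths))))
    names(phase_lengths) <- c("pre_drought", "drought", "recovery",
                              "post_recovery")
  if (any(phase_lengths < 1) || any(phase_lengths != round(phase_lengths)))
    stopf("all phase lengths must be whole numbers of days >= 1")
  check_number(pot_capacity, "pot_capacity", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(soil_mass, "soil_mass", lower = 0, strict_lower = TRUE)
  check_number(pot_volume, "pot_volume", lower = 0, strict_lower = TRUE)
  check_number(deficit_fraction, "deficit_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(vpd_mean, "vpd_mean", lower = 0, strict_lower = TRUE)
  check_number(vpd_amplitude, "vpd_amplitude", lower = 0)
  check_number(vpd_noise_sd, "vpd_noise_sd", lower = 0)
  check_number(wilt_swc, "wilt_swc", lower = 0, upper = 1, strict_upper = TRUE)
  if (wilt_swc >= pot_capacity)
    stopf("'wilt_swc' must be below 'pot_capacity'")
  check_number(recovery_depression, "recovery_depression", lower = 0,
               upper = 1, strict_lower = TRUE)
  check_number(post_recovery_fraction, "post_recovery_fraction",
               lower = 0, upper = 1)
  n_pulses <- check_count(n_pulses, "n_pulses")
  if (n_pulses > 3L) stopf("'n_pulses' must be between 1 and 3")
  check_number(tare, "tare", lower = 0, strict_lower = TRUE)
  step_min <- check_count(step_min, "step_min")
  if (1440L %% step_min != 0L)
    stopf("'step_min' must divide a day evenly")
  check_number(night_fraction, "night_fraction", lower = 0, upper = 1)
  check_number(drought_penalty, "drought_penalty", lower = 0, upper = 1)
  check_number(harvest_cv, "harvest_cv", lower = 0)
  if (!is.null(rng_seed)) rng_seed <- check_count(rng_seed, "rng_seed",
                                                  lower = 0)
  structure(list(
    n_control = n_control, n_drought = n_drought,
    phase_lengths = phase_lengths, pot_capacity = pot_capacity,
    soil_mass = soil_mass, pot_volume = pot_volume,
    deficit_fraction = deficit_fraction, noise_sd = noise_sd,
    vpd_mean = vpd_mean, vpd_amplitude = vpd_amplitude,
    vpd_noise_sd = vpd_noise_sd, vpd_peak_hour = vpd_peak_hour,
    vpd_range = vpd_range, photoperiod = photoperiod,
    night_fraction = night_fraction, n_pulses = n_pulses,
    wilt_swc = wilt_swc, recovery_depression = recovery_depression,
    post_recovery_fraction = post_recovery_fraction,
    tare = tare, start_date = as.character(start_date), step_min = step_min,
    drought_penalty = drought_penalty, harvest_cv = harvest_cv,
    rng_seed = rng_seed), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d+%d plants/cultivar, phases %s days, pot %g cm3 @ capacity %.2f,\n  deficit %.0f%%, weight noise sd %.2f g, start %s\n",
    x$n_control, x$n_drought, paste(x$phase_lengths, collapse = "/"),
    x$pot_volume, x$pot_capacity, 100 * x$deficit_fraction, x$noise_sd,
    x$start_date))
  invisible(x)
}

#' Generate atmospheric forcing for a simulated run
#'
#' Produces one record per measurement step for the whole run: a smooth
#' diurnal VPD sinusoid (mean `vpd_mean`, amplitude `vpd_amplitude`,
#' peaking at `vpd_peak_hour`) with optional Gaussian noise clipped to
#' `vpd_range`, a photoperiod light flag, and a two-level day/night
#' temperature. With the default seed handling the series is reproducible:
#' the same `rng_seed` yields an identical series.
#'
#' @param config A [simulation_config()].
#' @return A data frame of class `forcing_series` with columns `time`
#'   (POSIXct UTC), `vpd` (kPa), `light_on` (logical) and `temperature`
#'   (degrees C); one row per step plus a terminal record.
#' @examples
#' f <- generate_forcing(simulation_config(rng_seed = 1))
#' mean(f$vpd)
#' @export
generate_forcing <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(config$phase_lengths < 1))
    stopf("phase lengths must be positive")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  per_day <- 1440L %/% config$step_min
  n_days <- sum(config$phase_lengths)
  n <- n_days * per_day + 1L
  t0 <- as_utc(paste(config$start_date, "00:00:00"))
  times <- t0 + (seq_len(n) - 1L) * config$step_min * 60
  h <- minute_of_day(times) / 60
  vpd <- config$vpd_mean +
    config$vpd_amplitude * cos(2 * pi * (h - config$vpd_peak_hour) / 24)
  if (config$vpd_noise_sd > 0)
    vpd <- vpd + rnorm(n, 0, config$vpd_noise_sd)
  vpd <- pmin(pmax(vpd, config$vpd_range[1L]), config$vpd_range[2L])
  m <- minute_of_day(times)
  light_on <- m >= hm_to_min(config$photoperiod[1L]) &
    m < hm_to_min(config$photoperiod[2L])
  out <- data.frame(time = times, vpd = vpd, light_on = light_on,
                    temperature = ifelse(light_on, 23, 18))
  class(out) <- c("forcing_series", "data.frame")
  out
}
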