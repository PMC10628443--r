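# fixtures are generated in code; nothing is read from disk

# small, fast experiment for unit tests
tiny_config <- function(...) {
  defaults <- list(
    n_control = 2, n_drought = 2,
    phase_lengths = c(pre_drought = 2, drought = 4, recovery = 3,
                      post_recovery = 2),
    noise_sd = 0, vpd_noise_sd = 0, rng_seed = 42)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# full-size noiseless reference run, cached across test files
.sim_cache <- new.env(parent = emptyenv())
default_noiseless_sim <- function() {
  if (is.null(.sim_cache$ex))
    .sim_cache$ex <- simulate_experiment(
      simulation_config(noise_sd = 0, rng_seed = 101))
  .sim_cache$ex
}

# weight trace with a prescribed interval transpiration-rate profile
# (rates in g/min at each step start); optional irrigation doses by index
series_from_rates <- function(rates, step_min = 3, tare = 2000, w0 = 4100,
                              start = "2023-01-27 00:00:00",
                              doses = numeric(length(rates)),
                              plant_id = "P1") {
  t0 <- as.POSIXct(start, tz = "UTC")
  times <- t0 + (0:length(rates)) * step_min * 60
  w <- w0 + cumsum(c(0, -rates * step_min + doses))
  weight_series(plant_id, data.frame(time = times, weight_g = w),
                tare = tare)
}

# minimal plant_flux carrying only a daily table
flux_from_daily <- function(daily, plant_id = "P1") {
  structure(list(plant_id = plant_id, interval = NULL, swc = NULL,
                 daily = daily, params = list()), class = "plant_flux")
}
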