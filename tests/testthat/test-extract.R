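test_that("a linear weight decline yields the constant rate it encodes", {
  # 30 g over 60 min -> 0.5 g/min
  ws <- series_from_rates(rep(0.5, 20))
  tr <- interval_transpiration(ws)
  expect_equal(tr$rate_g_min, rep(0.5, 20))
  # constant weight -> zero flux
  ws0 <- series_from_rates(rep(0, 20))
  expect_equal(interval_transpiration(ws0)$rate_g_min, rep(0, 20))
})

test_that("integrated transpiration over an event-free span equals the weight drop", {
  set.seed(3)
  rates <- pmax(0, 0.4 + 0.2 * sin(seq(0, 4 * pi, length.out = 100)) +
                  rnorm(100, 0, 0.05))
  ws <- series_from_rates(rates)
  tr <- interval_transpiration(ws, smooth = 0, clip = FALSE)
  w <- ws$data$weight_g
  expect_equal(sum(tr$rate_g_min * 3), w[1] - w[length(w)],
               tolerance = 1e-10)
})

test_that("an irrigation event changes no extracted rate outside its guard window", {
  rates <- 0.3 + 0.2 * sin(seq(0, 2 * pi, length.out = 200))
  ws_plain <- series_from_rates(rates)
  doses <- numeric(200)
  doses[100] <- 150
  ws_event <- series_from_rates(rates, doses = doses)
  ev <- data.frame(time = ws_event$data$time[100] + 90, plant_id = "P1",
                   dose_g = 150)
  tr_plain <- interval_transpiration(ws_plain)
  tr_event <- interval_transpiration(ws_event, events = ev, guard = 6)
  # guard masks the event interval plus two records on each side
  expect_equal(nrow(tr_event), nrow(tr_plain) - 5)
  common <- merge(tr_plain, tr_event, by = "time")
  expect_equal(common$rate_g_min.x, common$rate_g_min.y)
  # weight-gain interval never surfaces as a rate
  expect_true(all(tr_event$rate_g_min >= 0))
})

test_that("daily totals bridge irrigation windows by mass balance", {
  rates <- rep(0.2, 480)  # one full day
  doses <- numeric(480)
  doses[60] <- 100  # 02:57 dose, within the night
  ws <- series_from_rates(rates, doses = doses, w0 = 4100)
  ev <- data.frame(time = ws$data$time[60] + 90, plant_id = "P1",
                   dose_g = 100)
  fl <- extract_flux(ws, events = ev, pot_volume = 3000, smooth = 0)
  expect_equal(fl$daily$daily_tr_g[1], 0.2 * 3 * 480, tolerance = 1e-9)
})

test_that("volumetric SWC converts weight with the documented formula", {
  ws <- series_from_rates(rep(0, 5), w0 = 2000 + 0.70 * 3000, tare = 2000)
  swc <- volumetric_swc(ws, pot_volume = 3000)
  expect_equal(swc$swc, rep(0.70, 6))
  # dry system -> zero
  ws0 <- series_from_rates(rep(0, 5), w0 = 2000, tare = 2000)
  expect_equal(volumetric_swc(ws0, pot_volume = 3000)$swc, rep(0, 6))
  # invariant to a common shift of weights and tare
  ws_shift <- series_from_rates(rep(0, 5), w0 = 2500 + 0.70 * 3000,
                                tare = 2500)
  expect_equal(volumetric_swc(ws_shift, pot_volume = 3000)$swc, swc$swc)
})

test_that("midday rate averages the window of a diurnal ramp", {
  m <- (as.numeric(series_from_rates(rep(0, 480))$data$time[1:480]) %/% 60) %% 1440
  ramp <- ifelse(m >= 330 & m < 1080, (m - 330) / 750, 0)
  ws <- series_from_rates(ramp)
  fl <- extract_flux(ws, pot_volume = 3000, smooth = 0)
  starts <- m[m >= 900 & m < 1020]
  expect_equal(midday_rate(fl, fl$daily$date[1]),
               mean((starts - 330) / 750), tolerance = 1e-10)
  # constant rate all day -> the window mean is that rate
  flc <- extract_flux(series_from_rates(rep(0.5, 480)), pot_volume = 3000)
  expect_equal(midday_rate(flc, flc$daily$date[1]), 0.5)
})

test_that("a window fully masked by irrigation guards yields a missing midday rate", {
  rates <- rep(0.3, 480)
  # events every 12 min across 15:00-17:00 mask the whole window
  idx <- which(seq_len(480) %% 4 == 0)
  idx <- idx[idx * 3 >= 900 & idx * 3 <= 1030]
  ws <- series_from_rates(rates)
  ev <- data.frame(time = ws$data$time[idx] + 90,
                   plant_id = "P1", dose_g = 1)
  ws2 <- series_from_rates(rates, doses = replace(numeric(480), idx, 1))
  fl <- extract_flux(ws2, events = ev, pot_volume = 3000)
  expect_true(is.na(midday_rate(fl, fl$daily$date[1])))
})

test_that("days failing the coverage rule are flagged missing", {
  rates <- rep(0.3, 960)  # two days
  ws <- series_from_rates(rates)
  keep <- rep(TRUE, nrow(ws$data))
  day2 <- which(as.Date(ws$data$time, tz = "UTC") ==
                  as.Date(ws$data$time[500], tz = "UTC"))
  drop <- sample(day2, floor(0.4 * length(day2)))
  keep[drop] <- FALSE
  ws_gappy <- weight_series("P1", ws$data[keep, ], tare = 2000)
  fl <- extract_flux(ws_gappy, pot_volume = 3000, min_coverage = 0.8)
  d <- fl$daily
  expect_true(d$valid[1])
  expect_false(d$valid[2])
  expect_true(is.na(daily_transpiration(fl, d$date[2])))
  expect_error(daily_transpiration(fl, as.Date("1999-01-01")), "not covered")
})

test_that("canopy conductance is the daytime mean rate per unit VPD", {
  ws <- series_from_rates(rep(0.5, 480))
  times <- ws$data$time
  m <- (as.numeric(times) %/% 60) %% 1440
  forcing2 <- data.frame(time = times, vpd = 2, light_on = m >= 330 & m < 1080)
  fl <- extract_flux(ws, forcing = forcing2, pot_volume = 3000)
  d1 <- fl$daily$date[1]
  expect_equal(canopy_conductance(fl, forcing2, d1), 0.25)
  forcing4 <- transform(forcing2, vpd = 4)
  expect_equal(canopy_conductance(fl, forcing4, d1), 0.125)
})

test_that("extraction recovers simulator ground truth exactly at zero noise", {
  ex <- simulate_experiment(tiny_config())
  for (pid in c("CHAN-D1", "CHAN-C1", "BAR-D2")) {
    fl <- extract_flux(ex$weights[[pid]], events = ex$irrigation,
                       pot_volume = ex$config$pot_volume, smooth = 0)
    tr <- ex$truth$daily[ex$truth$daily$plant_id == pid, ]
    m <- merge(fl$daily[fl$daily$valid, ], tr, by = "date")
    expect_equal(nrow(m), sum(ex$config$phase_lengths))
    expect_lt(max(abs(m$daily_tr_g - m$transpiration_g)), 1e-8)
    # SWC trace matches the simulator state
    swc <- volumetric_swc(ex$weights[[pid]], ex$config$pot_volume)
    i0 <- match(as.numeric(as.Date(tr$date)),
                as.numeric(as.Date(swc$time, tz = "UTC")))
    expect_lt(max(abs(swc$swc[i0] - tr$swc_start)), 1e-10)
  }
})

test_that("malformed inputs are rejected", {
  expect_error(weight_series("P1", data.frame(time = numeric(),
                                              weight_g = numeric()),
                             tare = 0), "empty")
  ws <- series_from_rates(rep(0.5, 10))
  ev <- data.frame(time = ws$data$time[1] - 86400, plant_id = "P1",
                   dose_g = 5)
  expect_error(interval_transpiration(ws, events = ev), "outside the time span")
  bad <- data.frame(time = ws$data$time[c(1, 2, 2)],
                    weight_g = c(3, 2, 1) + 2000)
  expect_error(weight_series("P1", bad, tare = 2000), "increasing")
})
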