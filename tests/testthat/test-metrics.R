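mk_daily <- function(dates, tr, valid = TRUE) {
  data.frame(date = dates, daily_tr_g = tr,
             coverage = ifelse(valid, 1, 0.5), valid = valid,
             midday_tr_g_min = NA_real_, swc_midday = NA_real_,
             canopy_conductance = NA_real_)
}

test_that("relative transpiration normalises by the same-day control mean", {
  dates <- as.Date("2023-02-03") + 0:9
  ctrl1 <- flux_from_daily(mk_daily(dates, 700), "C1")
  ctrl2 <- flux_from_daily(mk_daily(dates, 689.28), "C2")
  dr <- flux_from_daily(mk_daily(dates, 402.89), "D1")
  rtr <- relative_transpiration(dr, list(ctrl1, ctrl2))
  expect_equal(rtr$rtr, rep(402.89 / 694.64, 10), tolerance = 1e-12)
  expect_equal(round(rtr$rtr[1], 2), 0.58)
  # a drought plant transpiring the control mean scores 1 every day
  same <- flux_from_daily(mk_daily(dates, 694.64), "D2")
  expect_equal(relative_transpiration(same, list(ctrl1, ctrl2))$rtr,
               rep(1, 10))
  # dates with no valid control mean are absent from the output
  ctrl_gappy <- flux_from_daily(mk_daily(dates, 700,
                                         valid = c(FALSE, rep(TRUE, 9))),
                                "C3")
  rtr2 <- relative_transpiration(dr, list(ctrl_gappy))
  expect_equal(nrow(rtr2), 9)
  expect_false(dates[1] %in% rtr2$date)
})

test_that("control plants' rTR against their own cultivar mean averages to 1", {
  dates <- as.Date("2023-02-03") + 0:5
  set.seed(2)
  ctrls <- lapply(1:4, function(i)
    flux_from_daily(mk_daily(dates, runif(6, 400, 700)), paste0("C", i)))
  rtrs <- vapply(ctrls, function(f)
    relative_transpiration(f, ctrls)$rtr, numeric(6))
  expect_equal(rowMeans(rtrs), rep(1, 6), tolerance = 1e-12)
})

test_that("the recovery rate is the OLS slope of rTR on recovery days", {
  rtr <- data.frame(date = as.Date("2023-02-15") + 0:3,
                    rtr = c(0.50, 0.54, 0.58, 0.62))
  out <- recovery_rate(rtr, start = rtr$date[1])
  expect_equal(out$slope, 0.040, tolerance = 1e-12)
  expect_equal(out$n, 4L)
  expect_equal(recovery_rate(data.frame(date = rtr$date, rtr = 0.6),
                             start = rtr$date[1])$slope, 0)
  expect_error(recovery_rate(rtr[1:2, ], start = rtr$date[1]), "at least 3")
  # shift invariance and scale equivariance
  shifted <- transform(rtr, rtr = rtr + 0.2)
  expect_equal(recovery_rate(shifted, start = rtr$date[1])$slope, 0.040,
               tolerance = 1e-12)
  scaled <- transform(rtr, rtr = 3 * rtr)
  expect_equal(recovery_rate(scaled, start = rtr$date[1])$slope, 0.120,
               tolerance = 1e-12)
})

test_that("phase averages divide by valid days only", {
  cal <- phase_calendar("2023-02-01", c(pre_drought = 2, drought = 12,
                                        recovery = 3, post_recovery = 2))
  dates <- seq(as.Date("2023-02-01"), by = "day", length.out = 19)
  fl <- flux_from_daily(mk_daily(dates, 400), "P1")
  expect_equal(phase_average_dtr(fl, cal, "drought"), 400)
  # one missing day among 12: divide by 11
  valid <- rep(TRUE, 19)
  valid[5] <- FALSE
  fl2 <- flux_from_daily(mk_daily(dates, 400, valid), "P1")
  expect_equal(phase_average_dtr(fl2, cal, "drought"),
               400 * 11 / 11)
  tr <- ifelse(seq_along(dates) == 6, 800, 400)
  fl3 <- flux_from_daily(mk_daily(dates, tr, valid), "P1")
  expect_equal(phase_average_dtr(fl3, cal, "drought"),
               (400 * 10 + 800) / 11)
  fl4 <- flux_from_daily(mk_daily(dates, 400, FALSE), "P1")
  expect_error(phase_average_dtr(fl4, cal, "drought"), "no valid days")
})

test_that("water-use efficiency is harvest mass per kilogram of water", {
  expect_equal(water_use_efficiency(51.15, 23144), 51.15 / 23.144,
               tolerance = 1e-12)
  expect_equal(round(water_use_efficiency(51.15, 23144), 2), 2.21)
  expect_equal(water_use_efficiency(0, 20000), 0)
  expect_equal(water_use_efficiency(40, 40000),
               water_use_efficiency(40, 20000) / 2)
  expect_error(water_use_efficiency(40, 0), "water_used")
})

test_that("harvest index is grain over biomass with its bounds enforced", {
  expect_equal(harvest_index(51.15, 151.43), 51.15 / 151.43)
  expect_equal(round(harvest_index(51.15, 151.43), 2), 0.34)
  expect_equal(harvest_index(0, 100), 0)
  expect_equal(harvest_index(100, 100), 1)
  expect_error(harvest_index(101, 100), "exceed")
  expect_error(harvest_index(10, 0), "biomass")
})

test_that("transpiration-yield correlation matches the closed-form estimate", {
  x <- c(18.2, 21.5, 19.9, 24.3, 16.8, 23.1, 20.4, 22.7, 17.6)
  y <- c(38.0, 45.2, 41.1, 52.3, 35.9, 49.8, 44.0, 47.5, 36.4)
  # textbook formula computed directly
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- transpiration_yield_correlation(x, y, rep("control", 9))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$n, 9L)
  # exact proportionality and anti-proportionality
  expect_equal(transpiration_yield_correlation(1:5, 2 * (1:5),
                                               rep("a", 5))$r, 1)
  expect_equal(transpiration_yield_correlation(1:5, -3 * (1:5),
                                               rep("a", 5))$r, -1)
  expect_error(transpiration_yield_correlation(1:2, 1:2, rep("a", 2)),
               "fewer than 3")
  expect_error(transpiration_yield_correlation(rep(1, 5), 1:5, rep("a", 5)),
               "variance")
})

test_that("water-use classes separate the published cultivar behaviours", {
  d <- data.frame(cultivar = c("CHAN", "RGT", "FORM", "BAR"),
                  tr_max = c(0.68, 0.57, 0.50, 0.47),
                  slope = c(2.56, 1.71, 1.87, 1.17))
  cls <- classify_water_use(d)
  got <- setNames(cls$water_use_class, cls$cultivar)
  expect_equal(got[["CHAN"]], "non_conserving")
  expect_equal(got[["BAR"]], "conserving")
  expect_equal(got[["RGT"]], "dynamic")
  # rank-based: invariant to a joint monotone rescaling
  d2 <- transform(d, tr_max = 3 * tr_max + 0.1, slope = 2 * slope)
  expect_equal(classify_water_use(d2)$water_use_class,
               cls$water_use_class)
  expect_warning(cls1 <- classify_water_use(d[1, ]), "relative")
  expect_equal(cls1$water_use_class, "intermediate")
})

test_that("per-plant response metrics assemble end to end on a small run", {
  ex <- simulate_experiment(tiny_config(rng_seed = 3),
                            barley_profiles()[c("CHAN", "BAR")])
  fls <- lapply(ex$weights, extract_flux, events = ex$irrigation,
                pot_volume = ex$config$pot_volume)
  m <- response_metrics(fls, ex$design, ex$phases, ex$harvest)
  expect_s3_class(m, "response_metrics")
  expect_equal(nrow(m), nrow(ex$design))
  dr <- m$treatment == "drought"
  expect_true(all(is.finite(m$recovery_rate[dr])))
  expect_true(all(m$rtr_drought[dr] > 0 & m$rtr_drought[dr] < 1.05))
  expect_true(all(is.finite(m$wue_grain_g_kg)))
  expect_true(all(m$harvest_index >= 0 & m$harvest_index <= 1))
  expect_true(all(is.na(m$recovery_rate[!dr])))
})
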