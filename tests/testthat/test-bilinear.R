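test_that("noiseless points return the generating parameters to numerical precision", {
  for (p in barley_profiles()) {
    pts <- simulate_rate_points(p, n = 60, noise_sd = 0, seed = 5)
    fit <- bilinear(tr_rate ~ swc, pts)
    expect_equal(fit$status, "ok")
    expect_lt(abs(fit$theta_crit - p$theta_crit), 1e-6)
    expect_lt(abs(fit$tr_max - p$tr_max), 1e-6)
    expect_lt(abs(fit$slope - p$decline_slope), 1e-5)
    expect_gt(fit$r_squared, 1 - 1e-9)
  }
})

test_that("the profiled fit matches exhaustive brute-force search", {
  set.seed(99)
  for (i in 1:25) {
    inst <- random_instance()
    fit <- bilinear(tr_rate ~ swc, inst$data)
    br <- brute_bilinear(inst$data$swc, inst$data$tr_rate)
    expect_equal(fit$status, "ok")
    expect_lt(abs(fit$theta_crit - br$theta), 1e-3)
    # same-evaluator comparison: the refined fit attains the brute optimum
    s <- inst$data$swc; y <- inst$data$tr_rate
    expect_lt(oracle_sse(fit$theta_crit, s, y) -
                oracle_sse(br$theta, s, y), 1e-10)
  }
})

test_that("degenerate inputs are flagged, never silent numbers", {
  # horizontal line: plateau-only
  d <- data.frame(swc = seq(0.3, 0.7, length.out = 12), tr_rate = 0.5)
  fit <- bilinear(tr_rate ~ swc, d)
  expect_equal(fit$status, "degenerate")
  expect_equal(fit$slope, 0)
  expect_equal(fit$theta_crit, min(d$swc))
  expect_equal(fit$tr_max, 0.5)
  # all points in one regime (no admissible breakpoint spread)
  d2 <- data.frame(swc = rep(0.6, 8), tr_rate = runif(8, 0.4, 0.5))
  fit2 <- bilinear(tr_rate ~ swc, d2)
  expect_equal(fit2$status, "degenerate")
  expect_error(terminal_drought_point(fit2, 0.3), "degenerate")
  expect_error(trapezoid_area(fit), "degenerate")
  expect_error(bilinear(tr_rate ~ swc, d[1:4, ]), "at least")
})

test_that("the terminal drought point sits on the fitted line at the driest observation", {
  m <- bilinear_model(0.68, 0.557, 2.56)
  m <- terminal_drought_point(m, 0.347)
  expect_equal(m$terminal[["swc"]], 0.347)
  expect_equal(m$terminal[["tr"]], 0.68 - 2.56 * (0.557 - 0.347),
               tolerance = 1e-12)
  # driest observation at the breakpoint: zero-length falling limb
  m2 <- terminal_drought_point(bilinear_model(0.68, 0.557, 2.56), 0.557)
  expect_equal(m2$terminal[["tr"]], 0.68)
  expect_equal(trapezoid_area(m2)$analytic, 0)
})

test_that("the trapezoid integral matches quadrature and the closed form", {
  m <- bilinear_from_geometry(0.50, 0.476, swc_term = 0.308,
                              tr_term = 0.211)
  ar <- trapezoid_area(m)
  expect_equal(ar$analytic, 0.5 * (0.50 + 0.211) * (0.476 - 0.308),
               tolerance = 1e-12)
  expect_lt(abs(ar$analytic - ar$quadrature), 1e-9)
  expect_error(trapezoid_area(bilinear_model(0.5, 0.5, 2)), "terminal")
})

test_that("slope_from_geometry is the line slope and scales linearly", {
  expect_equal(slope_from_geometry(0.68, 0.557, swc_term = 0.347,
                                   tr_term = 0.141),
               (0.68 - 0.141) / (0.557 - 0.347), tolerance = 1e-12)
  expect_equal(slope_from_geometry(0.5, 0.5, swc_term = 0.3,
                                   tr_term = 0.5), 0)
  expect_equal(slope_from_geometry(2 * 0.68, 0.557, swc_term = 0.347,
                                   tr_term = 2 * 0.141),
               2 * slope_from_geometry(0.68, 0.557, swc_term = 0.347,
                                       tr_term = 0.141))
  expect_error(slope_from_geometry(0.5, 0.4, swc_term = 0.4,
                                   tr_term = 0.2), "exceed")
})

test_that("points lying on the fitted model do not move the fit", {
  p <- barley_profiles()$RGT
  pts <- simulate_rate_points(p, n = 40, seed = 21)
  fit <- bilinear(tr_rate ~ swc, pts)
  extra_s <- seq(0.32, 0.68, length.out = 10)
  extra <- data.frame(swc = extra_s, tr_rate = predict(fit, extra_s))
  fit2 <- bilinear(tr_rate ~ swc, rbind(pts, extra))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-7)
})

test_that("model methods behave like a classed fit should", {
  pts <- simulate_rate_points(barley_profiles()$CHAN, n = 50, seed = 8)
  fit <- bilinear(tr_rate ~ swc, pts)
  expect_named(coef(fit), c("tr_max", "theta_crit", "slope"))
  expect_equal(length(residuals(fit)), 50)
  expect_equal(fitted(fit) + residuals(fit), pts$tr_rate)
  # prediction is piecewise: flat above the breakpoint, linear below
  expect_equal(predict(fit, c(fit$theta_crit + 0.05, fit$theta_crit + 0.1)),
               rep(fit$tr_max, 2))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(50L, 3L))
  expect_true(all(sim >= 0))
  expect_output(print(fit), "theta_crit")
  expect_output(print(summary(terminal_drought_point(fit))), "trapezoid")
})

test_that("cumulative transpiration between crossings sums the daily record", {
  daily <- data.frame(date = as.Date("2023-02-03") + 0:11,
                      daily_tr_g = 400, coverage = 1, valid = TRUE,
                      midday_tr_g_min = 0.4,
                      swc_midday = seq(0.65, 0.35, length.out = 12),
                      canopy_conductance = NA_real_)
  fl <- flux_from_daily(daily)
  out <- cumulative_transpiration_between(fl, daily$date[1], daily$date[11])
  expect_equal(as.numeric(out), 400 * 11)
  expect_equal(attr(out, "n_days"), 11L)
  expect_error(cumulative_transpiration_between(fl, daily$date[5],
                                                daily$date[2]), "before")
  cal <- phase_calendar("2023-02-01", c(pre_drought = 2, drought = 12,
                                        recovery = 2, post_recovery = 2))
  w <- drought_window(fl, theta_crit = 0.5, cal)
  expect_equal(w$status, "ok")
  expect_equal(w$from, daily$date[which(daily$swc_midday < 0.5)[1]])
  w2 <- drought_window(fl, theta_crit = 0.1, cal)
  expect_equal(w2$status, "no physiological drought")
})
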