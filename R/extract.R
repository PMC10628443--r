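#' Raw per-plant weight series
#'
#' Container for one plant's timestamped system-weight trace (pot + soil +
#' sensors + plant) together with the dry-system tare used to convert
#' weight to soil water content. Timestamps must be strictly increasing;
#' a nominal 3-min spacing with gaps is expected.
#'
#' @param plant_id Plant label.
#' @param data Data frame with columns `time` (POSIXct) and `weight_g`.
#' @param tare Dry system weight, g.
#' @param tare_tolerance Allowed excursion of weights below `tare`, g
#'   (measurement noise).
#' @return An object of class `weight_series`.
#' @export
weight_series <- function(plant_id, data, tare, tare_tolerance = 50) {
  if (!is.data.frame(data) || !all(c("time", "weight_g") %in% names(data)))
    stopf("'data' must have columns 'time' and 'weight_g'")
  if (nrow(data) == 0L) stopf("weight series '%s' is empty", plant_id)
  data$time <- as_utc(data$time)
  if (any(diff(as.numeric(data$time)) <= 0))
    stopf("timestamps of '%s' must be strictly increasing", plant_id)
  check_number(tare, "tare", lower = 0)
  if (any(data$weight_g < tare - tare_tolerance))
    stopf("'%s' has weights below tare - tolerance; wrong tare?", plant_id)
  structure(list(plant_id = plant_id, data = data, tare = tare),
            class = "weight_series")
}

#' @export
print.weight_series <- function(x, ...) {
  cat(sprintf("Weight series '%s': %d records, %s .. %s, tare %.0f g\n",
              x$plant_id, nrow(x$data), format(min(x$data$time)),
              format(max(x$data$time)), x$tare))
  invisible(x)
}

# events for one plant, validated against the series span
.plant_events <- function(series, events) {
  if (is.null(events) || nrow(events) == 0L)
    return(data.frame(time = as_utc(character()), dose_g = numeric()))
  ev <- events
  if ("plant_id" %in% names(ev)) ev <- ev[ev$plant_id == series$plant_id, ]
  if (nrow(ev) == 0L)
    return(data.frame(time = as_utc(character()), dose_g = numeric()))
  ev$time <- as_utc(ev$time)
  if (any(ev$dose_g <= 0)) stopf("irrigation doses must be positive")
  t <- series$data$time
  if (any(ev$time < t[1L]) || any(ev$time > t[length(t)]))
    stopf("irrigation event outside the time span of series '%s'",
          series$plant_id)
  ev[order(ev$time), c("time", "dose_g")]
}

# Core interval decomposition shared by the extraction functions.
# Smoothing is applied to the raw rate series BEFORE masking (the median
# filter is robust to the few event-spike intervals), so that adding an
# irrigation event changes no extracted rate outside its guard window.
# Masked blocks carry a mass-balance bridge (weight drop + logged doses)
# used for exact daily sums.
.flux_core <- function(series, events = NULL, guard = 6, smooth = 5,
                       clip = TRUE, step_min = 3, gap_factor = 1.5) {
  d <- series$data
  n <- nrow(d)
  if (n < 2L) stopf("weight series '%s' has fewer than two records",
                    series$plant_id)
  t <- d$time
  w <- d$weight_g
  dtm <- diff(as.numeric(t)) / 60
  gap <- dtm > step_min * gap_factor
  rate_raw <- -diff(w) / dtm
  rate <- rate_raw
  if (smooth > 1 && length(rate) >= odd_width(smooth))
    rate <- as.numeric(runmed(rate, k = odd_width(smooth),
                              endrule = "keep"))
  ev <- .plant_events(series, events)
  mask <- logical(n - 1L)
  tn <- as.numeric(t)
  for (k in seq_len(nrow(ev))) {
    a <- as.numeric(ev$time[k]) - guard * 60
    b <- as.numeric(ev$time[k]) + guard * 60
    i1 <- max(1L, findInterval(a, tn))
    i2 <- min(n - 1L, max(1L, findInterval(b - 1e-9, tn)))
    mask[i1:i2] <- TRUE
  }
  if (clip) rate <- pmax(0, rate)
  # maximal runs of masked intervals -> mass-balance bridges
  blocks <- NULL
  if (any(mask)) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bi <- which(r$values)
    evn <- as.numeric(ev$time)
    blocks <- data.frame(
      i0 = starts[bi], i1 = ends[bi],
      date = date_utc(t[starts[bi]]),
      amount = vapply(bi, function(j) {
        i0 <- starts[j]; i1 <- ends[j]
        doses <- ev$dose_g[evn > tn[i0] & evn <= tn[i1 + 1L]]
        max(0, w[i0] - w[i1 + 1L] + sum(doses))
      }, 0))
  }
  list(t0 = t[-n], dt = dtm, rate = rate, rate_raw = rate_raw, mask = mask,
       gap = gap, rec_time = t, blocks = blocks)
}

#' Interval transpiration rates from a weight trace
#'
#' Converts a weight series to interval transpiration rates
#' (-d(weight)/dt). Intervals overlapping an irrigation event, plus a guard
#' window around it (drainage transients), are excluded, as are intervals
#' spanning record gaps (rates are never interpolated). A centred
#' rolling-median smoother (optional; robust to event spikes) is applied to
#' the raw rates before masking, and residual negative rates are clipped to
#' zero.
#'
#' @param series A [weight_series()].
#' @param events Irrigation log: data frame with `time`, `dose_g` and
#'   optionally `plant_id`.
#' @param guard Guard half-window around each event, minutes.
#' @param smooth Rolling-median width in records (values <= 1 disable
#'   smoothing).
#' @param clip Clip negative rates to zero.
#' @param step_min Nominal record spacing, minutes.
#' @return Data frame with `time` (interval start) and `rate_g_min`.
#' @export
interval_transpiration <- function(series, events = NULL, guard = 6,
                                   smooth = 5, clip = TRUE, step_min = 3) {
  core <- .flux_core(series, events, guard = guard, smooth = smooth,
                     clip = clip, step_min = step_min)
  keep <- !core$mask & !core$gap
  data.frame(time = core$t0[keep], rate_g_min = core$rate[keep],
             row.names = NULL)
}

#' Volumetric soil water content from a weight trace
#'
#' Converts system weight to volumetric soil water content:
#' `swc = (weight - tare - correction) / pot_volume` (water density
#' 1 g/cm^3), clipped to \[0, 1\]. The plant fresh-mass correction defaults
#' to zero: daily plant mass change is small against daily transpiration.
#'
#' @param series A [weight_series()].
#' @param pot_volume Pot volume, cm^3.
#' @param correction Plant water-mass correction, g.
#' @param tolerance Allowed excursion below tare, g.
#' @return Data frame with `time` and `swc`.
#' @export
volumetric_swc <- function(series, pot_volume, correction = 0,
                           tolerance = 50) {
  check_number(pot_volume, "pot_volume", lower = 0, strict_lower = TRUE)
  w <- series$data$weight_g
  if (any(w < series$tare - tolerance))
    stopf("weights below tare beyond tolerance in '%s'", series$plant_id)
  swc <- pmin(1, pmax(0, (w - series$tare - correction) / pot_volume))
  data.frame(time = series$data$time, swc = swc, row.names = NULL)
}

#' Extract the full per-plant flux record
#'
#' Runs the whole gravimetric extraction for one plant: cleaned interval
#' transpiration rates, volumetric soil water content, and a daily table
#' with total transpiration, a validity flag from record coverage, the
#' midday transpiration rate, midday soil water content and canopy
#' conductance. Daily totals integrate the unmasked interval rates and add
#' a mass-balance bridge over each irrigation guard window (weight change
#' plus the logged dose), so that at zero measurement noise the daily sum
#' equals the true transpired mass exactly. Days with less than
#' `min_coverage` of the expected records are flagged invalid and excluded
#' from downstream averages.
#'
#' @inheritParams interval_transpiration
#' @inheritParams volumetric_swc
#' @param forcing Optional [generate_forcing()] series (or any data frame
#'   with `time`, `vpd`, `light_on`) used for canopy conductance.
#' @param min_coverage Minimum fraction of expected records for a day to be
#'   valid.
#' @param midday Numeric `c(start, end)` hours of the midday window used
#'   for the rate-vs-SWC working point (default 15-17 h, when ambient
#'   conditions are most stable).
#' @return An object of class `plant_flux`: list with `plant_id`,
#'   `interval` (time, rate), `swc` (time, swc) and `daily` (date,
#'   daily_tr_g, coverage, valid, midday_tr_g_min, swc_midday,
#'   canopy_conductance).
#' @export
extract_flux <- function(series, events = NULL, forcing = NULL, pot_volume,
                         correction = 0, guard = 6, smooth = 5, clip = TRUE,
                         min_coverage = 0.8, midday = c(15, 17),
                         step_min = 3) {
  core <- .flux_core(series, events, guard = guard, smooth = smooth,
                     clip = clip, step_min = step_min)
  swc <- volumetric_swc(series, pot_volume, correction = correction)

  idate <- date_utc(core$t0)
  ok <- !core$mask & !core$gap
  dates <- sort(unique(idate))
  nd <- length(dates)
  di <- match(as.numeric(idate), as.numeric(dates))
  per_day <- 1440 / step_min
  n_rec <- tabulate(match(as.numeric(date_utc(core$rec_time)),
                          as.numeric(dates)), nbins = nd)
  coverage <- n_rec / per_day

  # grouped sum/mean by day index, NA where a day has no contributing value
  gsum <- function(v, sel) {
    out <- numeric(nd)
    if (any(sel)) {
      agg <- rowsum(v[sel], di[sel])
      out[as.integer(rownames(agg))] <- agg[, 1L]
    }
    out
  }
  gmean <- function(v, sel, group = di) {
    cnt <- tabulate(group[sel], nbins = nd)
    out <- numeric(nd)
    if (any(sel)) {
      agg <- rowsum(v[sel], group[sel])
      out[as.integer(rownames(agg))] <- agg[, 1L]
    }
    ifelse(cnt > 0, out / cnt, NA_real_)
  }

  daily_tr <- gsum(core$rate * core$dt, ok)
  if (!is.null(core$blocks)) {
    bi <- match(as.numeric(core$blocks$date), as.numeric(dates))
    bagg <- rowsum(core$blocks$amount, bi)
    j <- as.integer(rownames(bagg))
    daily_tr[j] <- daily_tr[j] + bagg[, 1L]
  }

  m0 <- minute_of_day(core$t0)
  in_mid <- m0 >= midday[1L] * 60 & m0 < midday[2L] * 60
  midday_tr <- gmean(core$rate, ok & in_mid)

  ms <- minute_of_day(swc$time)
  sdi <- match(as.numeric(date_utc(swc$time)), as.numeric(dates))
  in_mid_s <- ms >= midday[1L] * 60 & ms < midday[2L] * 60 & !is.na(sdi)
  swc_midday <- gmean(swc$swc, in_mid_s, group = sdi)

  gc_daily <- rep(NA_real_, nd)
  if (!is.null(forcing)) {
    fi <- match(as.numeric(core$t0), as.numeric(forcing$time))
    fv <- forcing$vpd[fi]
    fl <- forcing$light_on[fi]
    use <- ok & !is.na(fv) & fv > 0 & !is.na(fl) & fl
    gc_daily <- gmean(ifelse(use, core$rate / fv, 0), use)
  }

  daily <- data.frame(date = dates, daily_tr_g = daily_tr,
                      coverage = coverage, valid = coverage >= min_coverage,
                      midday_tr_g_min = midday_tr, swc_midday = swc_midday,
                      canopy_conductance = gc_daily, row.names = NULL)
  structure(list(plant_id = series$plant_id,
                 interval = data.frame(time = core$t0[ok],
                                       rate_g_min = core$rate[ok],
                                       row.names = NULL),
                 swc = swc, daily = daily,
                 params = list(guard = guard, smooth = smooth,
                               min_coverage = min_coverage,
                               midday = midday, pot_volume = pot_volume)),
            class = "plant_flux")
}

#' @export
print.plant_flux <- function(x, ...) {
  cat(sprintf(
    "Plant flux '%s': %d clean intervals, %d days (%d valid), mean daily transpiration %.1f g\n",
    x$plant_id, nrow(x$interval), nrow(x$daily), sum(x$daily$valid),
    mean(x$daily$daily_tr_g[x$daily$valid])))
  invisible(x)
}

#' Daily transpiration for a date
#'
#' Returns the daily transpired mass for a covered date, or `NA` when the
#' day fails the record-coverage rule (such days are excluded from
#' averages).
#'
#' @param flux A [extract_flux()] result.
#' @param date Date (or coercible).
#' @return Daily transpiration, g/day, or `NA` for an invalid day.
#' @export
daily_transpiration <- function(flux, date) {
  stopifnot(inherits(flux, "plant_flux"))
  i <- match(as.Date(date), flux$daily$date)
  if (is.na(i)) stopf("date %s is not covered by the records", date)
  if (!flux$daily$valid[i]) return(NA_real_)
  flux$daily$daily_tr_g[i]
}

#' Midday transpiration rate
#'
#' Mean cleaned interval rate within the midday window of a date; `NA`
#' when the window holds no valid interval (e.g. fully masked by an
#' irrigation guard).
#'
#' @inheritParams daily_transpiration
#' @param window Numeric `c(start, end)` hours.
#' @return Rate in g/min, or `NA`.
#' @export
midday_rate <- function(flux, date, window = c(15, 17)) {
  stopifnot(inherits(flux, "plant_flux"))
  date <- as.Date(date)
  m <- minute_of_day(flux$interval$time)
  sel <- date_utc(flux$interval$time) == date &
    m >= window[1L] * 60 & m < window[2L] * 60
  if (!any(sel)) return(NA_real_)
  mean(flux$interval$rate_g_min[sel])
}

#' Daily canopy conductance
#'
#' Whole-plant analogue of stomatal conductance: the daytime mean of
#' interval transpiration rate divided by interval VPD, in
#' g min^-1 kPa^-1. Intervals with zero or missing VPD are excluded. Note
#' this package's normalisation is its own documented definition; closed
#' phenotyping platforms publish conductance on an unspecified internal
#' scale, so only relative comparisons are meaningful across systems.
#'
#' @inheritParams daily_transpiration
#' @param forcing Forcing series with `time`, `vpd`, `light_on`.
#' @return Conductance in g min^-1 kPa^-1, or `NA`.
#' @export
canopy_conductance <- function(flux, forcing, date) {
  stopifnot(inherits(flux, "plant_flux"))
  date <- as.Date(date)
  sel <- date_utc(flux$interval$time) == date
  if (!any(sel)) return(NA_real_)
  ti <- flux$interval$time[sel]
  ri <- flux$interval$rate_g_min[sel]
  fi <- match(as.numeric(ti), as.numeric(forcing$time))
  fv <- forcing$vpd[fi]
  fl <- forcing$light_on[fi]
  use <- !is.na(fv) & fv > 0 & !is.na(fl) & fl
  if (!any(use)) return(NA_real_)
  mean(ri[use] / fv[use])
}
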