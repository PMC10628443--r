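#' Relative transpiration of a drought-stressed plant
#'
#' Normalises a drought plant's daily transpiration by the same-day mean of
#' the well-watered plants of its cultivar (size correction: big plants
#' transpire more and dry their pot faster). Dates with no valid control
#' mean are skipped; a zero control mean is flagged and skipped with a
#' warning.
#'
#' @param drought_flux [extract_flux()] result of a drought plant.
#' @param control_fluxes List of [extract_flux()] results of the same
#'   cultivar's control plants (>= 1).
#' @param dates Optional date subset.
#' @return Data frame with `date` and `rtr`.
#' @export
relative_transpiration <- function(drought_flux, control_fluxes,
                                   dates = NULL) {
  stopifnot(inherits(drought_flux, "plant_flux"))
  if (inherits(control_fluxes, "plant_flux"))
    control_fluxes <- list(control_fluxes)
  if (!length(control_fluxes))
    stopf("at least one control plant is required")
  dd <- drought_flux$daily[drought_flux$daily$valid, c("date", "daily_tr_g")]
  if (!is.null(dates)) dd <- dd[dd$date %in% as.Date(dates), ]
  ctrl <- vapply(dd$date, function(d) {
    v <- vapply(control_fluxes, function(f) {
      i <- match(d, f$daily$date)
      if (is.na(i) || !f$daily$valid[i]) NA_real_ else f$daily$daily_tr_g[i]
    }, 0)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  keep <- !is.na(ctrl)
  if (any(keep & ctrl == 0)) {
    warnf("zero control-mean transpiration on %d date(s); skipped",
          sum(keep & ctrl == 0))
    keep <- keep & ctrl != 0
  }
  data.frame(date = dd$date[keep], rtr = dd$daily_tr_g[keep] / ctrl[keep],
             row.names = NULL)
}

#' Drought-recovery (resilience) rate
#'
#' The slope of the ordinary least-squares regression of relative
#' transpiration on time over the re-irrigation period, in rTR/day. Day 1
#' is the first recovery day.
#'
#' @param rtr Data frame with `date` and `rtr` (see
#'   [relative_transpiration()]).
#' @param calendar Optional [phase_calendar()]; its recovery phase defines
#'   the window and day-1 origin.
#' @param start,end Alternative explicit window (Dates); `start` is day 1.
#' @return List with `slope` (rTR/day), `intercept`, `n`.
#' @examples
#' rtr <- data.frame(date = as.Date("2023-02-15") + 0:3,
#'                   rtr = c(0.50, 0.54, 0.58, 0.62))
#' recovery_rate(rtr, start = as.Date("2023-02-15"))$slope
#' @export
recovery_rate <- function(rtr, calendar = NULL, start = NULL, end = NULL) {
  if (!is.null(calendar)) {
    i <- match("recovery", calendar$phase)
    if (is.na(i)) stopf("the calendar has no recovery phase")
    start <- calendar$start[i]
    end <- calendar$end[i]
  }
  if (is.null(start)) stopf("supply 'calendar' or 'start'")
  start <- as.Date(start)
  sel <- rtr$date >= start & (if (is.null(end)) TRUE else
    rtr$date <= as.Date(end))
  sub <- rtr[sel, ]
  if (nrow(sub) < 3L)
    stopf("at least 3 recovery-phase rTR values are required")
  day <- as.numeric(sub$date - start) + 1
  fit <- lm(sub$rtr ~ day)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       n = nrow(sub))
}

#' Phase-average daily transpiration
#'
#' Cumulative transpiration over a phase's valid days divided by the
#' number of valid days (days failing the record-coverage rule are
#' excluded rather than counted as zeros).
#'
#' @param flux A [extract_flux()] result.
#' @param calendar A [phase_calendar()].
#' @param phase Phase label.
#' @return Average daily transpiration over the phase, g/day.
#' @export
phase_average_dtr <- function(flux, calendar, phase) {
  stopifnot(inherits(flux, "plant_flux"))
  dd <- phase_dates(calendar, phase)
  sub <- flux$daily[flux$daily$date %in% dd & flux$daily$valid, ]
  if (nrow(sub) == 0L)
    stopf("no valid days in phase '%s' for plant '%s'", phase,
          flux$plant_id)
  sum(sub$daily_tr_g) / nrow(sub)
}

#' Agronomic water-use efficiency
#'
#' Harvested mass per unit water transpired during the monitored period.
#' Reported in g harvest per kg water: gravimetric platforms publish WUE
#' values of order 1-10 on this scale (a per-gram denominator would put
#' them three orders of magnitude lower).
#'
#' @param harvest_mass Harvested mass (biomass or grain), g; >= 0.
#' @param water_used Cumulative transpiration over the monitored period, g;
#'   > 0.
#' @return WUE in g/kg.
#' @examples
#' water_use_efficiency(51.15, 23144)  # ~2.21 g/kg
#' @export
water_use_efficiency <- function(harvest_mass, water_used) {
  check_number(harvest_mass, "harvest_mass", lower = 0)
  check_number(water_used, "water_used", lower = 0, strict_lower = TRUE)
  harvest_mass / (water_used / 1000)
}

#' Harvest index
#'
#' Grain mass divided by total above-ground biomass.
#'
#' @param grain Grain mass, g.
#' @param biomass Above-ground biomass, g; > 0 and >= `grain`.
#' @return Fraction in \[0, 1\].
#' @export
harvest_index <- function(grain, biomass) {
  check_number(grain, "grain", lower = 0)
  check_number(biomass, "biomass", lower = 0, strict_lower = TRUE)
  if (grain > biomass) stopf("grain mass cannot exceed biomass")
  grain / biomass
}

#' Correlation of cumulative transpiration with grain yield
#'
#' Pearson correlation (with two-sided p-value) between per-plant
#' cumulative transpiration and final grain yield, computed separately per
#' treatment group.
#'
#' @param cum_transpiration Per-plant cumulative transpiration, g.
#' @param grain_yield Per-plant grain yield, g.
#' @param treatment Treatment labels (factor or character).
#' @return Data frame with one row per treatment: `treatment`, `r`, `p`,
#'   `n`.
#' @export
transpiration_yield_correlation <- function(cum_transpiration, grain_yield,
                                            treatment) {
  if (length(cum_transpiration) != length(grain_yield) ||
      length(grain_yield) != length(treatment))
    stopf("inputs must have equal length")
  groups <- unique(as.character(treatment))
  out <- lapply(groups, function(g) {
    sel <- treatment == g
    x <- cum_transpiration[sel]
    y <- grain_yield[sel]
    if (length(x) < 3L)
      stopf("treatment '%s' has fewer than 3 plants", g)
    if (sd(x) == 0 || sd(y) == 0)
      stopf("zero variance in treatment '%s'", g)
    ct <- cor.test(x, y, method = "pearson")
    data.frame(treatment = g, r = unname(ct$estimate), p = ct$p.value,
               n = length(x))
  })
  do.call(rbind, out)
}

#' Classify cultivar water-use behaviour
#'
#' Relative (rank-based) classification of cultivars into water-use types
#' from their well-watered transpiration level and their decline slope
#' under drying soil: high transpiration with a steep decline is
#' non-conserving (anisohydric-like, stomata stay open until late); low
#' transpiration with a shallow decline is conserving (isohydric-like,
#' early stomatal limitation); high transpiration with a shallow decline is
#' the dynamic type that switches from non-conserving to conserver-like
#' behaviour under drought; any other combination is intermediate. "High"
#' means above the cross-cultivar median by default; absolute thresholds
#' can be supplied instead. Classification needs at least two cultivars —
#' a single cultivar is labelled intermediate with a warning.
#'
#' @param cultivars Data frame with columns `cultivar`, `tr_max`
#'   (well-watered transpiration level or plateau rate, used for ranking)
#'   and `slope` (decline slope). An optional `recovery_rate` column is
#'   carried through.
#' @param thresholds Optional list with absolute cutoffs `tr_max` and/or
#'   `slope` replacing the median splits.
#' @return The input with an added `water_use_class` column, one of
#'   `conserving`, `non_conserving`, `dynamic`, `intermediate`.
#' @examples
#' d <- data.frame(cultivar = c("CHAN", "RGT", "FORM", "BAR"),
#'                 tr_max = c(0.68, 0.57, 0.50, 0.47),
#'                 slope = c(2.56, 1.71, 1.87, 1.17))
#' classify_water_use(d)
#' @export
classify_water_use <- function(cultivars, thresholds = NULL) {
  if (!is.data.frame(cultivars) ||
      !all(c("cultivar", "tr_max", "slope") %in% names(cultivars)))
    stopf("'cultivars' needs columns cultivar, tr_max, slope")
  n <- nrow(cultivars)
  if (n < 2L) {
    warnf("classification is relative; a single cultivar is 'intermediate'")
    cultivars$water_use_class <- rep("intermediate", n)
    return(cultivars)
  }
  cut_tr <- thresholds$tr_max %||% median(cultivars$tr_max)
  cut_sl <- thresholds$slope %||% median(cultivars$slope)
  high_tr <- cultivars$tr_max > cut_tr
  high_sl <- cultivars$slope > cut_sl
  cls <- rep("intermediate", n)
  cls[high_tr & high_sl] <- "non_conserving"
  cls[!high_tr & !high_sl] <- "conserving"
  cls[high_tr & !high_sl] <- "dynamic"
  cultivars$water_use_class <- cls
  cultivars
}

#' Per-plant response metrics of an experiment
#'
#' Assembles the physiological and agronomic readout for every plant:
#' phase-average daily transpiration, mean relative transpiration during
#' drought and recovery (drought plants), the recovery rate, cumulative
#' transpiration over the monitored period, water-use efficiency for
#' biomass and grain, and the harvest index.
#'
#' @param fluxes Named list of [extract_flux()] results (all plants).
#' @param design Design table with `plant_id`, `cultivar`, `treatment`.
#' @param calendar A [phase_calendar()].
#' @param harvest Optional harvest table with `plant_id`, `biomass_g`,
#'   `grain_g`.
#' @return A data frame of class `response_metrics`, one row per plant.
#' @export
response_metrics <- function(fluxes, design, calendar, harvest = NULL) {
  stopifnot(is.list(fluxes), is.data.frame(design))
  rows <- lapply(seq_len(nrow(design)), function(i) {
    pid <- design$plant_id[i]
    fl <- fluxes[[pid]]
    if (is.null(fl)) stopf("no flux record for plant '%s'", pid)
    dtr <- vapply(calendar$phase, function(ph) {
      tryCatch(phase_average_dtr(fl, calendar, ph), error = function(e)
        NA_real_)
    }, 0)
    names(dtr) <- paste0("dtr_", calendar$phase)
    cum_t <- sum(fl$daily$daily_tr_g[fl$daily$valid])
    rtr_drought <- NA_real_
    rtr_recovery <- NA_real_
    rec_slope <- NA_real_
    if (design$treatment[i] == "drought") {
      ctrl_ids <- design$plant_id[design$cultivar == design$cultivar[i] &
                                    design$treatment == "control"]
      ctrl <- fluxes[ctrl_ids]
      if (length(ctrl)) {
        rtr <- relative_transpiration(fl, ctrl)
        dsel <- rtr$date %in% phase_dates(calendar, "drought")
        rsel <- rtr$date %in% phase_dates(calendar, "recovery")
        if (any(dsel)) rtr_drought <- mean(rtr$rtr[dsel])
        if (any(rsel)) rtr_recovery <- mean(rtr$rtr[rsel])
        rec_slope <- tryCatch(recovery_rate(rtr, calendar)$slope,
                              error = function(e) NA_real_)
      }
    }
    wue_b <- wue_g <- hi <- NA_real_
    if (!is.null(harvest)) {
      h <- harvest[harvest$plant_id == pid, ]
      if (nrow(h) == 1L && cum_t > 0) {
        wue_b <- water_use_efficiency(h$biomass_g, cum_t)
        wue_g <- water_use_efficiency(h$grain_g, cum_t)
        hi <- harvest_index(h$grain_g, h$biomass_g)
      }
    }
    cbind(data.frame(plant_id = pid, cultivar = design$cultivar[i],
                     treatment = design$treatment[i],
                     cum_transpiration_g = cum_t,
                     rtr_drought = rtr_drought,
                     rtr_recovery = rtr_recovery,
                     recovery_rate = rec_slope,
                     wue_biomass_g_kg = wue_b, wue_grain_g_kg = wue_g,
                     harvest_index = hi),
          as.data.frame(as.list(dtr)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("response_metrics", "data.frame")
  out
}
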