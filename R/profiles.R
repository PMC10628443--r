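#' Cultivar water-use profile
#'
#' A `cultivar_profile` holds the physiological parameters that govern a
#' cultivar's whole-plant water use in the experiment simulator and in the
#' segmented transpiration model: the midday plateau transpiration rate
#' (`tr_max`), the critical volumetric soil water content below which soil
#' water limits transpiration (`theta_crit`), the rate at which transpiration
#' declines per unit soil water content below the breakpoint
#' (`decline_slope`), the drought-recovery slope of relative transpiration
#' per day (`recovery_rate`), and two agronomic parameters used only for
#' harvest synthesis (`biomass_potential`, `harvest_index`).
#'
#' @param name Cultivar label.
#' @param tr_max Plateau (maximum) midday transpiration rate, g/min; > 0.
#' @param theta_crit Critical volumetric soil water content, cm^3/cm^3,
#'   strictly inside (0, 1).
#' @param decline_slope Transpiration-rate decline per unit soil water
#'   content below `theta_crit`, (g/min)/(cm^3/cm^3); >= 0.
#' @param recovery_rate Slope of relative transpiration vs time during
#'   re-irrigation, 1/day.
#' @param biomass_potential Above-ground dry biomass under well-watered
#'   conditions, g.
#' @param harvest_index Grain mass / biomass, in \[0, 1\].
#'
#' @return An object of class `cultivar_profile`.
#' @seealso [barley_profiles()], [transpiration_demand()]
#' @examples
#' cultivar_profile("CHAN", tr_max = 0.68, theta_crit = 0.557,
#'                  decline_slope = 2.56)
#' @export
cultivar_profile <- function(name, tr_max, theta_crit, decline_slope,
                             recovery_rate = 0.04, biomass_potential = 120,
                             harvest_index = 0.33) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("'name' must be a non-empty string")
  check_number(tr_max, "tr_max", lower = 0, strict_lower = TRUE)
  check_number(theta_crit, "theta_crit", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(decline_slope, "decline_slope", lower = 0)
  check_number(recovery_rate, "recovery_rate", lower = 0)
  check_number(biomass_potential, "biomass_potential", lower = 0,
               strict_lower = TRUE)
  check_number(harvest_index, "harvest_index", lower = 0, upper = 1)
  structure(list(name = name, tr_max = tr_max, theta_crit = theta_crit,
                 decline_slope = decline_slope, recovery_rate = recovery_rate,
                 biomass_potential = biomass_potential,
                 harvest_index = harvest_index),
            class = "cultivar_profile")
}

#' @export
print.cultivar_profile <- function(x, ...) {
  cat(sprintf(
    "Cultivar profile '%s'\n  TRmax       %.3f g/min\n  theta_crit  %.3f cm3/cm3\n  slope       %.3f (g/min)/(cm3/cm3)\n  recovery    %.3f /day\n  biomass     %.1f g (HI %.3f)\n",
    x$name, x$tr_max, x$theta_crit, x$decline_slope, x$recovery_rate,
    x$biomass_potential, x$harvest_index))
  invisible(x)
}

#' Reference spring barley cultivar profiles
#'
#' Profiles for the four European spring barley cultivars used as the
#' package's reference experiment: Chanell (CHAN), RGT Planet (RGT),
#' Formula (FORM) and Baronesse (BAR). The segmented-model parameters
#' (plateau rate, breakpoint, decline slope) and the recovery rates are the
#' published platform estimates for these cultivars under a 12-day feedback
#' deficit-irrigation drought around flowering; biomass potential and
#' harvest index come from the corresponding well-watered harvest.
#'
#' Note: the published decline slopes for FORM (1.87) and RGT (1.71) are not
#' consistent with the slopes implied by their own plateau, breakpoint and
#' terminal drought points (approximately 1.72 and 1.86 — possibly
#' transposed in print). These defaults carry the values as printed;
#' [slope_from_geometry()] recovers the geometry-consistent value from any
#' fitted or constructed model.
#'
#' @return A named list of four [cultivar_profile] objects.
#' @examples
#' barley_profiles()$CHAN
#' @export
barley_profiles <- function() {
  list(
    CHAN = cultivar_profile("CHAN", tr_max = 0.68, theta_crit = 0.557,
                            decline_slope = 2.56, recovery_rate = 0.035,
                            biomass_potential = 161.36,
                            harvest_index = 54.96 / 161.36),
    RGT  = cultivar_profile("RGT", tr_max = 0.57, theta_crit = 0.579,
                            decline_slope = 1.71, recovery_rate = 0.040,
                            biomass_potential = 151.43,
                            harvest_index = 51.15 / 151.43),
    FORM = cultivar_profile("FORM", tr_max = 0.50, theta_crit = 0.476,
                            decline_slope = 1.87, recovery_rate = 0.041,
                            biomass_potential = 101.02,
                            harvest_index = 27.67 / 101.02),
    BAR  = cultivar_profile("BAR", tr_max = 0.47, theta_crit = 0.544,
                            decline_slope = 1.17, recovery_rate = 0.036,
                            biomass_potential = 99.91,
                            harvest_index = 38.13 / 99.91)
  )
}

#' Instantaneous whole-plant transpiration demand
#'
#' Evaluates the piecewise-linear transpiration response of a cultivar to
#' soil water content, scaled by atmospheric demand and the light period:
#' at or above `theta_crit` the plant transpires at its plateau rate; below
#' it the rate declines linearly with soil water content (floored at zero).
#' Atmospheric scaling is linear in vapour-pressure deficit and normalised
#' so that the scaling equals 1 at `vpd_ref`. At night demand drops to a
#' small fraction of the daytime value.
#'
#' @param profile A [cultivar_profile].
#' @param swc Volumetric soil water content(s) in \[0, 1\].
#' @param vpd Vapour pressure deficit, kPa.
#' @param light_on Logical; is the photoperiod light on?
#' @param vpd_ref Reference VPD at which the atmospheric scaling is 1 (kPa).
#' @param night_fraction Fraction of the VPD-scaled daytime demand that
#'   remains at night.
#'
#' @return Transpiration demand in g/min (vectorised over `swc`, `vpd`,
#'   `light_on`).
#' @examples
#' p <- barley_profiles()$CHAN
#' transpiration_demand(p, swc = 0.60, vpd = 1.7, light_on = TRUE)  # plateau
#' transpiration_demand(p, swc = 0.347, vpd = 1.7, light_on = TRUE)
#' @export
transpiration_demand <- function(profile, swc, vpd, light_on,
                                 vpd_ref = 1.7, night_fraction = 0.05) {
  stopifnot(inherits(profile, "cultivar_profile"))
  if (any(!is.finite(swc)) || any(swc < 0) || any(swc > 1))
    stopf("'swc' must lie within [0, 1]")
  check_number(vpd_ref, "vpd_ref", lower = 0, strict_lower = TRUE)
  check_number(night_fraction, "night_fraction", lower = 0, upper = 1)
  base <- pmax(0, profile$tr_max -
                 profile$decline_slope * pmax(0, profile$theta_crit - swc))
  base * (vpd / vpd_ref) * ifelse(light_on, 1, night_fraction)
}
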