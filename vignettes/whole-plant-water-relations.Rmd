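---
title: "Whole-plant water relations from gravimetric phenotyping data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-plant water relations from gravimetric phenotyping data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtflux)
```

## The measurement principle

A gravimetric phenotyping platform weighs each potted plant every few
minutes. With the soil surface sealed (no evaporation), the weight trace is
a complete water ledger: weight loss between two records is transpiration,
weight gain is irrigation, and the water stored in the pot converts
directly to volumetric soil water content (SWC),

$$\mathrm{SWC}(t) = \frac{w(t) - \text{tare}}{V_\text{pot}},$$

with water density 1 g/cm^3 and the tare the dry system weight (pot, dry
soil, sensors, plant). `droughtflux` covers the full chain from raw weight
traces to drought-response physiology. This vignette records the model, its
assumptions, and every numerically consequential choice.

## The segmented transpiration model

Plants transpire at a soil-water-independent plateau until the soil can no
longer resupply the roots fast enough; below that critical water content
transpiration falls approximately linearly. `bilinear()` fits

$$\mathrm{TR}(s) = \begin{cases}
\mathrm{TR}_{\max} & s \ge \theta_{\text{crit}}\\
\mathrm{TR}_{\max} - b\,(\theta_{\text{crit}} - s) & s < \theta_{\text{crit}}
\end{cases}$$

to midday working points (rate vs SWC), continuous at the breakpoint and
constrained to $b \ge 0$.

**Estimation.** For a fixed breakpoint $\theta$ the model is linear in
$(\mathrm{TR}_{\max}, b)$ via the hinge $h_i = \max(0, \theta - s_i)$, so
each candidate is solved in closed form. The profile over $\theta$ is
scanned on a uniform grid (default 200 candidates across the inner 5th-95th
percentile of observed SWC) augmented with the midpoint of every admissible
interval between consecutive observed SWC values; the optimum is then
refined continuously inside each admissible interval, with a final
golden-section polish (bracket $10^{-12}$) of the winning basin. The
interval-by-interval search matters because the profiled SSE is only
piecewise smooth — its kinks sit at the data points — and a grid alone can
land in the wrong basin. Ties in SSE (within $10^{-12}$) are broken towards
the **largest** breakpoint, i.e. the earlier stress onset.

**Identifiability.** An admissible breakpoint must keep at least `min_seg`
(default 2) points strictly below and at-or-above it. If no admissible
candidate exists, or the unconstrained decline is non-positive (e.g. all
points on a horizontal line), the fit is returned with
`status = "degenerate"`, slope 0, plateau at the mean rate and the
breakpoint reported at the minimum observed SWC — degenerate inputs never
produce silent numbers.

**Goodness of fit.** $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ against the
grand mean of the pooled points. Fits are pooled per cultivar over the
drought plants' midday points by default (the pipeline does exactly this);
per-plant fits are available by subsetting.

**Derived geometry.** The terminal drought point is the minimum observed
SWC with the fitted rate there; the trapezoid integral
$\tfrac12(\mathrm{TR}_{\max} + \mathrm{TR}_{\text{term}})
(\theta_{\text{crit}} - s_{\text{term}})$ is also computed by numerical
quadrature as a cross-check and both values are returned. A consistency
utility, `slope_from_geometry()`, recovers the decline slope implied by a
plateau/breakpoint/terminal triple; published parameter sets are sometimes
internally inconsistent at print precision (two of the four reference
cultivars' printed slopes appear transposed relative to their own
geometry), and this utility makes such checks one-liners.

**A note on scale.** Midday rates are observed near the diurnal VPD peak,
so plateau and slope estimates from midday points carry the midday VPD
scale (about 1.35 times the daily-mean-VPD scale under the default
forcing); the breakpoint is scale-free. Comparisons across cultivars within
one experiment are unaffected.

## Signal extraction

`extract_flux()` implements the platform-style bookkeeping:

- **Interval rates** are $-\Delta w/\Delta t$. Records are nominally 3 min
  apart; intervals spanning gaps (spacing > 1.5 nominal steps) yield no
  rates — rates are never interpolated.
- **Irrigation masking.** Intervals overlapping an event plus a guard
  half-window (default 6 min, two records — drainage transients) are
  excluded from the rate series.
- **Smoothing order.** A centred rolling median (default width 5 records)
  is applied to the raw rate series *before* masking, then residual
  negative rates are clipped to zero. The median is robust to the one or
  two event-spike intervals inside any window, and smoothing-before-masking
  guarantees that adding an irrigation event changes no extracted rate
  outside its own guard window (a property the test suite checks
  literally). Width 1 disables smoothing.
- **Daily totals bridge masked windows by mass balance.** Transpiration
  inside a guard window is recovered as (weight drop across the window +
  logged dose); nighttime transpiration is small but nonzero, so without
  the bridge daily sums would be biased low by whatever transpired during
  irrigation. With zero measurement noise this makes extracted daily sums
  equal the simulator's ground truth to floating-point precision — the
  package's strongest internal check.
- **Missing-day rule.** A day is valid only if at least 80% (configurable)
  of its expected records are present; invalid days are excluded from all
  averages rather than treated as zeros. Phase averages consequently divide
  by the number of valid days, not the nominal phase length.
- **Midday window.** Rate-vs-SWC working points are taken at 15:00-17:00,
  when ambient conditions are most stable; both the rate and the SWC are
  window means, which is first-order exact for a response linear in SWC.
- **Canopy conductance** is the daytime mean of rate/VPD
  (g min^-1 kPa^-1). This is the package's own normalisation; closed
  platforms publish conductance on an unspecified internal scale, so only
  relative comparisons are meaningful across systems.
- **Plant-mass correction** for the SWC conversion defaults to 0 g: daily
  plant fresh-mass change is small against daily transpiration. It is a
  config knob for long runs.

## Response metrics

Relative transpiration (rTR) divides a drought plant's daily sum by the
same-day mean of its cultivar's controls; dates without a valid control
mean are skipped, a zero control mean is flagged. The recovery
(resilience) rate is the OLS slope of rTR on days of the re-irrigation
period, day 1 being the first re-irrigated day. Agronomic water-use
efficiency is harvest mass per **kilogram** of transpired water: platform
studies print WUE of order 1-10 on this scale, which is only consistent
with a per-kilogram denominator, and the unit is labelled accordingly.
Water-use classification is deliberately relative (median splits of
well-watered transpiration level and of decline slope, both overridable
with absolute thresholds): high/steep is non-conserving, low/shallow is
conserving, high/shallow is the dynamic type that transpires freely under
ample water but declines like a conserver under drought; anything else is
intermediate. With fewer than two cultivars the classification is
meaningless and returns `intermediate` with a warning.

## The experiment simulator

`simulate_experiment()` emulates a feedback deficit-irrigation experiment
as a per-step water balance. Its defaults *are* the reference study
conditions: 3-L pots (1250 g potting mix) at pot capacity 0.70 volumetric;
4 control + 5 drought replicates per cultivar; phases of 7 (pre-drought),
12 (drought), 10 (recovery), 10 (post-recovery) days; photoperiod
05:30-18:00; VPD a diurnal sinusoid with mean 1.7 kPa clipped to
0.8-2.4 kPa (amplitude 0.7 kPa, peak 14:00, Gaussian jitter 0.05 kPa);
weight noise 0.5 g per record; drought irrigation 80% of the plant's own
previous-day transpiration. The four bundled cultivar profiles carry the
published plateau/breakpoint/slope estimates and recovery rates for the
reference spring barley cultivars.

Choices the measurement protocol leaves open, fixed once here:

- **Demand model.** Instantaneous demand is the cultivar's bilinear
  response evaluated at current SWC, scaled linearly by VPD (normalised to
  1 at the 1.7 kPa reference) and gated by the photoperiod; nighttime
  demand is 5% of the VPD-scaled daytime value — nonzero on purpose, so
  irrigation/transpiration disentangling is actually exercised. Demand is
  capped by the water available above a wilting floor (SWC 0.05).
- **Irrigation pulses.** Doses arrive as up to three discrete nocturnal
  pulses. Refill-to-capacity pulses run 21:00-23:00 (so controls start
  every day at pot capacity); drought-phase feedback doses run
  02:00-04:00 and split the previous *complete* day's transpiration
  exactly. Post-recovery irrigation is 90% of the refill dose ("slightly
  reduced" for maturing plants).
- **Recovery carryover.** Re-watered plants do not resume their
  end-of-drought relative transpiration at once — stomatal reopening and
  hydraulic repair take days, and published recovery-phase rTR levels sit
  *below* end-of-drought levels. The simulator therefore starts the
  recovery multiplier at `recovery_depression` (default 0.7) times the
  end-of-drought rTR and raises it linearly at the cultivar's configured
  recovery rate, saturating at 1. The default depression reproduces
  recovery-phase rTR levels of roughly 0.5 for the least resilient and
  0.7 for the most resilient reference cultivar. Without the depression
  the multiplier saturates mid-phase for conserving cultivars and the
  configured linear recovery rate would not be identifiable from the
  simulated data at all.
- **Re-irrigation at recovery onset** is delivered in the early-morning
  pulse window of the first recovery day, so the recovery phase starts
  from a refilled pot.
- **Harvest synthesis** is plumbing, not a crop model: biomass is the
  cultivar potential reduced in proportion (penalty 0.5) to the relative
  cumulative-transpiration deficit against the cultivar's control mean,
  grain is harvest index times biomass, with 5% CV noise.
- **Measurement noise** is i.i.d. Gaussian per weight record and does not
  feed back into the water state, so at `noise_sd = 0` conservation is
  exact by construction: for any plant and any day, (weight at day start -
  weight at day end + irrigation) equals true transpiration.

All randomness flows from one seed (`rng_seed`); the same seed reproduces
every series byte for byte.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: plant growth and the attendant drift in tare and
leaf area; temperature response of transpiration; pot-to-pot microclimate
differences; sensor drift, spikes and drainage leaks beyond Gaussian noise;
nonlinear (e.g. exponential) decline shapes below the breakpoint; and any
root-architecture mechanism behind cultivar differences in
$\theta_{\text{crit}}$. Real traces will need the smoothing, masking and
coverage rules to do actual work, and fitted parameters will inherit
whatever structured noise those rules do not remove.

## Validation suite and problem sizes

The package validates itself at sizes chosen to exercise each claim
without waste:

- worked-example geometry: closed-form checks on the four published
  parameter sets (milliseconds);
- estimator-vs-oracle: 200 random instances with up to 50 points, each
  compared against an independent exhaustive brute-force search (dense
  $10^{-4}$ breakpoint grid through the normal equations plus a
  golden-section polish), agreeing on SSE to $10^{-10}$ through a common
  evaluator and on the breakpoint to $10^{-3}$;
- parameter recovery: 200 replicates per cultivar of 60 points at 5% rate
  noise, requiring the breakpoint within $\pm 0.02$ and the slope within
  $\pm 10\%$ in at least 90% of replicates;
- end-to-end closure: one noiseless full-size run (36 plants, 39 days,
  3-min records) for exact extraction and conservation, plus 100 noisy
  replicates for recovery-rate fidelity within $\pm 0.005$ rTR/day.

## Known limitations

Nighttime respiration cannot be separated from nocturnal irrigation in
this design, so it is neither simulated as a distinct flux nor extractable.
The bilinear decline is the only response shape offered; no mixed-effects
or hydraulic (xylem-tension) models are attempted. The classification is
rank-based within an experiment and says nothing absolute about
isohydry/anisohydry, which would require leaf water potential. Inference
beyond the per-plant metrics (heteroscedasticity-aware group comparisons,
multiple-testing control) is intentionally left to standard tools — the
metrics tables are tidy inputs for them.
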