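# Segmented plateau-then-decline regression of transpiration rate on soil
# water content. For a fixed breakpoint theta the model
#   TR(s) = tr_max                           for s >= theta
#   TR(s) = tr_max - slope * (theta - s)     for s <  theta
# is linear in (tr_max, slope) via the hinge h = max(0, theta - s), so each
# candidate breakpoint is solved in closed form (constrained to slope >= 0)
# and theta is profiled.

# closed-form profile fit at one breakpoint; Inf SSE if inadmissible
.bl_profile <- function(theta, s, y, min_seg = 2L) {
  h <- pmax(0, theta - s)
  nb <- sum(h > 0)
  if (nb < min_seg || (length(s) - nb) < min_seg)
    return(list(sse = Inf, tr_max = NA_real_, slope = NA_real_))
  hb <- mean(h)
  yb <- mean(y)
  hc <- h - hb
  sxx <- sum(hc * hc)
  b <- if (sxx > 0) -sum(hc * (y - yb)) / sxx else 0
  if (b < 0) {
    b <- 0
    a <- yb
  } else {
    a <- yb + b * hb
  }
  r <- y - (a - b * h)
  list(sse = sum(r * r), tr_max = a, slope = b)
}

.bl_degenerate <- function(s, y, xname, yname, call) {
  sst <- sum((y - mean(y))^2)
  structure(list(
    tr_max = mean(y), theta_crit = min(s), slope = 0, terminal = NULL,
    r_squared = if (sst > 0) 0 else NA_real_, sse = sst,
    sigma = sqrt(sst / max(1L, length(y) - 1L)), n_points = length(y),
    status = "degenerate", xname = xname, yname = yname,
    data = stats::setNames(data.frame(s, y), c(xname, yname)), call = call),
    class = "bilinear")
}

#' Fit the plateau-then-decline transpiration model
#'
#' Fits the segmented (bilinear) response of midday transpiration rate to
#' volumetric soil water content: a horizontal plateau at the maximum rate
#' `tr_max` for soil water contents at or above the breakpoint
#' `theta_crit`, and a linear decline of slope `slope` below it, continuous
#' at the breakpoint. Parameters minimise the residual sum of squares: the
#' breakpoint is profiled over a candidate grid (each candidate solved in
#' closed form by constrained least squares, `slope >= 0`), the grid is
#' augmented with the midpoints of all admissible inter-point intervals,
#' and the optimum is refined by local search within every admissible
#' interval between consecutive observed soil water contents, so the
#' global SSE minimum is found. Ties are broken towards the largest
#' breakpoint (earlier stress onset). An admissible breakpoint must leave
#' at least `min_seg` points on each side (identifiability).
#'
#' When the data cannot identify a declining limb (all points in one
#' regime, or the unconstrained decline is non-positive, e.g. points on a
#' horizontal line) the fit is flagged `status = "degenerate"`: the slope
#' is 0, the plateau is the mean rate and the breakpoint is reported at
#' the minimum observed soil water content — never silent numbers.
#'
#' @param formula Model formula, rate ~ soil water content, e.g.
#'   `tr_rate ~ swc`.
#' @param data Data frame holding the variables; soil water content must
#'   lie in \[0, 1\] and rates must be non-negative.
#' @param grid Number of profiling candidates spanning the inner
#'   quantile range of the observed soil water contents.
#' @param min_seg Minimum number of points on each side of an admissible
#'   breakpoint.
#' @param range_quantiles Quantile range of observed soil water content
#'   spanned by the uniform candidate grid.
#' @param tol Convergence tolerance of the local refinement.
#'
#' @return An object of class `bilinear` with components `tr_max`,
#'   `theta_crit`, `slope`, `terminal` (set by
#'   [terminal_drought_point()]), `r_squared` (against the grand mean),
#'   `sse`, `sigma`, `n_points` and `status` ("ok" or "degenerate").
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`.
#' @seealso [terminal_drought_point()], [trapezoid_area()],
#'   [slope_from_geometry()], [simulate_rate_points()]
#' @examples
#' pts <- simulate_rate_points(barley_profiles()$CHAN, n = 60,
#'                             noise_sd = 0, seed = 1)
#' fit <- bilinear(tr_rate ~ swc, pts)
#' coef(fit)
#' @export
bilinear <- function(formula, data, grid = 200, min_seg = 2,
                     range_quantiles = c(0.05, 0.95), tol = 1e-10) {
  mf <- model.frame(formula, data)
  y <- as.numeric(model.response(mf))
  s <- as.numeric(mf[[2L]])
  xname <- names(mf)[2L]
  yname <- names(mf)[1L]
  min_seg <- check_count(min_seg, "min_seg")
  n <- length(y)
  if (n < max(5L, 2L * min_seg))
    stopf("at least %d points are required to fit the bilinear model",
          max(5L, 2L * min_seg))
  if (any(!is.finite(s)) || any(!is.finite(y)))
    stopf("non-finite values in the model variables")
  if (any(s < 0 | s > 1))
    stopf("soil water content must lie within [0, 1]")
  if (any(y < 0))
    stopf("transpiration rates must be non-negative")
  cl <- match.call()

  ss <- sort(s)
  lo <- ss[min_seg]            # need min_seg points strictly below theta
  hi <- ss[n - min_seg + 1L]   # and min_seg points at or above theta
  if (!(hi > lo)) return(.bl_degenerate(s, y, xname, yname, cl))

  qs <- as.numeric(quantile(s, range_quantiles))
  g_lo <- max(lo + 1e-9, qs[1L])
  g_hi <- min(hi, qs[2L])
  cand <- if (g_hi > g_lo) seq(g_lo, g_hi, length.out = grid) else numeric()
  uu <- unique(ss)
  bounds <- uu[uu >= lo & uu <= hi]
  if (length(bounds) >= 2L)
    cand <- c(cand, (bounds[-1L] + bounds[-length(bounds)]) / 2)
  cand <- sort(unique(c(cand, bounds[-1L], hi)))
  cand <- cand[cand > lo & cand <= hi]
  if (!length(cand)) return(.bl_degenerate(s, y, xname, yname, cl))

  sse_at <- function(th) .bl_profile(th, s, y, min_seg)$sse
  prof <- vapply(cand, sse_at, 0)
  best_th <- cand[which.min(prof)]
  best_sse <- min(prof)
  # continuous refinement inside every admissible inter-point interval
  if (length(bounds) >= 2L) {
    for (k in seq_len(length(bounds) - 1L)) {
      a <- bounds[k]; b <- bounds[k + 1L]
      if (b - a < 4 * tol) next
      opt <- optimize(sse_at, lower = a + 1e-12, upper = b, tol = tol)
      if (opt$objective < best_sse - 1e-12 ||
          (abs(opt$objective - best_sse) <= 1e-12 &&
           opt$minimum > best_th)) {
        best_sse <- opt$objective
        best_th <- opt$minimum
      }
    }
  }
  # final golden-section polish of the winning basin: optimize() stops at a
  # machine-limited bracket, the SSE profile is flat-quadratic at the
  # optimum, and downstream geometry wants the breakpoint as tight as the
  # arithmetic allows
  ib <- findInterval(best_th, bounds)
  g_a <- if (ib >= 1L) bounds[ib] + 1e-12 else lo + 1e-12
  g_b <- if (ib < length(bounds)) bounds[ib + 1L] else hi
  if (g_b > g_a) {
    gr <- (sqrt(5) - 1) / 2
    a <- g_a; b <- g_b
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- sse_at(x1); f2 <- sse_at(x2)
    while (b - a > 1e-12) {
      if (f1 < f2) {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- sse_at(x1)
      } else {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- sse_at(x2)
      }
    }
    th_p <- (a + b) / 2
    sse_p <- sse_at(th_p)
    if (sse_p <= best_sse) {
      best_sse <- sse_p
      best_th <- th_p
    }
  }
  fit <- .bl_profile(best_th, s, y, min_seg)
  if (!is.finite(fit$sse) || fit$slope <= 1e-10)
    return(.bl_degenerate(s, y, xname, yname, cl))
  sst <- sum((y - mean(y))^2)
  structure(list(
    tr_max = fit$tr_max, theta_crit = best_th, slope = fit$slope,
    terminal = NULL,
    r_squared = if (sst > 0) 1 - fit$sse / sst else NA_real_,
    sse = fit$sse, sigma = sqrt(fit$sse / max(1L, n - 3L)), n_points = n,
    status = "ok", xname = xname, yname = yname,
    data = stats::setNames(data.frame(s, y), c(xname, yname)), call = cl),
    class = "bilinear")
}

#' Construct a bilinear model from known parameters
#'
#' Builds a `bilinear` object directly from plateau rate, breakpoint and
#' decline slope (e.g. published estimates), without data.
#'
#' @param tr_max Plateau rate, g/min.
#' @param theta_crit Breakpoint soil water content.
#' @param slope Decline slope, (g/min)/(cm^3/cm^3).
#' @return A `bilinear` object with `status = "ok"` and no data.
#' @export
bilinear_model <- function(tr_max, theta_crit, slope) {
  check_number(tr_max, "tr_max", lower = 0, strict_lower = TRUE)
  check_number(theta_crit, "theta_crit", lower = 0, upper = 1)
  check_number(slope, "slope", lower = 0)
  structure(list(tr_max = tr_max, theta_crit = theta_crit, slope = slope,
                 terminal = NULL, r_squared = NA_real_, sse = NA_real_,
                 sigma = NA_real_, n_points = 0L, status = "ok",
                 xname = "swc", yname = "tr_rate", data = NULL,
                 call = match.call()), class = "bilinear")
}

#' Construct a bilinear model from its plotted geometry
#'
#' Builds a `bilinear` object from the plateau rate, breakpoint and
#' terminal drought point, deriving the decline slope from the geometry
#' via [slope_from_geometry()] and storing the terminal point.
#'
#' @inheritParams bilinear_model
#' @param swc_term Soil water content at the terminal drought point.
#' @param tr_term Transpiration rate at the terminal drought point, g/min.
#' @return A `bilinear` object with the terminal point set.
#' @examples
#' m <- bilinear_from_geometry(0.50, 0.476, swc_term = 0.308,
#'                             tr_term = 0.211)
#' trapezoid_area(m)$analytic
#' @export
bilinear_from_geometry <- function(tr_max, theta_crit, swc_term, tr_term) {
  m <- bilinear_model(tr_max, theta_crit,
                      slope_from_geometry(tr_max, theta_crit, swc_term,
                                          tr_term))
  m$terminal <- c(swc = swc_term, tr = tr_term)
  m
}

#' @export
coef.bilinear <- function(object, ...) {
  c(tr_max = object$tr_max, theta_crit = object$theta_crit,
    slope = object$slope)
}

#' @export
predict.bilinear <- function(object, newdata, ...) {
  s <- if (missing(newdata) || is.null(newdata)) {
    if (is.null(object$data)) stopf("no data stored; supply 'newdata'")
    object$data[[object$xname]]
  } else if (is.numeric(newdata)) {
    newdata
  } else {
    newdata[[object$xname]]
  }
  object$tr_max - object$slope * pmax(0, object$theta_crit - s)
}

#' @export
fitted.bilinear <- function(object, ...) predict(object)

#' @export
residuals.bilinear <- function(object, ...) {
  if (is.null(object$data)) stopf("no data stored in this model")
  object$data[[object$yname]] - fitted(object)
}

#' @export
print.bilinear <- function(x, ...) {
  cat("Bilinear transpiration-SWC model\n")
  cat(sprintf("  TRmax      %.4f g/min\n  theta_crit %.4f\n  slope      %.4f\n",
              x$tr_max, x$theta_crit, x$slope))
  if (!is.null(x$terminal))
    cat(sprintf("  terminal   TR %.4f g/min at SWC %.4f\n",
                x$terminal[["tr"]], x$terminal[["swc"]]))
  cat(sprintf("  status %s, n = %d%s\n", x$status, x$n_points,
              if (is.finite(x$r_squared))
                sprintf(", R^2 = %.3f", x$r_squared) else ""))
  invisible(x)
}

#' @export
summary.bilinear <- function(object, ...) {
  structure(list(fit = object), class = "summary.bilinear")
}

#' @export
print.summary.bilinear <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (f$status == "ok" && !is.null(f$terminal)) {
    ar <- trapezoid_area(f)
    cat(sprintf("  trapezoid water-use integral: %.4f (g/min)(cm3/cm3)\n",
                ar$analytic))
  }
  if (!is.null(f$data)) {
    cat(sprintf("  residual sd %.4f on %d points\n", f$sigma, f$n_points))
  }
  invisible(x)
}

#' @export
plot.bilinear <- function(x, ...,
                          xlab = "volumetric SWC (cm3/cm3)",
                          ylab = "TR rate (g/min)", main = NULL) {
  if (!is.null(x$data)) {
    plot(x$data[[x$xname]], x$data[[x$yname]], pch = 16,
         col = adjustcolor("grey30", 0.6), xlab = xlab, ylab = ylab,
         main = main, ...)
    rng <- range(x$data[[x$xname]])
  } else {
    rng <- c(if (!is.null(x$terminal)) x$terminal[["swc"]] else
      max(0, x$theta_crit - 0.2), min(1, x$theta_crit + 0.1))
    plot(NA, xlim = rng, ylim = c(0, x$tr_max * 1.1), xlab = xlab,
         ylab = ylab, main = main, ...)
  }
  sgrid <- seq(rng[1L], rng[2L], length.out = 200)
  lines(sgrid, predict(x, sgrid), col = "firebrick", lwd = 2)
  abline(v = x$theta_crit, lty = 2, col = "steelblue")
  if (!is.null(x$terminal))
    abline(v = x$terminal[["swc"]], lty = 3, col = "darkgreen")
  invisible(x)
}

#' @export
simulate.bilinear <- function(object, nsim = 1, seed = NULL, swc = NULL,
                              noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(swc)) {
    if (is.null(object$data)) stopf("no data stored; supply 'swc'")
    swc <- object$data[[object$xname]]
  }
  sdv <- noise_sd %||% object$sigma
  if (!is.finite(sdv)) stopf("no residual scale available; supply 'noise_sd'")
  mu <- predict(object, swc)
  out <- as.data.frame(
    vapply(seq_len(nsim), function(i) pmax(0, mu + rnorm(length(mu), 0, sdv)),
           numeric(length(mu))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Terminal drought point of a fitted model
#'
#' The last point on the falling limb of the bilinear model: the minimum
#' observed soil water content among the drought-phase midday points, and
#' the fitted transpiration rate there. Stored into the model object.
#'
#' @param fit A non-degenerate `bilinear` object.
#' @param points The rate points used for the fit (data frame with the
#'   model's soil-water-content column, or a numeric vector of soil water
#'   contents). Defaults to the data stored in the fit.
#' @return The `bilinear` object with `terminal = c(swc, tr)` set.
#' @examples
#' m <- bilinear_model(0.68, 0.557, 2.56)
#' terminal_drought_point(m, 0.347)$terminal
#' @export
terminal_drought_point <- function(fit, points = NULL) {
  stopifnot(inherits(fit, "bilinear"))
  if (fit$status != "ok")
    stopf("terminal drought point is undefined for a degenerate fit")
  s <- if (is.null(points)) {
    if (is.null(fit$data)) stopf("no data stored; supply 'points'")
    fit$data[[fit$xname]]
  } else if (is.numeric(points)) {
    points
  } else {
    points[[fit$xname]]
  }
  swc_term <- min(s)
  fit$terminal <- c(swc = swc_term, tr = predict(fit, swc_term))
  fit
}

#' Trapezoid water-use integral of the declining limb
#'
#' Integral of the fitted declining line between the terminal-drought soil
#' water content and the breakpoint — the trapezoid bounded by the
#' breakpoint, the x-axis interval and the terminal drought point. It
#' estimates the water transpired per unit soil water content after
#' physiological drought set in. Computed analytically,
#' `(tr_max + tr_term) * (theta_crit - swc_term) / 2`, and cross-checked by
#' numerical quadrature of the fitted line; both values are returned.
#'
#' @param fit A `bilinear` object with the terminal point set.
#' @return List with `analytic` and `quadrature` (both in
#'   (g/min)\eqn{\times}(cm^3/cm^3)) and `width` (`theta_crit - swc_term`).
#' @examples
#' m <- bilinear_from_geometry(0.57, 0.579, swc_term = 0.385,
#'                             tr_term = 0.209)
#' trapezoid_area(m)
#' @export
trapezoid_area <- function(fit) {
  stopifnot(inherits(fit, "bilinear"))
  if (fit$status != "ok")
    stopf("trapezoid area is undefined for a degenerate fit")
  if (is.null(fit$terminal))
    stopf("terminal drought point is not set; call terminal_drought_point()")
  swc_term <- fit$terminal[["swc"]]
  tr_term <- fit$terminal[["tr"]]
  width <- fit$theta_crit - swc_term
  if (width <= 0)
    return(list(analytic = 0, quadrature = 0, width = max(0, width)))
  analytic <- 0.5 * (fit$tr_max + tr_term) * width
  quad <- integrate(function(u) predict(fit, u), lower = swc_term,
                    upper = fit$theta_crit)$value
  list(analytic = analytic, quadrature = quad, width = width)
}

#' Decline slope implied by the model geometry
#'
#' Consistency utility: the slope of the falling limb implied by the
#' plateau rate, the breakpoint and the terminal drought point,
#' `(tr_max - tr_term) / (theta_crit - swc_term)`.
#'
#' @inheritParams bilinear_from_geometry
#' @return Slope in (g/min)/(cm^3/cm^3).
#' @examples
#' slope_from_geometry(0.68, 0.557, swc_term = 0.347, tr_term = 0.141)
#' @export
slope_from_geometry <- function(tr_max, theta_crit, swc_term, tr_term) {
  check_number(tr_max, "tr_max", lower = 0)
  check_number(theta_crit, "theta_crit", lower = 0, upper = 1)
  check_number(swc_term, "swc_term", lower = 0, upper = 1)
  check_number(tr_term, "tr_term", lower = 0)
  denom <- theta_crit - swc_term
  if (denom <= 0)
    stopf("theta_crit must exceed the terminal soil water content")
  (tr_max - tr_term) / denom
}

#' Cumulative transpiration between two time points
#'
#' Sums a plant's daily transpiration over the dates spanned by two time
#' points, typically the first midday crossing below the breakpoint and
#' the end of the terminal drought day. Only days passing the coverage
#' rule contribute.
#'
#' @param flux A [extract_flux()] result.
#' @param from,to Dates or timestamps, `from` strictly before `to`.
#' @return Total transpired mass, g, with attribute `n_days` (valid days).
#' @export
cumulative_transpiration_between <- function(flux, from, to) {
  stopifnot(inherits(flux, "plant_flux"))
  from <- as.Date(from)
  to <- as.Date(to)
  if (!(from < to)) stopf("'from' must be strictly before 'to'")
  sel <- flux$daily$date >= from & flux$daily$date <= to & flux$daily$valid
  out <- sum(flux$daily$daily_tr_g[sel])
  attr(out, "n_days") <- sum(sel)
  out
}

#' Locate the physiological-drought window of a plant
#'
#' Finds the first drought-phase day whose midday soil water content falls
#' below the breakpoint, and the last drought-phase day. When the crossing
#' never occurs the status is `"no physiological drought"`.
#'
#' @param flux A [extract_flux()] result.
#' @param theta_crit Breakpoint soil water content.
#' @param calendar A [phase_calendar()].
#' @return List with `from`, `to` (dates) and `status`.
#' @export
drought_window <- function(flux, theta_crit, calendar) {
  stopifnot(inherits(flux, "plant_flux"))
  dd <- phase_dates(calendar, "drought")
  sub <- flux$daily[flux$daily$date %in% dd & flux$daily$valid, ]
  below <- which(sub$swc_midday < theta_crit)
  if (!length(below))
    return(list(from = as.Date(NA), to = as.Date(NA),
                status = "no physiological drought"))
  list(from = sub$date[below[1L]], to = max(sub$date), status = "ok")
}

#' Simulate rate points from a cultivar's bilinear response
#'
#' Draws midday rate-vs-SWC working points from a cultivar's
#' piecewise-linear response with additive Gaussian rate noise (floored at
#' zero), for estimator validation.
#'
#' @param profile A [cultivar_profile].
#' @param n Number of points.
#' @param noise_sd Rate noise standard deviation, g/min (default 5% of the
#'   cultivar's plateau rate).
#' @param swc_range Range from which soil water contents are drawn
#'   uniformly.
#' @param seed Optional RNG seed.
#' @return Data frame with `swc` and `tr_rate`.
#' @export
simulate_rate_points <- function(profile, n = 60,
                                 noise_sd = 0.05 * profile$tr_max,
                                 swc_range = c(0.30, 0.70), seed = NULL) {
  stopifnot(inherits(profile, "cultivar_profile"))
  n <- check_count(n, "n")
  if (!is.null(seed)) set.seed(seed)
  swc <- runif(n, swc_range[1L], swc_range[2L])
  mu <- pmax(0, profile$tr_max -
               profile$decline_slope * pmax(0, profile$theta_crit - swc))
  data.frame(swc = swc, tr_rate = pmax(0, mu + rnorm(n, 0, noise_sd)))
}
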