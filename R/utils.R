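# internal helpers; all times are POSIXct UTC, all dates Date

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

date_utc <- function(t) {
  if (inherits(t, "POSIXct"))
    return(.Date(floor(as.numeric(t) / 86400)))
  as.Date(t, tz = "UTC")
}

# minutes since midnight UTC, integral for grid-aligned series
minute_of_day <- function(t) (as.numeric(t) %/% 60) %% 1440

# "HH:MM" -> minutes since midnight
hm_to_min <- function(x) {
  p <- strsplit(as.character(x), ":", fixed = TRUE)[[1L]]
  as.numeric(p[1L]) * 60 + as.numeric(p[2L])
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stopf("'%s' = %g is outside the admissible range %s%g, %g%s", name, x,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]")
  invisible(x)
}

check_count <- function(x, name, lower = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < lower)
    stopf("'%s' must be an integer >= %g", name, lower)
  invisible(as.integer(x))
}

odd_width <- function(k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k + 1L else k
}
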