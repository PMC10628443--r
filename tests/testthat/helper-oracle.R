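# Independent brute-force oracle for the segmented fit: exhaustive search
# over a dense breakpoint grid, each candidate solved through the 2x2
# normal equations (a different algebraic route from the package's centred
# profile formulas), then a hand-coded golden-section polish in the winning
# cell.

oracle_sse <- function(theta, s, y, min_seg = 2) {
  h <- pmax(0, theta - s)
  nb <- sum(h > 0)
  if (nb < min_seg || length(s) - nb < min_seg) return(Inf)
  X <- cbind(1, -h)
  ab <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                 error = function(e) NULL)
  if (is.null(ab) || ab[2L] < 0) ab <- c(mean(y), 0)
  r <- y - X %*% ab
  sum(r * r)
}

brute_bilinear <- function(s, y, grid_step = 1e-4, min_seg = 2) {
  n <- length(s)
  ss <- sort(s)
  lo <- ss[min_seg]
  hi <- ss[n - min_seg + 1L]
  g <- seq(lo + grid_step, hi, by = grid_step)
  sses <- vapply(g, oracle_sse, 0, s = s, y = y, min_seg = min_seg)
  th <- g[which.min(sses)]
  a <- max(lo + 1e-12, th - grid_step)
  b <- min(hi, th + grid_step)
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- oracle_sse(x1, s, y, min_seg); f2 <- oracle_sse(x2, s, y, min_seg)
  while (b - a > 1e-12) {
    if (f1 < f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- oracle_sse(x1, s, y, min_seg)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- oracle_sse(x2, s, y, min_seg)
    }
  }
  th2 <- (a + b) / 2
  s2 <- oracle_sse(th2, s, y, min_seg)
  if (s2 <= min(sses)) list(theta = th2, sse = s2)
  else list(theta = th, sse = min(sses))
}

# random fit instance spanning both regimes
random_instance <- function(n = NULL) {
  n <- n %||% sample(10:50, 1)
  trm <- runif(1, 0.3, 0.8)
  th <- runif(1, 0.35, 0.65)
  sl <- runif(1, 0.5, 3)
  sd0 <- runif(1, 0, 0.08)
  s <- runif(n, 0.25, 0.75)
  y <- pmax(0, trm - sl * pmax(0, th - s) + rnorm(n, 0, sd0))
  list(data = data.frame(swc = s, tr_rate = y),
       truth = c(tr_max = trm, theta_crit = th, slope = sl))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
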