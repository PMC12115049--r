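# Brute-force, explicit-loop oracles kept deliberately independent of
# the package's vectorized implementations.

oracle_pearson <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n
  yb <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - xb) * (y[i] - yb)
    dx2 <- dx2 + (x[i] - xb)^2
    dy2 <- dy2 + (y[i] - yb)^2
  }
  num / sqrt(dx2 * dy2)
}

oracle_stats <- function(v) {
  n <- length(v)
  m <- 0
  for (x in v) m <- m + x
  m <- m / n
  ss <- 0
  for (x in v) ss <- ss + (x - m)^2
  s <- sqrt(ss / (n - 1))
  c(mean = m, sd = s, cv_percent = 100 * s / m)
}

oracle_metrics <- function(obs, pred) {
  n <- length(obs)
  ssres <- 0; sabs <- 0
  for (i in seq_len(n)) {
    ssres <- ssres + (obs[i] - pred[i])^2
    sabs <- sabs + abs(obs[i] - pred[i])
  }
  ob <- sum(obs) / n
  sstot <- 0
  for (i in seq_len(n)) sstot <- sstot + (obs[i] - ob)^2
  rmse <- sqrt(ssres / n)
  c(r2 = 1 - ssres / sstot, rmse = rmse, mae = sabs / n,
    rpd = sqrt(sstot / (n - 1)) / rmse)
}

oracle_sum <- function(v) {
  s <- 0
  for (x in v) s <- s + x
  s
}

# independent point-to-source distance (grid search along polyline)
oracle_source_proximity <- function(x, y, geom, lambda) {
  vapply(seq_along(x), function(i) {
    if (nrow(geom) == 1) {
      d <- sqrt((x[i] - geom$x)^2 + (y[i] - geom$y)^2)
    } else {
      d <- Inf
      for (k in seq_len(nrow(geom) - 1)) {
        for (t in seq(0, 1, length.out = 2001)) {
          px <- geom$x[k] + t * (geom$x[k + 1] - geom$x[k])
          py <- geom$y[k] + t * (geom$y[k + 1] - geom$y[k])
          d <- min(d, sqrt((x[i] - px)^2 + (y[i] - py)^2))
        }
      }
    }
    exp(-d / lambda)
  }, numeric(1))
}
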