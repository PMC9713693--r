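# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Small mixed-coupling session: 10 ROIs (first 5 coupled 0.5 to theta),
# 16 electrodes, 2 minutes.
smallSession <- function() {
  if (is.null(.fixtures$small)) {
    cm <- matrix(0, 10, 4)
    cm[1:5, 1] <- 0.5
    cfg <- sessionConfig(n_rois = 10, n_electrodes = 16, duration_s = 120,
                         ephys_rate_hz = 250, coupling_matrix = cm,
                         seed = 42)
    .fixtures$small <- generateSession(cfg)
  }
  .fixtures$small
}

smallBandPower <- function() {
  if (is.null(.fixtures$small_bp)) {
    s <- smallSession()
    .fixtures$small_bp <- bandPowerTraces(s$ephys, frameTimes(s$traces))
  }
  .fixtures$small_bp
}

# Brute-force two-sample 1-D KS statistic: exhaustive CDF-gap scan.
ks1dOracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(t)
    abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# Brute-force Fasano-Franceschini 2-D statistic: for every data point of
# either sample, compare the four quadrant empirical CDFs.
ks2dOracle <- function(x1, y1, x2, y2) {
  d <- 0
  ex <- c(x1, x2); ey <- c(y1, y2)
  for (i in seq_along(ex)) {
    px <- ex[i]; py <- ey[i]
    quads <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE),
                  c(FALSE, FALSE))
    for (q in quads) {
      in1 <- (if (q[1]) x1 <= px else x1 > px) &
             (if (q[2]) y1 <= py else y1 > py)
      in2 <- (if (q[1]) x2 <= px else x2 > px) &
             (if (q[2]) y2 <= py else y2 > py)
      d <- max(d, abs(mean(in1) - mean(in2)))
    }
  }
  d
}

# Hand Pearson correlation from the definition.
pearsonOracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
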