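# Internal helpers: seeded evaluation, seed splitting, small numeric utilities.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All package randomness funnels
# through this so results are reproducible and side-effect free.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based seed splitting: derive an independent sub-seed for component
# `index` of a generator seeded with `seed`. Lehmer-style mix, kept < 2^31.
splitSeed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  for (k in seq_len(2)) s <- (s * 48271 + as.numeric(index) * 104729) %% m
  as.integer(s)
}

# Local maxima of a numeric vector with a minimum separation (in samples).
# Ties broken toward the earlier index; plateau centers are used.
localMaxima <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  sort(keep)
}

# Parabolic (three-point) interpolation of a peak position around index i.
refinePeak <- function(x, i) {
  if (i <= 1 || i >= length(x)) return(as.numeric(i))
  y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(as.numeric(i))
  i + 0.5 * (y1 - y3) / denom
}

# 2-D Gaussian smoothing with mask renormalization: unobserved cells
# (mask FALSE or NA values) are excluded from the kernel support so mass
# is not smeared into them and estimates near the mask edge stay unbiased.
maskedGaussianSmooth <- function(z, sigma, mask = NULL) {
  if (sigma <= 0) return(z)
  if (is.null(mask)) mask <- !is.na(z)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  zf <- z
  zf[!mask] <- 0
  m <- matrix(as.numeric(mask), nrow(z), ncol(z))
  sep <- function(a) {
    a <- apply(a, 2, function(col) as.numeric(filter(c(rep(0, half), col, rep(0, half)),
                                                     k, sides = 2))[(half + 1):(half + length(col))])
    a <- t(apply(a, 1, function(row) as.numeric(filter(c(rep(0, half), row, rep(0, half)),
                                                       k, sides = 2))[(half + 1):(half + length(row))]))
    a
  }
  num <- sep(zf)
  den <- sep(m)
  out <- num / den
  out[!mask] <- NA_real_
  out
}

# Rolling minimum with a centered window (used for baseline subtraction).
rollingMin <- function(x, window) {
  n <- length(x)
  half <- max(1L, floor(window / 2))
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    min(x[lo:hi])
  }, numeric(1))
}

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(TRUE)
}
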