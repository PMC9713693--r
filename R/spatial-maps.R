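# Freely-moving analyses: head velocity, transient positions,
# occupancy-normalized smoothed spatial activity maps, and pairwise 2-D
# Kolmogorov-Smirnov comparisons between maps.

#' Head velocity from a behavior track
#'
#' Centered finite-difference speed (one-sided at the ends), boxcar
#' smoothed over `smooth_window_s`. Output length equals the track length.
#'
#' @param track a [BehaviorTrack].
#' @param smooth_window_s boxcar window in seconds; 0 disables smoothing.
#' @return numeric speed per track point, px/s.
#' @export
headVelocity <- function(track, smooth_window_s = 0.5) {
  t <- trackTimes(track)
  if (length(t) < 2) stop("need at least 2 track points", call. = FALSE)
  if (any(diff(t) == 0)) stop("duplicate track timestamps", call. = FALSE)
  xy <- trackXY(track)
  n <- length(t)
  im <- c(1, seq_len(n - 2), n - 1)
  ip <- c(2, seq_len(n - 2) + 2, n)
  v <- sqrt((xy[ip, 1] - xy[im, 1])^2 + (xy[ip, 2] - xy[im, 2])^2) /
    (t[ip] - t[im])
  if (smooth_window_s > 0) {
    w <- max(1L, round(smooth_window_s * track@rate_hz))
    if (w %% 2 == 0) w <- w + 1L
    if (w > 1) {
      k <- rep(1 / w, w)
      half <- (w - 1L) %/% 2L
      padded <- c(rep(v[1], half), v, rep(v[n], half))
      v <- as.numeric(filter(padded, k, sides = 2))[(half + 1):(half + n)]
    }
  }
  v
}

#' Arena positions at calcium transient onsets
#'
#' A transient onset is an upward crossing of
#' `median + threshold_sd * robust SD` (robust SD = scaled MAD) by the
#' dF/F trace; the reported position is the track sample nearest in time
#' (imaging clock) to the onset frame. No crossings give an empty result,
#' not an error.
#'
#' @param trace numeric dF/F vector for one ROI.
#' @param frame_times_s its frame timestamps (imaging clock).
#' @param track a [BehaviorTrack], synced via [applySync()] if needed.
#' @param threshold_sd threshold in robust SDs above the median.
#' @return data.frame with `frame`, `time_s`, `x_px`, `y_px`.
#' @export
transientPositions <- function(trace, frame_times_s, track,
                               threshold_sd = 3) {
  thr <- median(trace) + threshold_sd * mad(trace)
  above <- trace >= thr
  onsets <- which(above[-1] & !above[-length(above)]) + 1L
  if (above[1]) onsets <- c(1L, onsets)
  if (!length(onsets))
    return(data.frame(frame = integer(0), time_s = numeric(0),
                      x_px = numeric(0), y_px = numeric(0)))
  tt <- trackTimes(track, "imaging")
  xy <- trackXY(track)
  nearest <- vapply(frame_times_s[onsets],
                    function(t0) which.min(abs(tt - t0)), integer(1))
  data.frame(frame = onsets, time_s = frame_times_s[onsets],
             x_px = xy[nearest, 1], y_px = xy[nearest, 2])
}

#' Occupancy-normalized smoothed spatial activity map
#'
#' Bins the arena into `bin_px` x `bin_px` cells; occupancy is the time the
#' animal spent per cell (from the video-rate track), activity is the
#' summed dF/F assigned by the animal's position at each imaging frame.
#' The normalized map is activity / occupancy on visited bins, Gaussian
#' smoothed with `sigma_px` using a kernel renormalized over the visited
#' support; unvisited bins stay `NA`.
#'
#' @param trace numeric dF/F vector for one ROI.
#' @param frame_times_s imaging frame timestamps.
#' @param track a [BehaviorTrack] covering the arena.
#' @param arena_px arena width and height in pixels.
#' @param bin_px bin side in pixels (> 0).
#' @param sigma_px smoothing sigma in pixels; 0 disables smoothing.
#' @param roi_id label stored in the result.
#' @return a [SpatialMap-class].
#' @export
buildSpatialMap <- function(trace, frame_times_s, track,
                            arena_px = c(600, 600), bin_px = 25,
                            sigma_px = 62.5, roi_id = "roi") {
  if (bin_px <= 0) stop("bin_px must be > 0", call. = FALSE)
  nx <- ceiling(arena_px[1] / bin_px)
  ny <- ceiling(arena_px[2] / bin_px)
  tt <- trackTimes(track, "imaging")
  xy <- trackXY(track)
  binOf <- function(x, y) {
    bx <- pmin(nx, pmax(1L, floor(x / bin_px) + 1L))
    by <- pmin(ny, pmax(1L, floor(y / bin_px) + 1L))
    cbind(by, bx)
  }
  # occupancy from the video-rate track
  occ <- matrix(0, ny, nx)
  bt <- binOf(xy[, 1], xy[, 2])
  dt_v <- 1 / track@rate_hz
  for (i in seq_len(nrow(bt))) occ[bt[i, 1], bt[i, 2]] <-
      occ[bt[i, 1], bt[i, 2]] + dt_v
  # activity from the imaging-rate trace at the interpolated position
  px <- approx(tt, xy[, 1], xout = frame_times_s, rule = 2)$y
  py <- approx(tt, xy[, 2], xout = frame_times_s, rule = 2)$y
  act <- matrix(0, ny, nx)
  bf <- binOf(px, py)
  for (i in seq_along(trace)) act[bf[i, 1], bf[i, 2]] <-
      act[bf[i, 1], bf[i, 2]] + trace[i]
  visited <- occ > 0
  norm <- act / occ
  norm[!visited] <- NA_real_
  if (sigma_px > 0)
    norm <- maskedGaussianSmooth(norm, sigma_px / bin_px, visited)
  methods::new("SpatialMap", occupancy_s = occ, activity = act,
               normalized = norm, visited = visited, bin_px = bin_px,
               sigma_px = sigma_px, arena_px = as.numeric(arena_px),
               roi_id = as.character(roi_id))
}

# Fasano-Franceschini statistic: max over all data points (both samples)
# of the max over the four quadrants of |F1 - F2|, where F is the
# empirical quadrant CDF at that point. The pooled indicator matrices are
# prepared once so that permutation replicates reduce to three
# matrix-vector products each.
ff2dPrep <- function(px, py) {
  A <- (outer(px, px, ">=")) * 1   # [i, j] = 1 when data j is <= eval i (x)
  B <- (outer(py, py, ">=")) * 1
  list(A = A, B = B, AB = A * B, n = length(px))
}

ff2dFromPrep <- function(prep, sel1) {
  v1 <- as.numeric(sel1); v2 <- 1 - v1
  n1 <- sum(v1); n2 <- prep$n - n1
  ll1 <- prep$AB %*% v1; ll2 <- prep$AB %*% v2
  ax1 <- prep$A %*% v1;  ax2 <- prep$A %*% v2
  by1 <- prep$B %*% v1;  by2 <- prep$B %*% v2
  d <- max(abs(ll1 / n1 - ll2 / n2))
  d <- max(d, max(abs((ax1 - ll1) / n1 - (ax2 - ll2) / n2)))
  d <- max(d, max(abs((by1 - ll1) / n1 - (by2 - ll2) / n2)))
  max(d, max(abs((n1 - ax1 - by1 + ll1) / n1 -
                 (n2 - ax2 - by2 + ll2) / n2)))
}

ff2dStat <- function(x1, y1, x2, y2) {
  prep <- ff2dPrep(c(x1, x2), c(y1, y2))
  ff2dFromPrep(prep, c(rep(TRUE, length(x1)), rep(FALSE, length(x2))))
}

#' Two-sample 2-D KS comparison of spatial maps
#'
#' Converts each map to a weighted point set (bin centers weighted by the
#' normalized activity, uniformly jittered within the bin), draws
#' `n_resample` points per map proportional to weight, computes the
#' Fasano-Franceschini two-sample 2-D KS statistic (maximal quadrant CDF
#' difference over all data points) and a permutation p-value from
#' relabelings of the pooled draws. Deterministic per seed.
#'
#' @param mapA,mapB [SpatialMap-class] objects on the same grid.
#' @param n_resample points drawn per map.
#' @param seed integer seed.
#' @param n_perm permutation count for the p-value.
#' @return list with `D` and `p`.
#' @export
ks2dCompare <- function(mapA, mapB, n_resample = 500, seed = 1L,
                        n_perm = 199) {
  if (!all(dim(mapA@normalized) == dim(mapB@normalized)))
    stop("maps must share the same grid", call. = FALSE)
  # each map's resample depends only on (map, seed): the same map under the
  # same seed yields identical points, so a map versus itself gives D = 0
  a <- withSeed(seed, mapPoints(mapA, n_resample))
  b <- withSeed(seed, mapPoints(mapB, n_resample))
  px <- c(a$x, b$x); py <- c(a$y, b$y)
  n1 <- length(a$x); n <- length(px)
  prep <- ff2dPrep(px, py)
  D <- ff2dFromPrep(prep, seq_len(n) <= n1)
  exceed <- 0
  withSeed(splitSeed(seed, 2), {
    for (k in seq_len(n_perm)) {
      sel <- seq_len(n) %in% sample.int(n, n1)
      if (ff2dFromPrep(prep, sel) >= D) exceed <- exceed + 1
    }
  })
  list(D = D, p = (1 + exceed) / (1 + n_perm))
}

# Weighted resampling of a map into a point set.
mapPoints <- function(map, n) {
  z <- map@normalized
  w <- ifelse(is.na(z) | z < 0, 0, z)
  if (sum(w) <= 0)
    stop("map has zero total activity; cannot resample", call. = FALSE)
  idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
  rc <- arrayInd(idx, dim(w))
  bp <- map@bin_px
  list(x = (rc[, 2] - 1) * bp + runif(n, 0, bp),
       y = (rc[, 1] - 1) * bp + runif(n, 0, bp))
}

#' Pairwise 2-D KS tests between several maps
#'
#' Tests all unordered pairs with [ks2dCompare()] and adjusts the p-values
#' across pairs with Benjamini-Hochberg.
#'
#' @param maps list of [SpatialMap-class] objects (>= 2).
#' @param n_resample,seed,n_perm passed to [ks2dCompare()].
#' @param fdr_q BH level for the verdicts.
#' @return data.frame with one row per pair: `i`, `j`, `D`, `p`,
#'   `p_adj`, `significant`.
#' @export
pairwiseMapTests <- function(maps, n_resample = 500, seed = 1L,
                             n_perm = 199, fdr_q = 0.05) {
  m <- length(maps)
  if (m < 2) stop("need at least 2 maps", call. = FALSE)
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ks <- ks2dCompare(maps[[i]], maps[[j]], n_resample,
                      seed = splitSeed(seed, k), n_perm = n_perm)
    data.frame(i = i, j = j, D = ks$D, p = ks$p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj <= fdr_q
  out[order(out$i, out$j), , drop = FALSE]
}
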