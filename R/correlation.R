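# ROI x electrode x band Pearson correlations between dF/F and LFP band
# power, with a circular-shift permutation null, per-pair empirical
# p-values, Benjamini-Hochberg significant fractions per band, and a KS
# comparison of original versus shuffled correlation distributions.

# Standardize matrix rows to mean 0, sd 1; rows with zero variance -> NA.
standardizeRows <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  s <- sqrt(rowSums(ctr^2) / (ncol(m) - 1))
  out <- ctr / s
  out[s == 0, ] <- NA_real_
  out
}

#' Zero-lag Pearson correlation of every ROI with every band-power trace
#'
#' Correlates each dF/F trace with each electrode's power trace in each
#' band over the valid (non-edge) frames. Constant traces give `NA`
#' entries (undefined correlation), never zero.
#'
#' @param traces a [TraceSet].
#' @param bp a [BandPowerSet] on the identical frame axis.
#' @return ROI x electrode x band array of Pearson coefficients.
#' @export
pearsonMatrix <- function(traces, bp) {
  checkFrameAxes(traces, bp)
  keep <- validFrames(bp)
  if (sum(keep) < 3)
    stop("fewer than 3 valid frames after edge exclusion", call. = FALSE)
  zx <- standardizeRows(dff(traces)[, keep, drop = FALSE])
  zp <- powerRowsStandardized(bp, keep)
  r <- tcrossprod(zx, zp$z) / (sum(keep) - 1)
  array(r, c(nrow(zx), zp$n_electrodes, zp$n_bands),
        dimnames = list(roiIds(traces), NULL, zp$bands))
}

checkFrameAxes <- function(traces, bp) {
  if (ncol(dff(traces)) != length(frameTimes(bp)) ||
      !isTRUE(all.equal(frameTimes(traces), frameTimes(bp))))
    stop("trace and band-power frame axes differ", call. = FALSE)
  invisible(TRUE)
}

# Stack the per-band electrode x frame matrices into one standardized
# (electrode * band) x frame matrix.
powerRowsStandardized <- function(bp, keep) {
  bands <- bandNames(bp)
  mats <- lapply(bands, function(b) bandPower(bp, b)[, keep, drop = FALSE])
  z <- standardizeRows(do.call(rbind, mats))
  list(z = z, n_electrodes = nrow(mats[[1]]), n_bands = length(bands),
       bands = bands)
}

#' Circular-shift shuffles of a trace
#'
#' Rotates the trace by a random number of frames, uniform on
#' `[ceil(L * min_shift_frac), L - ceil(L * min_shift_frac)]`, preserving
#' its autocorrelation (and exact value multiset) while destroying its
#' alignment with any other trace.
#'
#' @param trace numeric vector, length >= 10.
#' @param n_shuffles number of shuffles.
#' @param min_shift_frac minimum shift as a fraction of the length.
#' @param seed integer seed.
#' @return `n_shuffles` x `length(trace)` matrix of rotated copies.
#' @export
circularShuffle <- function(trace, n_shuffles = 100, min_shift_frac = 0.1,
                            seed = 1L) {
  L <- length(trace)
  if (L < 10) stop("trace must have at least 10 points", call. = FALSE)
  smin <- ceiling(L * min_shift_frac)
  shifts <- withSeed(seed,
    sample(seq.int(smin, L - smin), n_shuffles, replace = TRUE))
  t(vapply(shifts, function(s) trace[((seq_len(L) - 1 - s) %% L) + 1],
           numeric(L)))
}

# Internal: rotate each row of a matrix by its own shift.
rotateRows <- function(m, shifts) {
  L <- ncol(m)
  for (r in seq_len(nrow(m)))
    m[r, ] <- m[r, ((seq_len(L) - 1 - shifts[r]) %% L) + 1]
  m
}

#' Two-sided empirical p-value from permutation null draws
#'
#' `p = (1 + #\{|null| >= |obs|\}) / (1 + n_null)`, never exactly zero.
#'
#' @param rho_obs observed statistic (scalar or array).
#' @param rho_null_draws null draws; for array input, an array with one
#'   extra trailing dimension of draws.
#' @return p-values with the shape of `rho_obs`.
#' @export
empiricalP <- function(rho_obs, rho_null_draws) {
  if (is.null(dim(rho_obs)) && length(rho_obs) == 1) {
    if (!length(rho_null_draws)) stop("need at least one null draw",
                                      call. = FALSE)
    return((1 + sum(abs(rho_null_draws) >= abs(rho_obs))) /
             (1 + length(rho_null_draws)))
  }
  d <- dim(rho_null_draws)
  n_null <- d[length(d)]
  cnt <- rowSums(abs(rho_null_draws) >= as.vector(abs(rho_obs)),
                 dims = length(d) - 1)
  p <- (1 + cnt) / (1 + n_null)
  array(p, dim(rho_obs), dimnames = dimnames(rho_obs))
}

#' KS comparison of original versus shuffled correlation coefficients
#'
#' Two-sample Kolmogorov-Smirnov test between the pooled original
#' coefficients of a band and the pooled coefficients obtained from
#' shuffled traces, asymptotic p-value.
#'
#' @param rho_original numeric vector of original coefficients.
#' @param rho_shuffled numeric vector pooling all shuffles' coefficients.
#' @return list with `ks_stat` and `ks_p`.
#' @export
ksOriginalVsShuffled <- function(rho_original, rho_shuffled) {
  rho_original <- rho_original[is.finite(rho_original)]
  rho_shuffled <- rho_shuffled[is.finite(rho_shuffled)]
  if (!length(rho_original) || !length(rho_shuffled))
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(ks.test(rho_original, rho_shuffled))
  list(ks_stat = unname(kt$statistic), ks_p = kt$p.value)
}

#' Benjamini-Hochberg verdicts and per-band significant fractions
#'
#' Applies the BH step-up at level `fdr_q` across all ROI x electrode
#' pairs within each band (or across all bands jointly with
#' `pool_bands = TRUE`) and reports the fraction of significant pairs per
#' band. `NA` p-values (constant traces) are excluded from both the
#' adjustment and the denominators.
#'
#' @param p_emp ROI x electrode x band array of p-values in (0, 1].
#' @param fdr_q FDR level.
#' @param pool_bands adjust across all bands jointly.
#' @return list with `significant` (logical array) and
#'   `fraction_significant` (named per band).
#' @export
fdrFractions <- function(p_emp, fdr_q = 0.05, pool_bands = FALSE) {
  stopifnot(length(dim(p_emp)) == 3)
  sig <- array(NA, dim(p_emp), dimnames = dimnames(p_emp))
  if (pool_bands) {
    sig[] <- p.adjust(as.vector(p_emp), method = "BH") <= fdr_q
  } else {
    for (b in seq_len(dim(p_emp)[3]))
      sig[, , b] <- p.adjust(as.vector(p_emp[, , b]), method = "BH") <= fdr_q
  }
  frac <- apply(sig, 3, function(m) mean(m, na.rm = TRUE))
  frac[is.nan(frac)] <- 0
  list(significant = sig, fraction_significant = frac)
}

#' Full correlation analysis with circular-shift permutation null
#'
#' The package's headline computation: Pearson coefficients between every
#' dF/F trace and every electrode's band-power trace; a per-pair null built
#' by circularly shifting the dF/F trace `n_shuffles` times (each trace its
#' own random shift per shuffle); two-sided empirical p-values; BH verdicts
#' per band; and per-band KS comparison of original versus shuffled
#' coefficient distributions. The "shuffled dataset" fractions treat
#' shuffle 1 of each trace as the observation and the remaining shuffles as
#' its null.
#'
#' @inheritParams pearsonMatrix
#' @param n_shuffles circular shifts per trace.
#' @param min_shift_frac minimum shift fraction.
#' @param fdr_q BH level.
#' @param pool_bands BH across bands jointly instead of within band.
#' @param seed integer seed for the shifts.
#' @return a [CorrelationResult].
#' @examples
#' cfg <- sessionConfig(n_rois = 5, n_electrodes = 4, duration_s = 30,
#'                      ephys_rate_hz = 250, seed = 2)
#' s <- generateSession(cfg)
#' bp <- bandPowerTraces(s$ephys, frameTimes(s$traces))
#' res <- correlationAnalysis(s$traces, bp, n_shuffles = 20, seed = 3)
#' significantFraction(res)
#' @export
correlationAnalysis <- function(traces, bp, n_shuffles = 100,
                                min_shift_frac = 0.1, fdr_q = 0.05,
                                pool_bands = FALSE, seed = 1L) {
  checkFrameAxes(traces, bp)
  keep <- validFrames(bp)
  L <- sum(keep)
  if (L < 10) stop("fewer than 10 valid frames", call. = FALSE)
  zx <- standardizeRows(dff(traces)[, keep, drop = FALSE])
  zp <- powerRowsStandardized(bp, keep)
  n_roi <- nrow(zx); n_el <- zp$n_electrodes; n_band <- zp$n_bands
  dn <- list(roiIds(traces), NULL, zp$bands)

  rho_obs <- array(tcrossprod(zx, zp$z) / (L - 1), c(n_roi, n_el, n_band),
                   dimnames = dn)

  smin <- ceiling(L * min_shift_frac)
  zx0 <- zx
  zx0[is.na(zx0)] <- 0   # constant traces: rho forced finite, masked later
  rho_null <- array(NA_real_, c(n_roi, n_el, n_band, n_shuffles))
  withSeed(seed, {
    for (s in seq_len(n_shuffles)) {
      shifts <- sample(seq.int(smin, L - smin), n_roi, replace = TRUE)
      rs <- tcrossprod(rotateRows(zx0, shifts), zp$z) / (L - 1)
      rho_null[, , , s] <- rs
    }
  })
  const_roi <- is.na(zx[, 1])
  rho_null[const_roi, , , ] <- NA_real_

  p_emp <- empiricalP(rho_obs, rho_null)
  fdr <- fdrFractions(p_emp, fdr_q, pool_bands)

  # shuffled dataset: shuffle 1 is the observation, the rest its null
  p_shuf <- empiricalP(
    array(rho_null[, , , 1], c(n_roi, n_el, n_band), dimnames = dn),
    rho_null[, , , -1, drop = FALSE])
  fdr_shuf <- fdrFractions(p_shuf, fdr_q, pool_bands)

  ks_stat <- ks_p <- setNames(numeric(n_band), zp$bands)
  for (b in seq_len(n_band)) {
    kt <- ksOriginalVsShuffled(as.vector(rho_obs[, , b]),
                               as.vector(rho_null[, , b, ]))
    ks_stat[b] <- kt$ks_stat; ks_p[b] <- kt$ks_p
  }

  methods::new("CorrelationResult", rho = rho_obs, p_emp = p_emp,
               rho_shuffled = rho_null, significant = fdr$significant,
               fraction_significant = fdr$fraction_significant,
               fraction_significant_shuffled = fdr_shuf$fraction_significant,
               ks_stat = ks_stat, ks_p = ks_p,
               n_shuffles = as.integer(n_shuffles),
               min_shift_frac = min_shift_frac, fdr_q = fdr_q,
               n_excluded = as.integer(sum(const_roi) * n_el * n_band))
}

#' Top ROIs by mean correlation with a band
#'
#' Ranks ROIs by their mean Pearson coefficient across all electrodes for
#' one band, descending; ties broken by ROI order.
#'
#' @param result a [CorrelationResult].
#' @param band band name.
#' @param k number of ROIs to return; `k = 0` gives an empty table.
#' @return data.frame with `roi_id`, `mean_rho`, best first.
#' @export
topCorrelatedRois <- function(result, band, k = 4) {
  r <- rho(result)
  if (!band %in% dimnames(r)[[3]])
    stop(sprintf("unknown band '%s'", band), call. = FALSE)
  m <- rowMeans(r[, , band, drop = FALSE][, , 1, drop = FALSE], na.rm = TRUE)
  if (k > length(m)) {
    warning(sprintf("k = %d exceeds %d ROIs; truncating", k, length(m)),
            call. = FALSE)
    k <- length(m)
  }
  ord <- order(-m, seq_along(m))
  out <- data.frame(roi_id = dimnames(r)[[1]][ord], mean_rho = m[ord],
                    row.names = NULL)
  out[seq_len(k), , drop = FALSE]
}
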