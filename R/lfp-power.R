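# LFP conditioning, Morlet wavelet spectrograms, and band-power traces
# aligned to imaging frames.

#' Canonical frequency band definitions
#'
#' Theta 6-14 Hz, beta 15-30 Hz, low gamma 35-55 Hz, high gamma 65-95 Hz.
#'
#' @return data.frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
canonicalBands <- function() {
  data.frame(name = c("theta", "beta", "lgamma", "hgamma"),
             lo_hz = c(6, 15, 35, 65),
             hi_hz = c(14, 30, 55, 95))
}

#' Extract the low-frequency LFP from raw voltage
#'
#' Zero-phase band-pass (4th-order Butterworth, applied forward-backward)
#' of every electrode, keeping the 1-100 Hz local-field-potential band by
#' default. Output length equals input length.
#'
#' @param rec an [EphysRecording], or a numeric matrix (electrode x sample).
#' @param lo_hz,hi_hz passband edges; `hi_hz` must stay below Nyquist.
#' @param rate_hz sampling rate, required when `rec` is a bare matrix.
#' @return matrix of filtered voltage, same shape as the input.
#' @export
extractLFP <- function(rec, lo_hz = 1, hi_hz = 100, rate_hz = NULL) {
  if (methods::is(rec, "EphysRecording")) {
    v <- voltageUV(rec)
    rate_hz <- samplingRate(rec)
  } else {
    v <- as.matrix(rec)
    if (is.null(rate_hz)) stop("rate_hz is required for matrix input",
                               call. = FALSE)
  }
  nyq <- rate_hz / 2
  if (hi_hz >= nyq)
    stop(sprintf("hi_hz (%g) must be below Nyquist (%g)", hi_hz, nyq),
         call. = FALSE)
  bf <- signal::butter(4, c(lo_hz, hi_hz) / nyq, type = "pass")
  t(apply(v, 1, function(x) signal::filtfilt(bf, x)))
}

#' Morlet wavelet power spectrogram of one channel
#'
#' Squared magnitude of an analytic Morlet continuous wavelet transform
#' (default 6-cycle atom) evaluated at each requested frequency; the time
#' axis is the sample times of the input.
#'
#' @param x numeric vector, one LFP channel.
#' @param rate_hz sampling rate.
#' @param freqs_hz analysis frequencies, inside (0, Nyquist); default a
#'   1-Hz grid over 1-100 Hz (clipped below Nyquist).
#' @param omega0 wavelet cycles parameter.
#' @return time x frequency power matrix with `freqs_hz` as an attribute.
#' @export
waveletSpectrogram <- function(x, rate_hz, freqs_hz = NULL, omega0 = 6) {
  if (is.null(freqs_hz)) freqs_hz <- seq(1, min(100, rate_hz / 2 - 1))
  if (!length(freqs_hz)) stop("freqs_hz must be non-empty", call. = FALSE)
  if (any(freqs_hz <= 0 | freqs_hz >= rate_hz / 2))
    stop("freqs_hz must lie inside (0, Nyquist)", call. = FALSE)
  p <- cpp_cwt_power(as.numeric(x), rate_hz, as.numeric(freqs_hz), omega0)
  attr(p, "freqs_hz") <- freqs_hz
  attr(p, "times_s") <- (seq_len(nrow(p)) - 1) / rate_hz
  p
}

#' Mean wavelet spectrogram over all electrodes
#'
#' Arithmetic mean of the per-electrode Morlet power spectrograms, the
#' standard session-overview display for multi-electrode recordings.
#'
#' @inheritParams waveletSpectrogram
#' @param rec an [EphysRecording] or electrode x sample matrix.
#' @param rate_hz required for matrix input.
#' @return time x frequency mean power matrix.
#' @export
meanSpectrogram <- function(rec, freqs_hz = NULL, omega0 = 6,
                            rate_hz = NULL) {
  if (methods::is(rec, "EphysRecording")) {
    v <- voltageUV(rec)
    rate_hz <- samplingRate(rec)
  } else v <- as.matrix(rec)
  stopifnot(nrow(v) >= 1)
  acc <- NULL
  for (e in seq_len(nrow(v))) {
    p <- waveletSpectrogram(v[e, ], rate_hz, freqs_hz, omega0)
    acc <- if (is.null(acc)) p else acc + p
  }
  acc / nrow(v)
}

#' Per-electrode band-power traces on the imaging frame axis
#'
#' For each electrode and band: Morlet wavelet power is computed on a 1-Hz
#' frequency grid, averaged over the in-band frequencies, then averaged
#' within each inter-frame interval to give one value per imaging frame
#' (interval means, not instantaneous samples, to avoid aliasing fast power
#' fluctuations). Frames whose interval lies within `edge_s` of either end
#' of the recording are flagged invalid (wavelet cone of influence) and are
#' excluded from correlation analysis downstream.
#'
#' @param rec an [EphysRecording] (raw voltage is band-passed to 1-100 Hz
#'   first) or an electrode x sample matrix of already-conditioned LFP.
#' @param frame_times_s imaging frame timestamps (ephys clock); all frames
#'   must fall inside the recording span.
#' @param band_defs band definition table, by default [canonicalBands()].
#' @param rate_hz sampling rate, for matrix input.
#' @param omega0 wavelet cycles parameter.
#' @param edge_s edge exclusion in seconds.
#' @param prefilter band-pass the raw voltage before the transform.
#' @return a [BandPowerSet].
#' @export
bandPowerTraces <- function(rec, frame_times_s, band_defs = canonicalBands(),
                            rate_hz = NULL, omega0 = 6, edge_s = 1,
                            prefilter = TRUE) {
  tet <- NULL
  if (methods::is(rec, "EphysRecording")) {
    rate_hz <- samplingRate(rec)
    tet <- tetrodeOf(rec)
    v <- if (prefilter) extractLFP(rec) else voltageUV(rec)
  } else {
    v <- as.matrix(rec)
    if (is.null(rate_hz)) stop("rate_hz is required for matrix input",
                               call. = FALSE)
  }
  ns <- ncol(v)
  span <- c(0, (ns - 1) / rate_hz)
  outside <- frame_times_s < span[1] | frame_times_s > span[2]
  if (any(outside))
    stop(sprintf("frame times outside recording span: %s",
                 paste(utils::head(which(outside), 5), collapse = ", ")),
         call. = FALSE)

  freqs <- seq(1, min(100, floor(rate_hz / 2 - 1)))
  band_of <- rep(-1L, length(freqs))
  for (b in seq_len(nrow(band_defs)))
    band_of[freqs >= band_defs$lo_hz[b] & freqs <= band_defs$hi_hz[b]] <-
      b - 1L

  nf <- length(frame_times_s)
  # sample -> frame interval: frame i covers [t_i, t_{i+1}), last frame one
  # median inter-frame interval long
  dt_f <- if (nf > 1) median(diff(frame_times_s)) else 1 / rate_hz
  edges <- c(frame_times_s, frame_times_s[nf] + dt_f)
  st <- (seq_len(ns) - 1) / rate_hz
  frame_of <- findInterval(st, edges, rightmost.closed = FALSE) - 1L
  frame_of[frame_of < 0 | frame_of >= nf] <- -1L

  p <- cpp_band_power(t(v), rate_hz, as.numeric(freqs), band_of,
                      nrow(band_defs), frame_of, nf, omega0)
  dimnames(p) <- list(NULL, band_defs$name, NULL)
  valid <- frame_times_s >= span[1] + edge_s &
    (frame_times_s + dt_f) <= span[2] - edge_s
  BandPowerSet(p, frame_times_s, band_defs, tetrode_of = tet, valid = valid)
}
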