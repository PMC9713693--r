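#' TraceSet: per-ROI dF/F traces on the imaging clock
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one `"dff"` assay (ROI x frame), frame timestamps in `colData$frame_time_s`
#' (seconds, strictly increasing) and optional ROI centroids in `rowData`
#' (`centroid_x_px`, `centroid_y_px`).
#'
#' @param dff numeric ROI x frame matrix of fractional fluorescence change.
#' @param frame_times_s strictly increasing frame timestamps in seconds.
#' @param roi_ids character ROI identifiers; defaults to `roi_000`, ...
#' @param centroids optional ROI x 2 matrix of pixel centroids.
#' @param x a `TraceSet`.
#'
#' @return `TraceSet()` returns a validated `TraceSet`. `dff()` the assay
#'   matrix, `frameTimes()` the timestamp vector, `roiIds()` the ROI names,
#'   `roiCentroids()` the centroid matrix or `NULL`.
#'
#' @examples
#' ts <- TraceSet(matrix(rnorm(40), 4), frame_times_s = (0:9) / 15)
#' dim(dff(ts))
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

#' @rdname TraceSet-class
#' @export
TraceSet <- function(dff, frame_times_s, roi_ids = NULL, centroids = NULL) {
  dff <- as.matrix(dff)
  if (is.null(roi_ids))
    roi_ids <- sprintf("roi_%03d", seq_len(nrow(dff)) - 1L)
  rd <- S4Vectors::DataFrame(roi_id = roi_ids)
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    rd$centroid_x_px <- centroids[, 1]
    rd$centroid_y_px <- centroids[, 2]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dff = dff),
    rowData = rd,
    colData = S4Vectors::DataFrame(frame_time_s = as.numeric(frame_times_s)))
  rownames(se) <- roi_ids
  methods::new("TraceSet", se)
}

setValidity("TraceSet", function(object) {
  msg <- character(0)
  if (!"dff" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dff' is required")
  ft <- object$frame_time_s
  if (is.null(ft)) msg <- c(msg, "colData$frame_time_s is required")
  else if (any(diff(ft) <= 0))
    msg <- c(msg, "frame_time_s must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname TraceSet-class
#' @export
setMethod("dff", "TraceSet", function(x)
  SummarizedExperiment::assay(x, "dff"))

#' @rdname TraceSet-class
#' @export
setMethod("frameTimes", "TraceSet", function(x) x$frame_time_s)

#' @rdname TraceSet-class
#' @export
setMethod("roiIds", "TraceSet", function(x)
  SummarizedExperiment::rowData(x)$roi_id)

#' @rdname TraceSet-class
#' @export
setMethod("roiCentroids", "TraceSet", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"centroid_x_px" %in% colnames(rd)) return(NULL)
  cbind(x = rd$centroid_x_px, y = rd$centroid_y_px)
})

#' BandPowerSet: per-electrode LFP band power on the imaging frame axis
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one assay per
#' frequency band (each electrode x frame), `colData$frame_time_s` matching
#' the companion [TraceSet], `colData$valid` marking frames outside the
#' wavelet cone of influence, and the band definitions in
#' `metadata(x)$band_defs`.
#'
#' @param power electrode x band x frame array of mean wavelet power.
#' @param frame_times_s frame timestamps, identical to the imaging axis.
#' @param band_defs data.frame with columns `name`, `lo_hz`, `hi_hz`.
#' @param tetrode_of integer tetrode index per electrode.
#' @param valid logical per frame; `FALSE` frames are excluded from
#'   correlation analysis (edge effects).
#' @param x a `BandPowerSet`.
#' @param band band name (character) or index.
#'
#' @return `BandPowerSet()` a validated object; `bandPower()` the
#'   electrode x frame matrix for one band; `bandNames()` the band names;
#'   `validFrames()` the logical frame mask.
#' @export
setClass("BandPowerSet", contains = "SummarizedExperiment")

#' @rdname BandPowerSet-class
#' @export
BandPowerSet <- function(power, frame_times_s, band_defs, tetrode_of = NULL,
                         valid = NULL) {
  stopifnot(length(dim(power)) == 3, dim(power)[2] == nrow(band_defs))
  if (is.null(valid)) valid <- rep(TRUE, dim(power)[3])
  assays <- lapply(seq_len(nrow(band_defs)), function(b)
    matrix(power[, b, ], dim(power)[1], dim(power)[3]))
  names(assays) <- band_defs$name
  rd <- S4Vectors::DataFrame(
    electrode = seq_len(dim(power)[1]),
    tetrode = if (is.null(tetrode_of)) NA_integer_ else tetrode_of)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd,
    colData = S4Vectors::DataFrame(frame_time_s = as.numeric(frame_times_s),
                                   valid = valid))
  S4Vectors::metadata(se)$band_defs <- band_defs
  methods::new("BandPowerSet", se)
}

setValidity("BandPowerSet", function(object) {
  msg <- character(0)
  bd <- S4Vectors::metadata(object)$band_defs
  if (is.null(bd)) msg <- c(msg, "metadata band_defs is required")
  for (nm in SummarizedExperiment::assayNames(object)) {
    a <- SummarizedExperiment::assay(object, nm)
    if (any(a[is.finite(a)] < 0))
      msg <- c(msg, sprintf("negative power in band '%s'", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname BandPowerSet-class
#' @export
setMethod("bandNames", "BandPowerSet", function(x)
  SummarizedExperiment::assayNames(x))

#' @rdname BandPowerSet-class
#' @export
setMethod("bandPower", "BandPowerSet", function(x, band)
  SummarizedExperiment::assay(x, band))

#' @rdname BandPowerSet-class
#' @export
setMethod("frameTimes", "BandPowerSet", function(x) x$frame_time_s)

#' @rdname BandPowerSet-class
#' @export
setMethod("validFrames", "BandPowerSet", function(x) x$valid)

#' EphysRecording: multi-electrode voltage with tetrode grouping
#'
#' Raw extracellular voltage (microvolts) for all electrodes at the ephys
#' sampling rate, with the tetrode each electrode belongs to and an
#' optional frame-trigger channel carrying one pulse per imaging frame.
#'
#' @slot voltage_uV electrode x sample numeric matrix, microvolts.
#' @slot rate_hz sampling rate in samples per second.
#' @slot tetrode_of integer tetrode index per electrode.
#' @slot trigger numeric trigger channel (length = samples) or length 0.
#' @slot uv_per_count quantization step used when exporting to int16.
#'
#' @param voltage_uV,rate_hz,tetrode_of,trigger,uv_per_count see slots.
#' @param x an `EphysRecording`.
#' @export
setClass("EphysRecording",
  representation(voltage_uV = "matrix", rate_hz = "numeric",
                 tetrode_of = "integer", trigger = "numeric",
                 uv_per_count = "numeric"))

#' @rdname EphysRecording-class
#' @export
EphysRecording <- function(voltage_uV, rate_hz, tetrode_of = NULL,
                           trigger = numeric(0), uv_per_count = 0.195) {
  voltage_uV <- as.matrix(voltage_uV)
  ne <- nrow(voltage_uV)
  if (is.null(tetrode_of)) tetrode_of <- ((seq_len(ne) - 1L) %/% 4L) + 1L
  methods::new("EphysRecording", voltage_uV = voltage_uV,
               rate_hz = as.numeric(rate_hz),
               tetrode_of = as.integer(tetrode_of),
               trigger = as.numeric(trigger),
               uv_per_count = uv_per_count)
}

setValidity("EphysRecording", function(object) {
  msg <- character(0)
  if (object@rate_hz <= 0) msg <- c(msg, "rate_hz must be > 0")
  ne <- nrow(object@voltage_uV)
  if (length(object@tetrode_of) != ne)
    msg <- c(msg, "tetrode_of must have one entry per electrode")
  if (ne == 16 && length(unique(object@tetrode_of)) != 4)
    msg <- c(msg, "16 electrodes must be grouped into exactly 4 tetrodes")
  if (ne == 16 && !all(table(object@tetrode_of) == 4))
    msg <- c(msg, "16 electrodes must form 4 tetrodes of 4")
  if (length(object@trigger) &&
      length(object@trigger) != ncol(object@voltage_uV))
    msg <- c(msg, "trigger length must equal the number of samples")
  if (length(msg)) msg else TRUE
})

#' @rdname EphysRecording-class
#' @export
setMethod("voltageUV", "EphysRecording", function(x) x@voltage_uV)

#' @rdname EphysRecording-class
#' @export
setMethod("samplingRate", "EphysRecording", function(x) x@rate_hz)

#' @rdname EphysRecording-class
#' @export
setMethod("tetrodeOf", "EphysRecording", function(x) x@tetrode_of)

#' @rdname EphysRecording-class
#' @export
setMethod("triggerChannel", "EphysRecording", function(x)
  if (length(x@trigger)) x@trigger else NULL)

setMethod("show", "EphysRecording", function(object) {
  cat(sprintf("EphysRecording: %d electrodes (%d tetrodes), %d samples @ %g Hz (%.1f s)%s\n",
              nrow(object@voltage_uV), length(unique(object@tetrode_of)),
              ncol(object@voltage_uV), object@rate_hz,
              ncol(object@voltage_uV) / object@rate_hz,
              if (length(object@trigger)) ", with frame trigger" else ""))
})

#' SpikeTrainSet: sorted single-unit spike times
#'
#' @slot spikes data.frame with columns `unit_id`, `tetrode`, `time_s`;
#'   times strictly increasing within each unit.
#'
#' @param spikes data.frame as above.
#' @param x a `SpikeTrainSet`.
#' @param unit unit identifier.
#' @export
setClass("SpikeTrainSet", representation(spikes = "data.frame"))

#' @rdname SpikeTrainSet-class
#' @export
SpikeTrainSet <- function(spikes) {
  spikes <- as.data.frame(spikes)
  stopifnot(all(c("unit_id", "time_s") %in% names(spikes)))
  if (!"tetrode" %in% names(spikes)) spikes$tetrode <- NA_integer_
  spikes <- spikes[order(spikes$unit_id, spikes$time_s), , drop = FALSE]
  rownames(spikes) <- NULL
  methods::new("SpikeTrainSet", spikes = spikes)
}

setValidity("SpikeTrainSet", function(object) {
  sp <- object@spikes
  bad <- vapply(split(sp$time_s, sp$unit_id),
                function(t) any(diff(t) <= 0), logical(1))
  if (any(bad))
    return(sprintf("spike times not strictly increasing for unit(s): %s",
                   paste(names(bad)[bad], collapse = ", ")))
  TRUE
})

#' @rdname SpikeTrainSet-class
#' @export
setMethod("unitIds", "SpikeTrainSet", function(x) unique(x@spikes$unit_id))

#' @rdname SpikeTrainSet-class
#' @export
setMethod("spikeTimes", "SpikeTrainSet", function(x, unit)
  x@spikes$time_s[x@spikes$unit_id == unit])

setMethod("show", "SpikeTrainSet", function(object) {
  cat(sprintf("SpikeTrainSet: %d units, %d spikes\n",
              length(unique(object@spikes$unit_id)), nrow(object@spikes)))
})

#' BehaviorTrack: head position at video rate with imaging-clock sync
#'
#' Positions are in video pixels (origin top-left, x right, y down). The
#' affine map to the imaging clock is
#' `t_imaging = sync_factor * t_video + sync_offset_s`.
#'
#' @slot times_s video-clock timestamps, strictly increasing.
#' @slot xy_px n x 2 matrix of positions in pixels.
#' @slot rate_hz nominal video frame rate.
#' @slot sync_offset_s offset of the affine video-to-imaging map.
#' @slot sync_factor rate-correction factor of the map.
#'
#' @param times_s,xy_px,rate_hz,sync_offset_s,sync_factor see slots.
#' @param x a `BehaviorTrack`.
#' @param clock `"video"` or `"imaging"`.
#' @export
setClass("BehaviorTrack",
  representation(times_s = "numeric", xy_px = "matrix", rate_hz = "numeric",
                 sync_offset_s = "numeric", sync_factor = "numeric"))

#' @rdname BehaviorTrack-class
#' @export
BehaviorTrack <- function(times_s, xy_px, rate_hz = 30,
                          sync_offset_s = 0, sync_factor = 1) {
  methods::new("BehaviorTrack", times_s = as.numeric(times_s),
               xy_px = as.matrix(xy_px), rate_hz = as.numeric(rate_hz),
               sync_offset_s = as.numeric(sync_offset_s),
               sync_factor = as.numeric(sync_factor))
}

setValidity("BehaviorTrack", function(object) {
  msg <- character(0)
  if (any(diff(object@times_s) <= 0))
    msg <- c(msg, "track times must be strictly increasing")
  if (nrow(object@xy_px) != length(object@times_s))
    msg <- c(msg, "xy_px must have one row per timestamp")
  if (ncol(object@xy_px) != 2) msg <- c(msg, "xy_px must have 2 columns")
  if (length(msg)) msg else TRUE
})

#' @rdname BehaviorTrack-class
#' @export
setMethod("trackXY", "BehaviorTrack", function(x) x@xy_px)

#' @rdname BehaviorTrack-class
#' @export
setMethod("trackTimes", "BehaviorTrack", function(x, clock = c("video", "imaging")) {
  clock <- match.arg(clock)
  if (clock == "video") x@times_s
  else x@sync_factor * x@times_s + x@sync_offset_s
})

setMethod("show", "BehaviorTrack", function(object) {
  cat(sprintf("BehaviorTrack: %d points @ %g fps, %.1f s; sync offset %+.3f s, factor %.4f\n",
              length(object@times_s), object@rate_hz,
              diff(range(object@times_s)), object@sync_offset_s,
              object@sync_factor))
})

#' CorrelationResult: ROI x electrode x band correlation analysis
#'
#' Holds the zero-lag Pearson coefficients between dF/F traces and LFP
#' band-power traces, the circular-shift permutation null, two-sided
#' empirical p-values, Benjamini-Hochberg verdicts per band, and the
#' Kolmogorov-Smirnov comparison of the original versus shuffled
#' correlation distributions.
#'
#' @slot rho ROI x electrode x band array of Pearson coefficients.
#' @slot p_emp matching array of two-sided empirical p-values.
#' @slot rho_shuffled ROI x electrode x band x shuffle null draws.
#' @slot significant logical array from BH at `fdr_q` within band.
#' @slot fraction_significant named per-band fraction of significant pairs.
#' @slot fraction_significant_shuffled same, for the shuffled dataset
#'   (shuffle 1 treated as the observation, the rest as its null).
#' @slot ks_stat,ks_p per-band two-sample KS statistic and p-value of
#'   original versus pooled shuffled coefficients.
#' @slot n_shuffles,min_shift_frac,fdr_q analysis parameters.
#' @slot n_excluded number of constant (undefined-correlation) pairs.
#'
#' @param x a `CorrelationResult`.
#' @param shuffled return the shuffled-dataset fractions instead.
#' @export
setClass("CorrelationResult",
  representation(rho = "array", p_emp = "array", rho_shuffled = "array",
                 significant = "array", fraction_significant = "numeric",
                 fraction_significant_shuffled = "numeric",
                 ks_stat = "numeric", ks_p = "numeric",
                 n_shuffles = "integer", min_shift_frac = "numeric",
                 fdr_q = "numeric", n_excluded = "integer"))

setValidity("CorrelationResult", function(object) {
  msg <- character(0)
  r <- object@rho
  if (any(abs(r[is.finite(r)]) > 1 + 1e-12)) msg <- c(msg, "|rho| must be <= 1")
  p <- object@p_emp
  if (any(p[is.finite(p)] <= 0 | p[is.finite(p)] > 1))
    msg <- c(msg, "p_emp must lie in (0, 1]")
  fs <- object@fraction_significant
  if (any(fs < 0 | fs > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname CorrelationResult-class
#' @export
setMethod("rho", "CorrelationResult", function(x) x@rho)

#' @rdname CorrelationResult-class
#' @export
setMethod("empiricalPValues", "CorrelationResult", function(x) x@p_emp)

#' @rdname CorrelationResult-class
#' @export
setMethod("significantFraction", "CorrelationResult",
  function(x, shuffled = FALSE)
    if (shuffled) x@fraction_significant_shuffled else x@fraction_significant)

setMethod("show", "CorrelationResult", function(object) {
  d <- dim(object@rho)
  cat(sprintf("CorrelationResult: %d ROIs x %d electrodes x %d bands (%d shuffles)\n",
              d[1], d[2], d[3], object@n_shuffles))
  cat("  significant fraction (BH q=", object@fdr_q, "):\n", sep = "")
  print(round(object@fraction_significant, 3))
})

#' SpatialMap: occupancy-normalized spatial activity map
#'
#' Binned arena activity normalized by time spent per bin and Gaussian
#' smoothed. Unvisited bins are `NA`, never zero-filled; smoothing
#' renormalizes the kernel over the visited support.
#'
#' @slot occupancy_s seconds spent per bin (y-bin x x-bin matrix).
#' @slot activity summed dF/F per bin.
#' @slot normalized smoothed activity / occupancy; `NA` where unvisited.
#' @slot visited logical matrix of visited bins.
#' @slot bin_px bin side in pixels.
#' @slot sigma_px Gaussian smoothing sigma in pixels.
#' @slot arena_px arena width, height in pixels.
#' @slot roi_id source ROI identifier.
#' @export
setClass("SpatialMap",
  representation(occupancy_s = "matrix", activity = "matrix",
                 normalized = "matrix", visited = "matrix",
                 bin_px = "numeric", sigma_px = "numeric",
                 arena_px = "numeric", roi_id = "character"))

setValidity("SpatialMap", function(object) {
  msg <- character(0)
  if (any(object@occupancy_s < 0)) msg <- c(msg, "occupancy must be >= 0")
  nz <- object@normalized[object@visited]
  if (any(!is.finite(nz))) msg <- c(msg, "normalized map must be finite on visited bins")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpatialMap", function(object) {
  cat(sprintf("SpatialMap [%s]: %d x %d bins of %g px, sigma %g px, %.1f%% visited\n",
              object@roi_id, nrow(object@normalized), ncol(object@normalized),
              object@bin_px, object@sigma_px, 100 * mean(object@visited)))
})

#' OpticsReport: optical characterization summary
#'
#' @slot magnification measured magnification M.
#' @slot fov_um field of view in micrometers.
#' @slot lateral_fwhm_um magnification-corrected (1/M) lateral FWHM.
#' @slot axial_fwhm_um magnification-corrected (1/M^2) axial FWHM.
#' @slot n_beads_used number of beads averaged per FWHM estimate.
#' @slot bead_fits per-bead fit table.
#' @export
setClass("OpticsReport",
  representation(magnification = "numeric", fov_um = "numeric",
                 lateral_fwhm_um = "numeric", axial_fwhm_um = "numeric",
                 n_beads_used = "integer", bead_fits = "data.frame"))

setMethod("show", "OpticsReport", function(object) {
  cat(sprintf(paste0("OpticsReport: M = %.3f, FOV = %g um, ",
                     "lateral FWHM = %.3f um, axial FWHM = %.2f um (%d beads)\n"),
              object@magnification, object@fov_um, object@lateral_fwhm_um,
              object@axial_fwhm_um, object@n_beads_used))
})

#' PseudoTrace: spike train rendered as a calcium-like trace
#'
#' @slot values per-frame amplitude (arbitrary units), non-negative.
#' @slot frame_times_s imaging frame timestamps.
#' @slot decay_tau_s exponential kernel time constant.
#' @slot unit_id source unit.
#' @export
setClass("PseudoTrace",
  representation(values = "numeric", frame_times_s = "numeric",
                 decay_tau_s = "numeric", unit_id = "character"))

setValidity("PseudoTrace", function(object) {
  if (any(object@values < -1e-12)) return("pseudo trace must be non-negative")
  TRUE
})

setMethod("show", "PseudoTrace", function(object) {
  cat(sprintf("PseudoTrace [%s]: %d frames, tau = %g s, %d active frames\n",
              object@unit_id, length(object@values), object@decay_tau_s,
              sum(object@values > 0)))
})
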