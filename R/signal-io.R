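# Session directory layout:
#   traces.csv  frame_time_s, roi_000, roi_001, ...
#   ephys.bin   little-endian int16, channel-interleaved (all channels of
#               sample 1, then sample 2, ...); trigger stored as an extra
#               channel when present
#   meta.json   ephys rate, channel map, uV-per-count, trigger channel,
#               video rate
#   spikes.csv  unit_id, tetrode, time_s           (optional)
#   track.csv   frame, x_px, y_px                  (optional)
#   truth.json  generator config / ground truth    (optional)

#' Write a session directory
#'
#' Exports a (typically synthetic) session in the package's plain-file
#' layout. The voltage matrix is written as little-endian 16-bit integers
#' using the recording's microvolt-per-count quantization, so a write/read
#' round trip reproduces the voltage exactly.
#'
#' @param session list with elements `traces`, `ephys` and optionally
#'   `spikes`, `track`, `truth` (as returned by [generateSession()]).
#' @param path output directory, created if needed.
#' @return `path`, invisibly.
#' @seealso [loadSession()]
#' @export
writeSession <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tr <- session$traces
  df <- data.frame(frame_time_s = frameTimes(tr),
                   t(dff(tr)), check.names = FALSE)
  colnames(df) <- c("frame_time_s", roiIds(tr))
  write.csv(df, file.path(path, "traces.csv"), row.names = FALSE)

  rec <- session$ephys
  v <- voltageUV(rec)
  q <- rec@uv_per_count
  counts <- round(v / q)
  trig <- triggerChannel(rec)
  trigger_channel <- NA_integer_
  if (!is.null(trig)) {
    counts <- rbind(counts, round(trig / q))
    trigger_channel <- nrow(counts)
  }
  con <- file(file.path(path, "ephys.bin"), "wb")
  writeBin(as.integer(counts), con, size = 2, endian = "little")
  close(con)
  meta <- list(rate_hz = samplingRate(rec),
               n_channels = nrow(counts),
               uv_per_count = q,
               tetrode_of = tetrodeOf(rec),
               trigger_channel = trigger_channel,
               video_rate_hz = if (!is.null(session$track))
                 session$track@rate_hz else NA)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  if (!is.null(session$spikes))
    write.csv(session$spikes@spikes, file.path(path, "spikes.csv"),
              row.names = FALSE)
  if (!is.null(session$track)) {
    xy <- trackXY(session$track)
    write.csv(data.frame(frame = seq_len(nrow(xy)) - 1L,
                         x_px = xy[, 1], y_px = xy[, 2]),
              file.path(path, "track.csv"), row.names = FALSE)
  }
  if (!is.null(session$truth)) {
    truth <- session$truth
    jsonlite::write_json(
      list(coupling_matrix = truth$coupling_matrix,
           latent_freqs_hz = truth$latent_freqs_hz,
           electrode_weights = truth$electrode_weights,
           place_field_centers = truth$place_field_centers,
           n_spikes = vapply(truth$spike_times, length, integer(1)),
           seed = truth$config$seed),
      file.path(path, "truth.json"), digits = NA, null = "null")
  }
  invisible(path)
}

#' Load a session directory
#'
#' Reads the layout written by [writeSession()]. `spikes.csv`, `track.csv`
#' and `truth.json` are optional; their absence gives `NULL` elements, not
#' an error. Missing mandatory files and NaN values in the traces are
#' rejected with informative messages.
#'
#' @param path session directory.
#' @return list with `traces`, `ephys`, `spikes`, `track`, `truth`.
#' @export
loadSession <- function(path) {
  need <- c("traces.csv", "ephys.bin", "meta.json")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop(sprintf("missing mandatory session file: %s", f), call. = FALSE)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)

  df <- read.csv(file.path(path, "traces.csv"), check.names = FALSE)
  dffm <- t(as.matrix(df[, -1, drop = FALSE]))
  if (any(is.na(dffm))) {
    bad <- which(is.na(dffm), arr.ind = TRUE)
    stop(sprintf("NaN in traces: ROI %s, frame %d (and %d more)",
                 rownames(dffm)[bad[1, 1]], bad[1, 2], nrow(bad) - 1L),
         call. = FALSE)
  }
  traces <- TraceSet(dffm, df$frame_time_s, roi_ids = colnames(df)[-1])

  nch <- meta$n_channels
  sz <- file.info(file.path(path, "ephys.bin"))$size
  n_int <- sz / 2
  if (n_int %% nch != 0)
    stop(sprintf("truncated ephys.bin: %d int16 samples not divisible by %d channels",
                 n_int, nch), call. = FALSE)
  con <- file(file.path(path, "ephys.bin"), "rb")
  counts <- readBin(con, "integer", n = n_int, size = 2, endian = "little")
  close(con)
  counts <- matrix(counts, nrow = nch)
  trig <- NULL
  if (!is.null(meta$trigger_channel) && !is.na(meta$trigger_channel)) {
    trig <- counts[meta$trigger_channel, ] * meta$uv_per_count
    counts <- counts[-meta$trigger_channel, , drop = FALSE]
  }
  ephys <- EphysRecording(counts * meta$uv_per_count, meta$rate_hz,
                          tetrode_of = meta$tetrode_of,
                          trigger = if (is.null(trig)) numeric(0) else trig,
                          uv_per_count = meta$uv_per_count)

  spikes <- NULL
  if (file.exists(file.path(path, "spikes.csv"))) {
    sp <- read.csv(file.path(path, "spikes.csv"))
    if (nrow(sp)) spikes <- SpikeTrainSet(sp)
  }
  track <- NULL
  if (file.exists(file.path(path, "track.csv"))) {
    tk <- read.csv(file.path(path, "track.csv"))
    vr <- if (!is.null(meta$video_rate_hz) && !is.na(meta$video_rate_hz))
      meta$video_rate_hz else 30
    track <- BehaviorTrack(tk$frame / vr, cbind(tk$x_px, tk$y_px),
                           rate_hz = vr)
  }
  truth <- NULL
  if (file.exists(file.path(path, "truth.json")))
    truth <- jsonlite::read_json(file.path(path, "truth.json"),
                                 simplifyVector = TRUE)
  list(traces = traces, ephys = ephys, spikes = spikes, track = track,
       truth = truth)
}

#' Frame times from a trigger channel
#'
#' Detects rising edges in the synchronization frame-trigger channel the
#' microscope emits (one pulse per imaging frame) and returns one timestamp
#' per edge on the electrophysiology clock, which the package treats as the
#' master clock. An edge is the first sample at or above threshold after a
#' below-threshold sample. Detection is invariant to amplitude scaling
#' because the default threshold is the pulse mid-level,
#' `min + (max - min) / 2`.
#'
#' @param trigger numeric trigger channel.
#' @param rate_hz sampling rate of the trigger channel.
#' @param threshold detection level; default mid-level.
#' @return rising-edge times in seconds (first sample is t = 0).
#' @export
frameTimesFromTrigger <- function(trigger, rate_hz, threshold = NULL) {
  stopifnot(length(trigger) > 1, rate_hz > 0)
  if (max(trigger) == min(trigger))
    stop("no rising edges found in trigger channel (constant signal)",
         call. = FALSE)
  if (is.null(threshold))
    threshold <- min(trigger) + 0.5 * (max(trigger) - min(trigger))
  above <- trigger >= threshold
  edges <- which(above[-1] & !above[-length(above)]) + 1L
  if (above[1]) edges <- c(1L, edges)
  if (!length(edges))
    stop("no rising edges found in trigger channel", call. = FALSE)
  (edges - 1) / rate_hz
}

#' Synchronize a behavioral video to the imaging clock
#'
#' Fixes the affine map from video time to imaging time using two anchor
#' frames: the video frames where the imaging laser's infrared light first
#' and last appears, which correspond to the start and end of the imaging
#' acquisition. The map is `t_imaging = factor * t_video + offset_s`; a
#' factor outside \[0.99, 1.01\] (camera clock drift beyond 1%) triggers a
#' warning but the mapping is still returned.
#'
#' @param laser_on_frame,laser_off_frame video frame indices of the two
#'   anchors.
#' @param video_rate_hz nominal video frame rate.
#' @param imaging_start_s,imaging_end_s imaging-clock times of the anchors.
#' @return list with `offset_s` and `factor`.
#' @export
syncVideo <- function(laser_on_frame, laser_off_frame, video_rate_hz,
                      imaging_start_s, imaging_end_s) {
  if (laser_on_frame >= laser_off_frame)
    stop("laser_on_frame must precede laser_off_frame", call. = FALSE)
  if (imaging_start_s >= imaging_end_s)
    stop("imaging_start_s must precede imaging_end_s", call. = FALSE)
  t_on <- laser_on_frame / video_rate_hz
  t_off <- laser_off_frame / video_rate_hz
  factor <- (imaging_end_s - imaging_start_s) / (t_off - t_on)
  offset <- imaging_start_s - factor * t_on
  if (factor < 0.99 || factor > 1.01)
    warning(sprintf("video rate-correction factor %.4f outside [0.99, 1.01]",
                    factor), call. = FALSE)
  list(offset_s = offset, factor = factor)
}

#' Apply a video sync to a BehaviorTrack
#'
#' @param track a [BehaviorTrack].
#' @param sync result of [syncVideo()].
#' @return the track with its sync slots set.
#' @export
applySync <- function(track, sync) {
  track@sync_offset_s <- sync$offset_s
  track@sync_factor <- sync$factor
  track
}
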