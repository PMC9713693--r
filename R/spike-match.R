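# Spike-train to calcium matching: render sorted spikes as a pseudo
# calcium trace and find the best-correlated imaged ROI.

#' Convolve a spike train with a calcium decay kernel
#'
#' Bins spikes to imaging frames (binary by default: a frame with one or
#' more spikes gets 1) and convolves with the causal single-exponential
#' kernel `exp(-t / tau)` evaluated at the frame spacing, giving the trace
#' the unit would produce if read out by a calcium indicator with decay
#' constant `tau`. Implemented as an exact first-order recursive filter, so
#' the impulse response is `exp(-m * dt / tau)` to machine precision and
#' superposition is exact.
#'
#' @param spikes a [SpikeTrainSet], or a numeric vector of spike times.
#' @param decay_tau_s indicator decay time constant, seconds (> 0).
#' @param frame_times_s imaging frame timestamps (uniform spacing assumed
#'   for the kernel step).
#' @param unit unit to render when `spikes` is a `SpikeTrainSet`.
#' @param count use per-frame spike counts instead of binary occupancy.
#' @return a [PseudoTrace-class].
#' @export
convolveSpikes <- function(spikes, decay_tau_s, frame_times_s,
                           unit = NULL, count = FALSE) {
  if (decay_tau_s <= 0) stop("decay_tau_s must be > 0", call. = FALSE)
  if (methods::is(spikes, "SpikeTrainSet")) {
    if (is.null(unit)) unit <- unitIds(spikes)[1]
    st <- spikeTimes(spikes, unit)
  } else {
    st <- as.numeric(spikes)
    if (is.null(unit)) unit <- "unit"
  }
  nf <- length(frame_times_s)
  dt <- if (nf > 1) median(diff(frame_times_s)) else decay_tau_s
  lo <- frame_times_s[1]
  hi <- frame_times_s[nf] + dt
  out_of_span <- st < lo | st >= hi
  if (any(out_of_span)) {
    warning(sprintf("%d spike(s) outside the frame span clipped",
                    sum(out_of_span)), call. = FALSE)
    st <- st[!out_of_span]
  }
  cnt <- tabulate(findInterval(st, c(frame_times_s, hi)), nf)
  if (!count) cnt <- as.integer(cnt > 0)
  vals <- as.numeric(filter(cnt, exp(-dt / decay_tau_s),
                            method = "recursive"))
  methods::new("PseudoTrace", values = vals,
               frame_times_s = as.numeric(frame_times_s),
               decay_tau_s = decay_tau_s, unit_id = as.character(unit))
}

#' Best-matching imaged ROI for a pseudo calcium trace
#'
#' Pearson-correlates the pseudo trace against every ROI's dF/F and
#' returns the best match plus the full ranking. Pearson's scale
#' invariance makes the result independent of the pseudo trace's
#' arbitrary amplitude.
#'
#' @param pseudo a [PseudoTrace-class] (or numeric vector per frame).
#' @param traces a [TraceSet] on the same frame axis.
#' @return list with `roi_id`, `rho`, and `ranking` (data.frame of all
#'   ROIs sorted by decreasing correlation).
#' @export
bestMatch <- function(pseudo, traces) {
  v <- if (methods::is(pseudo, "PseudoTrace")) pseudo@values
       else as.numeric(pseudo)
  if (length(v) != ncol(dff(traces)))
    stop("pseudo trace and TraceSet frame axes differ", call. = FALSE)
  if (sd(v) == 0)
    stop("pseudo trace is constant (no spikes?); correlation undefined",
         call. = FALSE)
  r <- as.vector(cor(v, t(dff(traces))))
  ord <- order(-r, seq_along(r))
  ranking <- data.frame(roi_id = roiIds(traces)[ord], rho = r[ord],
                        row.names = NULL)
  list(roi_id = ranking$roi_id[1], rho = ranking$rho[1], ranking = ranking)
}
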