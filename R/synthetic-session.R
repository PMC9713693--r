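# Synthetic bimodal sessions with known ground-truth coupling.
#
# Generative model, in brief: each frequency band b carries a latent drive
# l_b(t) = envelope_b(t) * sin(2 pi f_b t + phase), where the envelope is a
# rectified Ornstein-Uhlenbeck process (mean 1) so band power fluctuates on
# calcium timescales. Electrode voltage is a per-electrode weighted sum of
# the latents plus 1/f-shaped noise. ROI i fires as an inhomogeneous Poisson
# process with rate baseline + sum_b coupling[i, b] * max(l_b, 0) (times a
# Gaussian place-field factor when field centers are given), and its dF/F is
# the per-frame spike count convolved with a single-exponential kernel plus
# Gaussian noise. A trigger channel carries one pulse per imaging frame.

#' Configuration of a synthetic bimodal session
#'
#' Bundles and validates every parameter of [generateSession()]. Defaults
#' mirror a 10-minute head-fixed session: 100 ROIs, 16 electrodes in 4
#' tetrodes, 15 Hz imaging frames and 30 fps behavioral video.
#'
#' @param n_rois number of imaged ROIs.
#' @param n_electrodes number of electrodes; 16 implies 4 tetrodes of 4.
#' @param duration_s session length in seconds.
#' @param imaging_rate_hz imaging frame rate (frames/s).
#' @param ephys_rate_hz electrophysiology sampling rate (samples/s).
#' @param video_rate_hz behavioral video frame rate (frames/s).
#' @param coupling_matrix ROI x band matrix of dimensionless weights in
#'   \[0, 1\] tying each ROI's firing rate to each band latent. Defaults to
#'   all zeros (no coupling).
#' @param latent_freqs_hz carrier frequency of each band latent, one per
#'   canonical band (theta, beta, low gamma, high gamma).
#' @param noise_sd standard deviation of the additive Gaussian dF/F noise.
#' @param decay_tau_s calcium indicator decay time constant (seconds).
#' @param arena_px arena width and height in pixels (video convention:
#'   origin top-left, x right, y down).
#' @param place_field_centers optional ROI x 2 matrix of place-field
#'   centers in arena pixels; when given, each ROI's baseline rate is
#'   multiplied by a Gaussian bump of the animal's distance to its center.
#' @param place_field_sigma_px width of that Gaussian bump.
#' @param baseline_rate_hz baseline firing rate per ROI.
#' @param rate_gain_hz firing-rate increment per unit coupling at unit
#'   rectified latent amplitude.
#' @param lfp_amp_uV scale of the oscillatory LFP component, microvolts.
#' @param lfp_noise_uV scale of the 1/f electrode noise, microvolts.
#' @param noise_exponent spectral exponent of the electrode noise.
#' @param seed integer seed; identical config + seed gives identical output.
#'
#' @return a list of class `"SessionConfig"`.
#' @seealso [generateSession()]
#' @export
sessionConfig <- function(n_rois = 100, n_electrodes = 16, duration_s = 600,
                          imaging_rate_hz = 15, ephys_rate_hz = 1000,
                          video_rate_hz = 30,
                          coupling_matrix = NULL,
                          latent_freqs_hz = c(10, 22, 45, 80),
                          noise_sd = 0.05, decay_tau_s = 0.7,
                          arena_px = c(600, 600),
                          place_field_centers = NULL,
                          place_field_sigma_px = 60,
                          baseline_rate_hz = 1, rate_gain_hz = 10,
                          lfp_amp_uV = 100, lfp_noise_uV = 30,
                          noise_exponent = 1, seed = 1L) {
  if (is.null(coupling_matrix))
    coupling_matrix <- matrix(0, n_rois, length(latent_freqs_hz))
  coupling_matrix <- as.matrix(coupling_matrix)
  cfg <- list(n_rois = n_rois, n_electrodes = n_electrodes,
              duration_s = duration_s, imaging_rate_hz = imaging_rate_hz,
              ephys_rate_hz = ephys_rate_hz, video_rate_hz = video_rate_hz,
              coupling_matrix = coupling_matrix,
              latent_freqs_hz = latent_freqs_hz, noise_sd = noise_sd,
              decay_tau_s = decay_tau_s, arena_px = arena_px,
              place_field_centers = place_field_centers,
              place_field_sigma_px = place_field_sigma_px,
              baseline_rate_hz = baseline_rate_hz,
              rate_gain_hz = rate_gain_hz, lfp_amp_uV = lfp_amp_uV,
              lfp_noise_uV = lfp_noise_uV, noise_exponent = noise_exponent,
              seed = as.integer(seed))
  class(cfg) <- "SessionConfig"
  validateSessionConfig(cfg)
  cfg
}

validateSessionConfig <- function(cfg) {
  num <- c(cfg$n_rois, cfg$n_electrodes, cfg$duration_s, cfg$imaging_rate_hz,
           cfg$ephys_rate_hz, cfg$video_rate_hz, cfg$latent_freqs_hz,
           cfg$noise_sd, cfg$decay_tau_s, cfg$arena_px, cfg$baseline_rate_hz,
           cfg$rate_gain_hz, cfg$coupling_matrix)
  stopIfNotFinite(num, "session config")
  rates <- c(cfg$imaging_rate_hz, cfg$ephys_rate_hz, cfg$video_rate_hz)
  if (any(rates <= 0)) stop("all rates must be > 0", call. = FALSE)
  if (cfg$duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (nrow(cfg$coupling_matrix) != cfg$n_rois ||
      ncol(cfg$coupling_matrix) != length(cfg$latent_freqs_hz))
    stop("coupling_matrix must be n_rois x n_bands", call. = FALSE)
  if (!is.null(cfg$place_field_centers) &&
      nrow(as.matrix(cfg$place_field_centers)) != cfg$n_rois)
    stop("place_field_centers must have one row per ROI", call. = FALSE)
  invisible(cfg)
}

# Rectified Ornstein-Uhlenbeck envelope times a sinusoidal carrier.
latentDrive <- function(n, dt, freq_hz, tau_env_s = 1, env_sd = 0.5) {
  a <- exp(-dt / tau_env_s)
  innov <- rnorm(n, sd = env_sd * sqrt(1 - a^2))
  ou <- as.numeric(filter(innov, a, method = "recursive"))
  env <- pmax(0, 1 + ou)
  phase <- runif(1, 0, 2 * pi)
  env * sin(2 * pi * freq_hz * dt * (seq_len(n) - 1) + phase)
}

# 1/f^(exponent/2)-shaped Gaussian noise via spectral shaping, unit sd.
oneOverFNoise <- function(n, exponent) {
  white <- rnorm(n)
  spec <- fft(white)
  k <- c(1, seq_len(n - 1))          # avoid the DC singularity
  shape <- k^(-exponent / 2)
  shape[1] <- 0
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate a coupled calcium/ephys/behavior session
#'
#' Simulates a full bimodal recording with known ground truth so every
#' analysis stage downstream can be tested without real data: per-ROI dF/F
#' traces, multi-electrode voltage with a frame-trigger channel, sorted
#' spike times, and a reflecting-random-walk behavior track. See the file
#' header comment for the generative model. Identical config and seed give
#' bit-identical output.
#'
#' @param config a [sessionConfig()].
#'
#' @return a list with elements `traces` ([TraceSet]), `ephys`
#'   ([EphysRecording]), `spikes` ([SpikeTrainSet]), `track`
#'   ([BehaviorTrack]) and `truth` (a list holding the latent drives, the
#'   per-electrode band weights, the configured coupling matrix, spike
#'   times per ROI, and place-field centers).
#' @examples
#' cfg <- sessionConfig(n_rois = 4, n_electrodes = 4, duration_s = 20,
#'                      ephys_rate_hz = 250, seed = 7)
#' s <- generateSession(cfg)
#' dim(dff(s$traces))
#' @export
generateSession <- function(config) {
  validateSessionConfig(config)
  cfg <- config
  n_bands <- length(cfg$latent_freqs_hz)
  nf <- round(cfg$duration_s * cfg$imaging_rate_hz)
  ns <- round(cfg$duration_s * cfg$ephys_rate_hz)
  nv <- round(cfg$duration_s * cfg$video_rate_hz)
  dt_e <- 1 / cfg$ephys_rate_hz
  frame_times <- (seq_len(nf) - 1) / cfg$imaging_rate_hz

  # -- band latents (one seeded stream per component, so each piece can be
  #    regenerated independently)
  latents <- withSeed(splitSeed(cfg$seed, 1), {
    vapply(cfg$latent_freqs_hz,
           function(f) latentDrive(ns, dt_e, f), numeric(ns))
  })                                           # ns x n_bands

  # -- electrode voltage: weighted latents + 1/f noise, quantized to the
  #    int16 export grid so file round-trips are exact
  weights <- withSeed(splitSeed(cfg$seed, 2),
    matrix(runif(cfg$n_electrodes * n_bands, 0.4, 1),
           cfg$n_electrodes, n_bands))
  noise <- withSeed(splitSeed(cfg$seed, 3), {
    vapply(seq_len(cfg$n_electrodes),
           function(e) oneOverFNoise(ns, cfg$noise_exponent), numeric(ns))
  })                                           # ns x n_electrodes
  volt <- latents %*% t(weights) * cfg$lfp_amp_uV + noise * cfg$lfp_noise_uV
  q <- 0.195
  volt <- round(t(volt) / q) * q               # electrode x sample, uV

  # -- frame trigger: one short TTL-like pulse per imaging frame
  trigger <- numeric(ns)
  onset <- pmin(ns, floor(frame_times * cfg$ephys_rate_hz) + 1L)
  width <- max(1L, round(0.001 * cfg$ephys_rate_hz))
  for (w in seq_len(width) - 1L) trigger[pmin(ns, onset + w)] <- 5

  # -- behavior: reflecting random walk with AR(1) velocity
  track <- withSeed(splitSeed(cfg$seed, 4), {
    stepsd <- 90 / cfg$video_rate_hz          # ~90 px/s RMS speed
    vx <- as.numeric(filter(rnorm(nv, sd = stepsd * sqrt(1 - 0.8^2)), 0.8,
                            method = "recursive"))
    vy <- as.numeric(filter(rnorm(nv, sd = stepsd * sqrt(1 - 0.8^2)), 0.8,
                            method = "recursive"))
    x <- cfg$arena_px[1] / 2 + cumsum(vx)
    y <- cfg$arena_px[2] / 2 + cumsum(vy)
    reflect <- function(p, hi) {
      p <- p %% (2 * hi)
      ifelse(p > hi, 2 * hi - p, p)
    }
    cbind(reflect(x, cfg$arena_px[1]), reflect(y, cfg$arena_px[2]))
  })
  track_times <- (seq_len(nv) - 1) / cfg$video_rate_hz

  # -- firing rates on a coarse rate clock, then Poisson spikes
  rate_hz_clock <- min(100, cfg$ephys_rate_hz)
  nb <- round(cfg$duration_s * rate_hz_clock)
  rect <- pmax(latents, 0)
  # bin-mean the rectified latents onto the rate clock
  idx <- pmin(nb, floor((seq_len(ns) - 1) * (nb / ns)) + 1L)
  rect_clock <- rowsum(rect, idx) / tabulate(idx, nb)   # nb x n_bands
  bin_t <- (seq_len(nb) - 0.5) / rate_hz_clock
  place_factor <- matrix(1, nb, cfg$n_rois)
  if (!is.null(cfg$place_field_centers)) {
    ctr <- as.matrix(cfg$place_field_centers)
    px <- approx(track_times, track[, 1], xout = bin_t, rule = 2)$y
    py <- approx(track_times, track[, 2], xout = bin_t, rule = 2)$y
    for (i in seq_len(cfg$n_rois)) {
      d2 <- (px - ctr[i, 1])^2 + (py - ctr[i, 2])^2
      place_factor[, i] <- exp(-d2 / (2 * cfg$place_field_sigma_px^2))
    }
  }
  drive <- rect_clock %*% t(cfg$coupling_matrix)   # nb x n_rois
  rate <- sweep(drive * cfg$rate_gain_hz, 2, cfg$baseline_rate_hz, "+") *
    place_factor
  spike_list <- withSeed(splitSeed(cfg$seed, 5), {
    counts <- matrix(rpois(nb * cfg$n_rois, pmax(rate, 0) / rate_hz_clock),
                     nb, cfg$n_rois)
    lapply(seq_len(cfg$n_rois), function(i) {
      nz <- which(counts[, i] > 0)
      if (!length(nz)) return(numeric(0))
      t0 <- rep((nz - 1) / rate_hz_clock, counts[nz, i])
      sort(t0 + runif(length(t0), 0, 1 / rate_hz_clock))
    })
  })

  # -- dF/F: per-frame spike counts through an exponential decay kernel
  decay <- exp(-(1 / cfg$imaging_rate_hz) / cfg$decay_tau_s)
  dffm <- withSeed(splitSeed(cfg$seed, 6), {
    m <- vapply(spike_list, function(st) {
      cnt <- tabulate(pmin(nf, floor(st * cfg$imaging_rate_hz) + 1L), nf)
      as.numeric(filter(cnt, decay, method = "recursive"))
    }, numeric(nf))
    t(m) + matrix(rnorm(cfg$n_rois * nf, sd = cfg$noise_sd), cfg$n_rois, nf)
  })
  centroids <- withSeed(splitSeed(cfg$seed, 7),
    cbind(runif(cfg$n_rois, 0, 512), runif(cfg$n_rois, 0, 512)))

  spikes_df <- data.frame(
    unit_id = rep(sprintf("unit_%03d", seq_len(cfg$n_rois) - 1L),
                  vapply(spike_list, length, integer(1))),
    tetrode = rep(((seq_len(cfg$n_rois) - 1L) %% 4L) + 1L,
                  vapply(spike_list, length, integer(1))),
    time_s = unlist(spike_list))

  list(
    traces = TraceSet(dffm, frame_times, centroids = centroids),
    ephys = EphysRecording(volt, cfg$ephys_rate_hz,
                           tetrode_of = ((seq_len(cfg$n_electrodes) - 1L) %/%
                                           4L) + 1L,
                           trigger = trigger, uv_per_count = q),
    spikes = SpikeTrainSet(spikes_df),
    track = BehaviorTrack(track_times, track, rate_hz = cfg$video_rate_hz),
    truth = list(latent_drives = latents,
                 latent_freqs_hz = cfg$latent_freqs_hz,
                 electrode_weights = weights,
                 coupling_matrix = cfg$coupling_matrix,
                 spike_times = spike_list,
                 place_field_centers = cfg$place_field_centers,
                 config = cfg))
}
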