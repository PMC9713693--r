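# End-to-end orchestration: simulate or load a session, synchronize
# streams, extract band power, run the correlation analysis, match spikes,
# build spatial maps, and write a deterministic report bundle.

#' Run the full bimodal analysis pipeline
#'
#' Executes every stage on a session (a directory path or the in-memory
#' result of [generateSession()]) and writes `rho.csv`, `pvalues.csv`,
#' `match.json`, `map_tests.csv` (when a behavior track is present),
#' `summary.json` and `run.log` into `out_dir`. Re-running with the same
#' config yields a byte-identical `summary.json`.
#'
#' @param session session directory path or list from [generateSession()].
#' @param out_dir output directory.
#' @param band_defs band definitions, default [canonicalBands()].
#' @param n_shuffles,min_shift_frac,fdr_q correlation parameters.
#' @param tau_s calcium decay constant for spike matching.
#' @param bin_px,sigma_px spatial map parameters.
#' @param n_resample,n_perm 2-D KS parameters.
#' @param map_rois number of ROIs mapped (the most active ones).
#' @param seed master seed for every stochastic stage.
#' @return the summary list, invisibly.
#' @export
runAll <- function(session, out_dir, band_defs = canonicalBands(),
                   n_shuffles = 100, min_shift_frac = 0.1, fdr_q = 0.05,
                   tau_s = 0.7, bin_px = 25, sigma_px = 62.5,
                   n_resample = 500, n_perm = 199, map_rois = 4,
                   seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    cat(sprintf("%-12s %7.2f s\n", name, proc.time()[3] - t0),
        file = logf, append = TRUE)
    out
  }

  s <- stage("load", if (is.character(session)) loadSession(session)
             else session)
  traces <- s$traces

  bp <- stage("bandpower",
              bandPowerTraces(s$ephys, frameTimes(traces), band_defs))
  res <- stage("correlation",
               correlationAnalysis(traces, bp, n_shuffles = n_shuffles,
                                   min_shift_frac = min_shift_frac,
                                   fdr_q = fdr_q,
                                   seed = splitSeed(seed, 11)))
  stage("write_corr", {
    writeRhoCsv(res, file.path(out_dir, "rho.csv"))
    writePCsv(res, file.path(out_dir, "pvalues.csv"))
  })

  match <- NULL
  if (!is.null(s$spikes)) {
    match <- stage("spikematch", {
      lapply(unitIds(s$spikes), function(u) {
        pt <- convolveSpikes(s$spikes, tau_s, frameTimes(traces), unit = u)
        if (sd(pt@values) == 0) return(NULL)
        bm <- bestMatch(pt, traces)
        list(unit_id = u, roi_id = bm$roi_id, rho = bm$rho)
      })
    })
    match <- Filter(Negate(is.null), match)
    jsonlite::write_json(match, file.path(out_dir, "match.json"),
                         auto_unbox = TRUE, digits = 10)
  }

  map_tests <- NULL
  if (!is.null(s$track)) {
    map_tests <- stage("maps", {
      act <- rowMeans(dff(traces))
      top <- order(-act)[seq_len(min(map_rois, nrow(traces)))]
      arena <- ceiling(apply(trackXY(s$track), 2, max))
      maps <- lapply(top, function(i)
        buildSpatialMap(dff(traces)[i, ], frameTimes(traces), s$track,
                        arena_px = arena, bin_px = bin_px,
                        sigma_px = sigma_px, roi_id = roiIds(traces)[i]))
      pairwiseMapTests(maps, n_resample = n_resample,
                       seed = splitSeed(seed, 13), n_perm = n_perm,
                       fdr_q = fdr_q)
    })
    write.csv(map_tests, file.path(out_dir, "map_tests.csv"),
              row.names = FALSE)
  }

  bands <- bandNames(bp)
  rho_moments <- lapply(setNames(bands, bands), function(b) {
    v <- as.vector(rho(res)[, , b])
    v <- v[is.finite(v)]
    list(mean = mean(v), sd = sd(v))
  })
  best <- if (length(match)) {
    rhos <- vapply(match, function(m) m$rho, numeric(1))
    match[[which.max(rhos)]]
  } else NULL
  summary <- list(
    n_rois = nrow(traces), n_electrodes = nrow(bp),
    n_frames = ncol(traces), bands = bands,
    params = list(n_shuffles = n_shuffles, min_shift_frac = min_shift_frac,
                  fdr_q = fdr_q, tau_s = tau_s, bin_px = bin_px,
                  sigma_px = sigma_px, seed = seed),
    rho_moments = rho_moments,
    ks_stat = as.list(res@ks_stat), ks_p = as.list(res@ks_p),
    fraction_significant = as.list(significantFraction(res)),
    fraction_significant_shuffled =
      as.list(significantFraction(res, shuffled = TRUE)),
    best_spike_match = best,
    map_pairs_significant = if (!is.null(map_tests))
      sum(map_tests$significant) else NULL,
    map_pairs_tested = if (!is.null(map_tests)) nrow(map_tests) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  cat(sprintf("%-12s %7.2f s\n", "total", proc.time()[3] - t_all),
      file = logf, append = TRUE)
  invisible(summary)
}

writeRhoCsv <- function(res, path) {
  r <- rho(res)
  d <- dim(r); dn <- dimnames(r)
  long <- data.frame(
    roi_id = rep(dn[[1]], times = d[2] * d[3]),
    electrode = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    band = rep(dn[[3]], each = d[1] * d[2]),
    rho = as.vector(r))
  write.csv(long, path, row.names = FALSE)
}

writePCsv <- function(res, path) {
  p <- empiricalPValues(res)
  sig <- res@significant
  d <- dim(p); dn <- dimnames(p)
  long <- data.frame(
    roi_id = rep(dn[[1]], times = d[2] * d[3]),
    electrode = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    band = rep(dn[[3]], each = d[1] * d[2]),
    p_emp = as.vector(p), significant = as.vector(sig))
  write.csv(long, path, row.names = FALSE)
}

#' Write a ready-to-analyze synthetic demo session
#'
#' Three presets: `"headfixed_100roi"` mirrors a 10-minute head-fixed
#' session (100 ROIs, 16 electrodes, mixed band coupling on half the
#' ROIs); `"freelymoving_place"` an 8-minute foraging session with
#' place-modulated ROIs and a 30-fps track; `"null"` a zero-coupling
#' control at the head-fixed scale.
#'
#' @param preset one of the three names above.
#' @param out_dir target directory; must be empty unless `force`.
#' @param seed generator seed.
#' @param force overwrite a non-empty directory.
#' @param ... overrides passed to [sessionConfig()].
#' @return the session directory path, invisibly.
#' @export
makeDemo <- function(preset = c("headfixed_100roi", "freelymoving_place",
                                "null"),
                     out_dir, seed = 1L, force = FALSE, ...) {
  preset <- match.arg(preset)
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop(sprintf("output directory '%s' is not empty (use force = TRUE)",
                 out_dir), call. = FALSE)
  base <- switch(preset,
    headfixed_100roi = list(n_rois = 100, n_electrodes = 16,
                            duration_s = 600),
    freelymoving_place = list(n_rois = 8, n_electrodes = 16,
                              duration_s = 480, baseline_rate_hz = 4),
    null = list(n_rois = 100, n_electrodes = 16, duration_s = 600))
  args <- utils::modifyList(base, list(...))
  args$seed <- seed
  if (preset == "headfixed_100roi" && is.null(args$coupling_matrix)) {
    # half the ROIs coupled with random weights up to 0.5 across bands
    h <- ceiling(args$n_rois / 2)
    cm <- matrix(0, args$n_rois, 4)
    cm[seq_len(h), ] <- matrix(runif2(h * 4, seed), h, 4) * 0.5
    args$coupling_matrix <- cm
  }
  if (preset == "freelymoving_place") {
    if (is.null(args$place_field_centers))
      args$place_field_centers <- withSeed(splitSeed(seed, 21),
        cbind(runif(args$n_rois, 100, 500), runif(args$n_rois, 100, 500)))
    if (is.null(args$coupling_matrix))
      args$coupling_matrix <- matrix(0.2, args$n_rois, 4)
  }
  cfg <- do.call(sessionConfig, args)
  s <- generateSession(cfg)
  writeSession(s, out_dir)
  invisible(out_dir)
}

runif2 <- function(n, seed) withSeed(splitSeed(seed, 20), runif(n))
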