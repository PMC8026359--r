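# MEP-level analysis: artifact rejection, peak-to-peak amplitude, onset
# latency, excitability maps, hotspot localization, and adaptive
# maximum-likelihood estimation of the resting motor threshold.

#' Stimulus-locked EMG trace
#'
#' @param samples numeric vector, EMG in mV.
#' @param sampling_rate Hz (default 10000; acquisition is assumed already
#'   bandpass filtered in hardware, no re-filtering is applied here).
#' @param stimulus_index 1-based sample index of the TMS pulse.
#' @param muscle `"FDI"` or `"ADM"`.
#' @return an object of class `emg_trace`.
#' @details The trace must span at least -100 ms before and +60 ms after the
#'   stimulus so that the baseline window and the 10-40 ms MEP window are
#'   fully covered.
#' @export
emg_trace <- function(samples, sampling_rate = 10000, stimulus_index,
                      muscle = c("FDI", "ADM")) {
  muscle <- match.arg(muscle)
  if (!is.numeric(samples) || anyNA(samples))
    knob_stop("samples must be finite numeric", "knobmap_input_error")
  n_pre <- stimulus_index - 1L
  n_post <- length(samples) - stimulus_index
  if (n_pre < 0.100 * sampling_rate || n_post < 0.060 * sampling_rate)
    knob_stop("trace must cover at least -100..+60 ms around the stimulus",
              "knobmap_input_error")
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate,
                 stimulus_index = as.integer(stimulus_index), muscle = muscle),
            class = "emg_trace")
}

# index range (relative to samples) of a [from_ms, to_ms] window around the
# stimulus; from is inclusive, sample at exactly t = from_ms included.
window_idx <- function(trace, from_ms, to_ms) {
  fs <- trace$sampling_rate
  i0 <- trace$stimulus_index + round(from_ms * fs / 1000)
  i1 <- trace$stimulus_index + round(to_ms * fs / 1000)
  if (i0 < 1L || i1 > length(trace$samples))
    knob_stop("analysis window falls outside the trace", "knobmap_input_error")
  i0:i1
}

#' Flag trials with a contaminated pre-stimulus baseline
#'
#' Algorithmic surrogate for the visual screening of artifact trials: a trial
#' is rejected when the root-mean-square of the -100..0 ms pre-stimulus
#' window exceeds `baseline_rms_limit`.
#'
#' @param trace an [emg_trace()].
#' @param baseline_rms_limit RMS limit in mV (default 0.02).
#' @return `TRUE` if the trial is valid, `FALSE` if rejected.
#' @export
reject_artifact_trial <- function(trace, baseline_rms_limit = 0.02) {
  stopifnot(inherits(trace, "emg_trace"))
  idx <- window_idx(trace, -100, 0)
  idx <- idx[-length(idx)]            # baseline strictly before the stimulus
  rms <- sqrt(mean(trace$samples[idx]^2))
  rms <= baseline_rms_limit
}

#' Peak-to-peak MEP amplitude
#'
#' Maximum minus minimum of the EMG within `window` ms after the stimulus
#' (default 10-40 ms), extracted trial by trial.
#'
#' @param trace an [emg_trace()].
#' @param window length-2 numeric, post-stimulus window in ms.
#' @return amplitude in mV (>= 0).
#' @export
extract_amplitude <- function(trace, window = c(10, 40)) {
  stopifnot(inherits(trace, "emg_trace"))
  x <- trace$samples[window_idx(trace, window[1], window[2])]
  max(x) - min(x)
}

#' MEP onset latency by sustained threshold crossing
#'
#' Algorithmic surrogate for visual latency reading: the onset is the
#' earliest time within `window` at which the rectified, baseline-corrected
#' EMG exceeds `k_sd` times the pre-stimulus baseline SD continuously for
#' `sustain_ms`. With a silent baseline (SD exactly zero) any sustained
#' non-zero deflection counts; an all-zero trace yields no onset.
#'
#' @param trace an [emg_trace()].
#' @param k_sd threshold in baseline SDs (default 3).
#' @param sustain_ms minimum supra-threshold duration in ms (default 0.5).
#' @param window post-stimulus search window in ms (default `c(10, 40)`).
#' @return latency in ms, or `NA_real_` when no onset is found.
#' @export
estimate_latency <- function(trace, k_sd = 3, sustain_ms = 0.5,
                             window = c(10, 40)) {
  stopifnot(inherits(trace, "emg_trace"))
  base <- trace$samples[utils::head(window_idx(trace, -100, 0), -1)]
  idx <- window_idx(trace, window[1], window[2])
  latency_from_signal(trace$samples[idx], mean(base), stats::sd(base),
                      t0_ms = window[1], fs = trace$sampling_rate,
                      k_sd = k_sd, sustain_ms = sustain_ms)
}

# core onset search on a windowed signal; t0_ms is the time of signal[1]
latency_from_signal <- function(signal, base_mean, base_sd, t0_ms, fs,
                                k_sd = 3, sustain_ms = 0.5) {
  thr <- k_sd * base_sd
  dev <- abs(signal - base_mean)
  above <- if (thr > 0) dev > thr else dev > 0
  if (!any(above)) return(NA_real_)
  need <- max(1L, ceiling(sustain_ms * fs / 1000))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= need)
  if (!length(ok)) return(NA_real_)
  first <- ends[ok[1]] - r$lengths[ok[1]] + 1L
  t0_ms + (first - 1L) * 1000 / fs
}

#' Per-site excitability map
#'
#' Averages peak-to-peak MEP amplitudes over valid trials for each grid site.
#' A site with zero valid trials is flagged (its mean is `NA`) and excluded
#' from the later hotspot search, with a warning.
#'
#' @param records data frame with columns `line_index`, `target_index`,
#'   `amplitude` (mV) and logical `valid`.
#' @param n_lines,n_targets grid dimensions (defaults 5 and 7).
#' @return an object of class `excitability_map`: list with matrices
#'   `mean_amplitude`, `n_valid_trials` and logical `flagged`
#'   (`n_lines` x `n_targets`, rows = lines).
#' @export
build_map <- function(records, n_lines = 5, n_targets = 7) {
  need <- c("line_index", "target_index", "amplitude", "valid")
  if (!all(need %in% names(records)))
    knob_stop(paste("records must have columns:", paste(need, collapse = ", ")),
              "knobmap_input_error")
  if (any(records$line_index < 1 | records$line_index > n_lines |
          records$target_index < 1 | records$target_index > n_targets))
    knob_stop("site indices outside the grid", "knobmap_input_error")
  mean_amp <- matrix(NA_real_, n_lines, n_targets)
  n_valid <- matrix(0L, n_lines, n_targets)
  ok <- records$valid
  li <- records$line_index[ok]; ti <- records$target_index[ok]
  amp <- records$amplitude[ok]
  key <- (ti - 1L) * n_lines + li
  sums <- tapply(amp, key, sum)
  cnts <- tapply(amp, key, length)
  kk <- as.integer(names(sums))
  n_valid[kk] <- as.integer(cnts)
  mean_amp[kk] <- sums / cnts
  flagged <- n_valid == 0L
  if (any(flagged))
    warning(sprintf("%d site(s) with zero valid trials flagged and excluded",
                    sum(flagged)), call. = FALSE)
  structure(list(mean_amplitude = mean_amp, n_valid_trials = n_valid,
                 flagged = flagged),
            class = "excitability_map")
}

#' @export
print.excitability_map <- function(x, ...) {
  cat(sprintf("<excitability_map> %d x %d sites, peak mean %.3f mV, %d flagged\n",
              nrow(x$mean_amplitude), ncol(x$mean_amplitude),
              suppressWarnings(max(x$mean_amplitude, na.rm = TRUE)),
              sum(x$flagged)))
  invisible(x)
}

#' Locate the motor hotspot on an excitability map
#'
#' The hotspot is the unflagged site with the largest mean MEP amplitude.
#' Exact ties are broken towards the lower line index (more posterior), then
#' the lower target index (more medial), and reported via a message. The
#' shortest latency is the minimum valid per-trial latency among that site's
#' trials, restricted to the physiological 10-40 ms window.
#'
#' @param map an [build_map()] result.
#' @param grid the [build_grid()] the map was recorded on.
#' @param latencies optional data frame with columns `line_index`,
#'   `target_index`, `latency` (ms; one row per trial, `NA` allowed).
#' @return an object of class `hotspot`: list with `line_index`,
#'   `target_index`, `mean_amplitude`, `shortest_latency` (or `NA`),
#'   `position` and `y_coordinate`.
#' @export
find_hotspot <- function(map, grid, latencies = NULL) {
  stopifnot(inherits(map, "excitability_map"), inherits(grid, "stimulation_grid"))
  amp <- map$mean_amplitude
  amp[map$flagged] <- NA_real_
  if (all(is.na(amp)))
    knob_stop("all sites flagged: cannot localize a hotspot", "knobmap_analysis_error")
  best <- max(amp, na.rm = TRUE)
  # candidate sites, scanned line-major so ties resolve posterior/medial first
  cand <- which(!is.na(amp) & amp == best, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  if (nrow(cand) > 1)
    message(sprintf("hotspot tie across %d sites; keeping line %d, target %d",
                    nrow(cand), cand[1, 1], cand[1, 2]))
  li <- unname(cand[1, 1]); ti <- unname(cand[1, 2])
  shortest <- NA_real_
  if (!is.null(latencies)) {
    lat <- latencies$latency[latencies$line_index == li &
                             latencies$target_index == ti]
    lat <- lat[!is.na(lat) & lat >= 10 & lat <= 40]
    if (length(lat)) shortest <- min(lat)
  }
  pos <- grid_site_position(grid, li, ti)
  structure(list(line_index = li, target_index = ti,
                 mean_amplitude = best, shortest_latency = shortest,
                 position = pos, y_coordinate = unname(pos["y"])),
            class = "hotspot")
}

#' @export
print.hotspot <- function(x, ...) {
  cat(sprintf("<hotspot> line %d, target %d: %.3f mV, shortest latency %s ms, y = %.1f mm\n",
              x$line_index, x$target_index, x$mean_amplitude,
              ifelse(is.na(x$shortest_latency), "NA",
                     sprintf("%.2f", x$shortest_latency)), x$y_coordinate))
  invisible(x)
}

#' Resting motor threshold by adaptive maximum likelihood (PEST)
#'
#' Sequential threshold hunting: after every stimulus the threshold of a
#' fixed-slope logistic recruitment curve is refit by maximum likelihood over
#' a 1% MSO grid, and the next stimulus is delivered at the current ML
#' estimate. The responder is queried trial by trial, emulating the
#' experimenter observing whether the MEP exceeds the response criterion.
#'
#' @param responder a function of stimulus intensity (% MSO) returning either
#'   a logical (MEP present) or a numeric MEP amplitude in mV, which is then
#'   compared against `response_criterion`.
#' @param n_trials number of stimuli (default 20).
#' @param response_criterion amplitude criterion in mV (default 0.05), used
#'   when the responder returns numeric amplitudes.
#' @param slope logistic slope parameter in % MSO (default 2, fixed).
#' @param intensity_grid candidate thresholds in % MSO (default `1:100`).
#' @param start first stimulus intensity (default 50% MSO).
#' @return an object of class `rmt_estimate`: list with `threshold` (% MSO),
#'   `flagged_boundary` (`TRUE` when the estimate is pinned within one grid
#'   step of the grid edge, e.g. after an all-yes or all-no run),
#'   `intensities` and `responses`.
#' @examples
#' est <- estimate_rmt_pest(function(i) i >= 58)
#' est$threshold
#' @export
estimate_rmt_pest <- function(responder, n_trials = 20,
                              response_criterion = 0.05, slope = 2,
                              intensity_grid = 1:100, start = 50) {
  stopifnot(is.function(responder), n_trials >= 1, slope > 0)
  ll <- rep(0, length(intensity_grid))
  intensity <- start
  intensities <- numeric(n_trials)
  responses <- logical(n_trials)
  for (k in seq_len(n_trials)) {
    ans <- responder(intensity)
    yes <- if (is.logical(ans)) ans else ans >= response_criterion
    intensities[k] <- intensity
    responses[k] <- yes
    p <- stats::plogis((intensity - intensity_grid) / slope)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- ll + if (yes) log(p) else log(1 - p)
    intensity <- intensity_grid[which.max(ll)]
  }
  est <- intensity_grid[which.max(ll)]
  boundary <- est <= intensity_grid[1] + 1 ||
    est >= intensity_grid[length(intensity_grid)] - 1 ||
    all(responses) || !any(responses)
  structure(list(threshold = est, flagged_boundary = boundary,
                 intensities = intensities, responses = responses),
            class = "rmt_estimate")
}

#' @export
print.rmt_estimate <- function(x, ...) {
  cat(sprintf("<rmt_estimate> %d%% MSO after %d trials%s\n", x$threshold,
              length(x$responses),
              if (x$flagged_boundary) " [boundary estimate]" else ""))
  invisible(x)
}

#' Analyze one EMG mapping session
#'
#' Runs the full MEP chain on a simulated (or imported) session: artifact
#' rejection, per-trial peak-to-peak amplitude, the per-site excitability
#' map, hotspot localization, and per-trial onset latencies at the hotspot
#' site.
#'
#' @param session one muscle's session as produced by
#'   [simulate_emg_session()]: a list with `traces` (samples x trials
#'   matrix), `line_index`, `target_index` (per trial), `sampling_rate`,
#'   `stimulus_index`.
#' @param grid the [build_grid()] the session was recorded on.
#' @param baseline_rms_limit artifact-rejection limit in mV.
#' @param k_sd,sustain_ms latency-rule parameters, see [estimate_latency()].
#' @param window amplitude/latency window in ms.
#' @return list with `records` (per-trial data frame), `map`, `hotspot`.
#' @export
analyze_emg_session <- function(session, grid, baseline_rms_limit = 0.02,
                                k_sd = 3, sustain_ms = 0.5, window = c(10, 40)) {
  fs <- session$sampling_rate
  stim <- session$stimulus_index
  tr <- session$traces
  n_trials <- ncol(tr)
  pre <- (stim - round(0.100 * fs)):(stim - 1L)
  win <- (stim + round(window[1] * fs / 1000)):(stim + round(window[2] * fs / 1000))

  base_seg <- tr[pre, , drop = FALSE]
  rms <- sqrt(colMeans(base_seg^2))
  valid <- rms <= baseline_rms_limit
  seg <- tr[win, , drop = FALSE]
  amplitude <- apply(seg, 2, max) - apply(seg, 2, min)

  records <- data.frame(line_index = session$line_index,
                        target_index = session$target_index,
                        trial = seq_len(n_trials),
                        amplitude = amplitude, valid = valid)
  map <- build_map(records, n_lines = grid$n_lines, n_targets = grid$n_targets)

  # provisional hotspot from amplitudes, then latencies for its trials only
  hs0 <- find_hotspot(map, grid)
  at_hs <- which(records$line_index == hs0$line_index &
                 records$target_index == hs0$target_index & valid)
  bm <- colMeans(base_seg[, at_hs, drop = FALSE])
  bs <- apply(base_seg[, at_hs, drop = FALSE], 2, stats::sd)
  lat <- vapply(seq_along(at_hs), function(j)
    latency_from_signal(seg[, at_hs[j]], bm[j], bs[j], t0_ms = window[1],
                        fs = fs, k_sd = k_sd, sustain_ms = sustain_ms),
    numeric(1))
  lat_df <- data.frame(line_index = records$line_index[at_hs],
                       target_index = records$target_index[at_hs],
                       latency = lat)
  hotspot <- find_hotspot(map, grid, lat_df)
  list(records = records, map = map, hotspot = hotspot)
}
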