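# EMG-level simulation: stimulus-locked traces for every grid site.

# biphasic MEP template: Hanning-windowed sine, `duration_ms` long, scaled
# to unit peak-to-peak amplitude on the discrete sample grid (so that the
# extracted peak-to-peak amplitude of a noise-free trial equals the target
# amplitude exactly)
mep_template <- function(fs = 10000, duration_ms = 8) {
  tt <- seq(0, duration_ms / 1000, by = 1 / fs)
  w <- sin(2 * pi * tt * 1000 / duration_ms) *
    0.5 * (1 - cos(2 * pi * tt * 1000 / duration_ms))
  w / (max(w) - min(w))
}

#' Simulate one sulcus-aligned EMG mapping session
#'
#' Generates stimulus-locked EMG traces (-100..+60 ms around the pulse,
#' 10 kHz) for `trials_per_site` stimuli at each of the 35 grid sites, for
#' one or both hand muscles. The expected per-site amplitude follows an
#' isotropic 2D Gaussian bump of width `spatial_sigma` centred on the
#' subject's true hotspot; trial amplitudes are lognormal around the site
#' mean (`trial_amp_cv`), the MEP onset is the subject's corticomotor
#' latency plus Normal(0, `latency_jitter_sd`) trial jitter, the waveform is
#' a biphasic Hanning-windowed 8 ms sine, and white Gaussian background
#' noise of SD `emg_noise_sd` is added. With `artifact_rate > 0` a random
#' subset of trials receives strong baseline contamination (so the artifact
#' screen has something to catch).
#'
#' @param subject a [simulate_subject()] result.
#' @param grid a [build_grid()] stimulation grid (35 sites by default).
#' @param config a [generator_config()].
#' @param muscles which muscles to simulate, subset of `c("FDI", "ADM")`.
#' @param seed optional substream-seed override.
#' @return an object of class `emg_session`: a named list (one entry per
#'   muscle) of lists with `traces` (samples x trials matrix, mV),
#'   `line_index`, `target_index`, `trial`, `onset_ms` and `amplitude_true`
#'   (ground truth per trial), `site_surface` (true 5 x 7 amplitude
#'   surface), `sampling_rate`, `stimulus_index`, `muscle`.
#' @export
simulate_emg_session <- function(subject, grid, config,
                                 muscles = c("FDI", "ADM"), seed = NULL) {
  stopifnot(inherits(subject, "synthetic_subject"),
            inherits(grid, "stimulation_grid"),
            inherits(config, "generator_config"))
  muscles <- match.arg(muscles, several.ok = TRUE)
  if (is.null(seed))
    seed <- substream_seed(config$seed, "emg", subject$subject_id)
  set.seed(seed)

  fs <- 10000
  n_pre <- 1000L                        # -100..0 ms
  n_post <- 600L                        # 0..+60 ms
  n_samp <- n_pre + n_post + 1L
  stim_idx <- n_pre + 1L
  tpl <- mep_template(fs)
  cf <- config

  out <- list()
  for (m in muscles) {
    hx <- if (m == "FDI") subject$true_hotspot_x else subject$adm_hotspot_x
    hy <- if (m == "FDI") subject$true_hotspot_y else subject$adm_hotspot_y
    amp0 <- if (m == "FDI") subject$amp_fdi else subject$amp_adm
    lat0 <- if (m == "FDI") subject$true_latency else subject$adm_latency

    d2 <- (grid$sites$x - hx)^2 + (grid$sites$y - hy)^2
    site_mean <- amp0 * exp(-d2 / (2 * cf$spatial_sigma^2))

    npt <- cf$trials_per_site
    n_trials <- nrow(grid$sites) * npt
    line_index <- rep(grid$sites$line_index, each = npt)
    target_index <- rep(grid$sites$target_index, each = npt)
    mu <- rep(site_mean, each = npt)

    amp <- if (cf$trial_amp_cv > 0) {
      lp <- lognorm_pars(1, cf$trial_amp_cv)
      mu * stats::rlnorm(n_trials, lp$meanlog, lp$sdlog)
    } else mu
    onset <- lat0 + cf$latency_jitter_sd * stats::rnorm(n_trials)

    traces <- if (cf$emg_noise_sd > 0)
      matrix(stats::rnorm(n_samp * n_trials, sd = cf$emg_noise_sd),
             n_samp, n_trials)
    else matrix(0, n_samp, n_trials)

    on_idx <- stim_idx + as.integer(round(onset * fs / 1000))
    ntpl <- length(tpl)
    for (j in seq_len(n_trials)) {
      i0 <- on_idx[j]
      i1 <- min(i0 + ntpl - 1L, n_samp)
      if (i0 >= 1L && i0 <= n_samp)
        traces[i0:i1, j] <- traces[i0:i1, j] + amp[j] * tpl[seq_len(i1 - i0 + 1L)]
    }

    if (cf$artifact_rate > 0) {
      bad <- which(stats::runif(n_trials) < cf$artifact_rate)
      if (length(bad))
        traces[seq_len(n_pre), bad] <- traces[seq_len(n_pre), bad] +
          stats::rnorm(n_pre * length(bad), sd = 0.2)
    }

    surface <- matrix(NA_real_, grid$n_lines, grid$n_targets)
    surface[cbind(grid$sites$line_index, grid$sites$target_index)] <- site_mean

    out[[m]] <- list(traces = traces, line_index = line_index,
                     target_index = target_index,
                     trial = rep(seq_len(npt), times = nrow(grid$sites)),
                     onset_ms = onset, amplitude_true = amp,
                     site_surface = surface, sampling_rate = fs,
                     stimulus_index = stim_idx, muscle = m)
  }
  structure(out, class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  for (m in names(x))
    cat(sprintf("<emg_session> %s: %d trials x %d samples at %g kHz\n",
                m, ncol(x[[m]]$traces), nrow(x[[m]]$traces),
                x[[m]]$sampling_rate / 1000))
  invisible(x)
}

#' Extract one trial as an [emg_trace()]
#'
#' @param session_muscle one muscle's entry of an `emg_session`.
#' @param trial column index of the trial.
#' @return an `emg_trace`.
#' @export
session_trace <- function(session_muscle, trial) {
  emg_trace(session_muscle$traces[, trial],
            sampling_rate = session_muscle$sampling_rate,
            stimulus_index = session_muscle$stimulus_index,
            muscle = session_muscle$muscle)
}
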