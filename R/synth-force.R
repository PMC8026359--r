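# Force-trace simulation for the 1 Hz paced visuomotor synchronization task.

#' Simulate a force trace from the paced finger-abduction task
#'
#' Emulates the strain-gauge recording: movement blocks of
#' `cues_per_block` visual cues at `cue_interval` seconds, separated by rest
#' gaps. Each cue triggers one raised-cosine force pulse whose centre is
#' jittered by Normal(0, `cv_target / sqrt(2)`) seconds, so that the
#' coefficient of variation of the intermovement interval is approximately
#' `cv_target` (the difference of two independent jitters has SD
#' `sqrt(2) * sigma`). Pulse amplitudes are drawn from
#' Normal(`pulse_amp_mean`, `pulse_amp_sd`), floored at 0.8 V so every
#' movement clears the detection threshold, and the summed trace is clipped
#' at the sensor ceiling `clip_level` — saturated pulses show the flat tops
#' seen in real recordings.
#'
#' @param cv_target target intermovement-interval CV (>= 0).
#' @param config a [generator_config()] (task-structure and pulse fields).
#' @param seed optional seed (integer); when `NULL` the current RNG state is
#'   used.
#' @param n_blocks number of movement blocks (default
#'   `config$n_move_blocks`).
#' @return a [force_trace()] with cue times and block boundaries attached.
#' @examples
#' tr <- simulate_force_trace(0.05, generator_config(), seed = 1, n_blocks = 2)
#' max(tr$samples) <= 2.5
#' @export
simulate_force_trace <- function(cv_target, config, seed = NULL,
                                 n_blocks = config$n_move_blocks) {
  stopifnot(inherits(config, "generator_config"))
  if (!is_scalar_number(cv_target) || cv_target < 0)
    knob_stop("cv_target must be a single number >= 0", "knobmap_input_error")
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  fs <- 500

  block_len <- cf$cues_per_block * cf$cue_interval
  block_start <- 1 + (seq_len(n_blocks) - 1) * (block_len + cf$rest_duration)
  cue_times <- as.vector(vapply(block_start, function(s)
    s + (seq_len(cf$cues_per_block) - 1) * cf$cue_interval,
    numeric(cf$cues_per_block)))

  sigma <- cv_target / sqrt(2)
  centers <- cue_times + if (sigma > 0)
    stats::rnorm(length(cue_times), sd = sigma) else 0
  amps <- rep(cf$pulse_amp_mean, length(cue_times)) + if (cf$pulse_amp_sd > 0)
    stats::rnorm(length(cue_times), sd = cf$pulse_amp_sd) else 0
  # floor keeps every movement above the 0.6 V detection threshold and the
  # worst-case prominence floor (clip_level / 3): detection misses would put
  # spurious 2 s intervals into the CV
  amps <- pmax(amps, 0.9)

  total <- max(cue_times) + 2
  n <- as.integer(ceiling(total * fs))
  x <- numeric(n)
  half <- cf$pulse_width / 2
  for (j in seq_along(centers)) {
    i0 <- max(1L, as.integer(floor((centers[j] - half) * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling((centers[j] + half) * fs)) + 1L)
    tt <- (seq(i0, i1) - 1) / fs
    inside <- abs(tt - centers[j]) <= half
    x[i0:i1][inside] <- x[i0:i1][inside] +
      amps[j] * 0.5 * (1 + cos(pi * (tt[inside] - centers[j]) / half))
  }
  if (cf$force_noise_sd > 0) x <- x + stats::rnorm(n, sd = cf$force_noise_sd)
  x <- pmin(pmax(x, 0), cf$clip_level)

  blocks <- data.frame(start = block_start - 0.5,
                       end = block_start + block_len - cf$cue_interval + 0.5)
  force_trace(x, sampling_rate = fs, cue_times = cue_times, blocks = blocks)
}
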