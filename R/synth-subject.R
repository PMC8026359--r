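# Subject-level generation: one latent myelin trait drives every structural
# and functional readout.

#' Simulate one subject
#'
#' Draws a `synthetic_subject` from the latent-trait model. A standard-normal
#' myelin trait `z1` determines both regional R1 values exactly
#' (`roi_r1 = mean + sd * z1`, preserving the caudal > rostral gradient);
#' correlated readouts are generated as `rho * z1 + sqrt(1 - rho^2) * eps`.
#' The hotspot y-coordinate follows the rostrality driver, and the shortest
#' MEP latency follows the y-coordinate linearly with independent residual
#' noise, so that spatially rostral hotspots come with longer corticomotor
#' latencies. The little-finger (ADM) hotspot tracks the index-finger (FDI)
#' one with a small muscle-specific y offset and a medial x shift.
#'
#' All draws happen in a fixed order on a subject-specific substream
#' ([substream_seed()]), so a subject is reproducible independently of
#' cohort size.
#'
#' @param config a [generator_config()].
#' @param subject_id integer id (>= 1).
#' @param seed optional override of the substream seed.
#' @return an object of class `synthetic_subject`.
#' @examples
#' s <- simulate_subject(generator_config(), subject_id = 1)
#' s$roi_r1_caudal > s$roi_r1_rostral
#' @export
simulate_subject <- function(config, subject_id = 1, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) seed <- substream_seed(config$seed, "subject", subject_id)
  set.seed(seed)
  cf <- config

  z1 <- stats::rnorm(1)
  mix <- function(rho) rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)

  # subject-specific caudal-rostral R1 gradient variation; splits +/- so it
  # cancels exactly in the whole-knob mean R1
  r1_grad <- cf$r1_gradient_sd * stats::rnorm(1)

  z_rost <- mix(cf$rho_r1_rostrality)
  true_hotspot_y <- cf$y_mean + cf$y_sd * z_rost
  true_latency <- cf$latency_intercept +
    cf$latency_slope * (true_hotspot_y - cf$y_mean) +
    cf$latency_resid_sd * stats::rnorm(1)

  adm_hotspot_y <- true_hotspot_y + cf$muscle_y_jitter_sd * stats::rnorm(1)
  adm_latency <- cf$latency_intercept_adm +
    cf$latency_slope * (adm_hotspot_y - cf$y_mean) +
    cf$latency_resid_sd * stats::rnorm(1)

  hotspot_x <- cf$hotspot_x_mean + cf$hotspot_x_sd * stats::rnorm(1)
  adm_hotspot_x <- hotspot_x + cf$adm_x_offset + stats::rnorm(1)

  lp_f <- lognorm_pars(cf$mep_amp_mean_fdi, max(cf$mep_amp_between_cv, 1e-12))
  lp_a <- lognorm_pars(cf$mep_amp_mean_adm, max(cf$mep_amp_between_cv, 1e-12))
  amp_fdi <- if (cf$mep_amp_between_cv > 0)
    stats::rlnorm(1, lp_f$meanlog, lp_f$sdlog) else cf$mep_amp_mean_fdi
  amp_adm <- if (cf$mep_amp_between_cv > 0)
    stats::rlnorm(1, lp_a$meanlog, lp_a$sdlog) else cf$mep_amp_mean_adm

  bold_little <- cf$bold_mean + cf$bold_between_sd * mix(cf$rho_r1_bold)
  bold_index <- cf$bold_mean + cf$bold_between_sd * mix(cf$rho_r1_bold_index)
  zb <- mix(cf$rho_r1_bold)
  bold_caudal <- cf$bold_caudal_mean +
    cf$bold_caudal_sd * (0.9 * zb + sqrt(1 - 0.81) * stats::rnorm(1))
  bold_rostral <- cf$bold_rostral_mean +
    cf$bold_rostral_sd * (0.9 * zb + sqrt(1 - 0.81) * stats::rnorm(1))

  cv_little <- max(cf$cv_floor,
                   cf$cv_mean + cf$cv_between_sd * mix(cf$rho_r1_cv))
  cv_index <- max(cf$cv_floor,
                  cf$cv_mean + cf$cv_between_sd * mix(cf$rho_r1_cv_index))

  z_th <- stats::rnorm(1)
  thickness_caudal <- cf$thickness_caudal_mean +
    cf$thickness_caudal_sd * (0.7 * z_th + sqrt(0.51) * stats::rnorm(1))
  thickness_rostral <- cf$thickness_rostral_mean +
    cf$thickness_rostral_sd * (0.7 * z_th + sqrt(0.51) * stats::rnorm(1))
  z_cu <- stats::rnorm(1)
  curvature_caudal <- cf$curvature_caudal_mean +
    cf$curvature_sd * (0.97 * z_cu + sqrt(1 - 0.9409) * stats::rnorm(1))
  curvature_rostral <- cf$curvature_rostral_mean +
    cf$curvature_sd * (0.97 * z_cu + sqrt(1 - 0.9409) * stats::rnorm(1))

  rmt_true <- min(max(cf$rmt_mean + cf$rmt_between_sd * stats::rnorm(1), 25), 90)

  structure(list(
    subject_id = subject_id,
    latent_myelin = z1,
    roi_r1_caudal = cf$r1_caudal_mean + cf$r1_between_sd * z1 + r1_grad / 2,
    roi_r1_rostral = cf$r1_rostral_mean + cf$r1_between_sd * z1 - r1_grad / 2,
    true_hotspot_x = hotspot_x,
    true_hotspot_y = true_hotspot_y,
    true_latency = true_latency,
    adm_hotspot_x = adm_hotspot_x,
    adm_hotspot_y = adm_hotspot_y,
    adm_latency = adm_latency,
    amp_fdi = amp_fdi,
    amp_adm = amp_adm,
    thickness_caudal = thickness_caudal,
    thickness_rostral = thickness_rostral,
    curvature_caudal = curvature_caudal,
    curvature_rostral = curvature_rostral,
    bold_index = bold_index,
    bold_little = bold_little,
    bold_caudal = bold_caudal,
    bold_rostral = bold_rostral,
    cv_index = cv_index,
    cv_little = cv_little,
    rmt_true = rmt_true
  ), class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject %d> z1 = %.2f, R1 %.1f/%.1f, hotspot y = %.1f mm, latency %.1f ms\n",
              x$subject_id, x$latent_myelin, x$roi_r1_caudal,
              x$roi_r1_rostral, x$true_hotspot_y, x$true_latency))
  invisible(x)
}
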