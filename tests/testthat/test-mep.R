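test_that("baseline RMS screening separates clean and contaminated trials", {
  flat <- emg_trace(numeric(1601), 10000, 1001, "FDI")
  expect_true(reject_artifact_trial(flat))

  contaminated <- emg_trace(c(rep(0.05, 1000), numeric(601)), 10000, 1001, "FDI")
  expect_false(reject_artifact_trial(contaminated)) # RMS of a constant = 0.05

  expect_error(emg_trace(numeric(700), 10000, 650, "FDI"), "-100")
})

test_that("clean baseline noise is almost never rejected at the default limit", {
  set.seed(41)
  n_rep <- 5000
  rejected <- 0L
  for (k in seq_len(n_rep)) {
    tr <- emg_trace(rnorm(1601, sd = 0.01), 10000, 1001, "FDI")
    if (!reject_artifact_trial(tr)) rejected <- rejected + 1L
  }
  # RMS of ~1000 samples at SD 0.01 concentrates far below the 0.02 limit
  expect_lt(rejected / n_rep, 0.01)
})

test_that("peak-to-peak amplitude is max minus min in the 10-40 ms window", {
  x <- numeric(1601)
  x[1001 + 150] <- 0.8   # +15 ms
  x[1001 + 300] <- -0.4  # +30 ms
  tr <- emg_trace(x, 10000, 1001, "FDI")
  expect_equal(extract_amplitude(tr), 1.2)

  expect_equal(extract_amplitude(emg_trace(numeric(1601), 10000, 1001, "FDI")), 0)

  # generator round trip: template scaled to 1.0 mV peak-to-peak
  expect_equal(extract_amplitude(emg_with_mep(amp = 1)), 1, tolerance = 1e-3)
})

test_that("amplitude extraction is offset-invariant and scale-equivariant", {
  set.seed(5)
  for (k in 1:20) {
    tr <- emg_with_mep(amp = runif(1, 0.2, 2), onset_ms = runif(1, 15, 30),
                       noise_sd = 0.01)
    a0 <- extract_amplitude(tr)
    shifted <- tr; shifted$samples <- tr$samples + 0.37
    expect_equal(extract_amplitude(shifted), a0, tolerance = 1e-12)
    scaled <- tr; scaled$samples <- tr$samples * 2.5
    expect_equal(extract_amplitude(scaled), 2.5 * a0, tolerance = 1e-12)
  }
})

test_that("latency detection finds the template onset", {
  # noise-free: first deflecting sample is one sample after the nominal onset
  est <- estimate_latency(emg_with_mep(amp = 1, onset_ms = 22.6))
  expect_lte(abs(est - 22.6), 0.1 + 1e-9)

  expect_true(is.na(estimate_latency(emg_trace(numeric(1601), 10000, 1001, "FDI"))))
})

test_that("latency errors are a stable small detection delay, not noise", {
  set.seed(7)
  errs <- replicate(300, {
    onset <- runif(1, 18, 28)
    est <- estimate_latency(emg_with_mep(amp = 1, onset_ms = onset,
                                         noise_sd = 0.01))
    est - onset
  })
  # the sustained-crossing rule fires once the 8 ms biphasic template clears
  # 3 x baseline SD: a sub-millisecond systematic delay with high precision
  expect_gt(stats::median(errs), 0.3)
  expect_lt(stats::median(errs), 1.1)
  expect_lt(stats::sd(errs), 0.3)
})

test_that("latency estimates never leave the physiological window", {
  set.seed(8)
  for (k in 1:50) {
    tr <- emg_with_mep(amp = runif(1, 0.05, 2), onset_ms = runif(1, 5, 45),
                       noise_sd = 0.02)
    est <- estimate_latency(tr)
    expect_true(is.na(est) || (est >= 10 && est <= 40))
  }
})

test_that("excitability maps average valid trials per site", {
  rec <- data.frame(line_index = 3, target_index = 4,
                    amplitude = rep(1, 20), valid = TRUE)
  expect_warning(m <- build_map(rec), "flagged")
  expect_equal(m$mean_amplitude[3, 4], 1)
  expect_equal(m$n_valid_trials[3, 4], 20L)

  rec2 <- data.frame(line_index = 1, target_index = 1,
                     amplitude = c(0.5, 1.5), valid = TRUE)
  expect_warning(m2 <- build_map(rec2), "flagged")
  expect_equal(m2$mean_amplitude[1, 1], 1)
  expect_true(all(m2$flagged[-1]))
})

test_that("a noise-free session reproduces the generating Gaussian surface", {
  cfg <- generator_config(emg_noise_sd = 0, trial_amp_cv = 0, trials_per_site = 2)
  g <- default_grid(cfg)
  s <- simulate_subject(cfg, 1)
  ses <- simulate_emg_session(s, g, cfg, muscles = "FDI")
  ana <- analyze_emg_session(ses$FDI, g)
  expect_equal(ana$map$mean_amplitude, ses$FDI$site_surface, tolerance = 1e-9)
})

test_that("map means equal a brute-force per-site average", {
  cfg <- generator_config(trials_per_site = 5)
  g <- default_grid(cfg)
  ses <- simulate_emg_session(simulate_subject(cfg, 2), g, cfg, muscles = "FDI")
  ana <- analyze_emg_session(ses$FDI, g)
  rec <- ana$records
  for (k in sample(35, 10)) {
    li <- g$sites$line_index[k]; ti <- g$sites$target_index[k]
    sel <- rec$line_index == li & rec$target_index == ti & rec$valid
    expect_equal(ana$map$mean_amplitude[li, ti], mean(rec$amplitude[sel]))
  }
})

test_that("hotspot localization picks the map maximum with documented tie-breaks", {
  g <- build_grid(straight_curve())
  amp <- matrix(0, 5, 7); amp[3, 4] <- 1.2
  m <- structure(list(mean_amplitude = amp, n_valid_trials = matrix(20L, 5, 7),
                      flagged = matrix(FALSE, 5, 7)), class = "excitability_map")
  hs <- find_hotspot(m, g)
  expect_equal(c(hs$line_index, hs$target_index), c(3, 4))
  expect_equal(hs$mean_amplitude, 1.2)
  expect_equal(hs$y_coordinate, 10)

  amp2 <- amp; amp2[2, 6] <- 1.2
  m2 <- m; m2$mean_amplitude <- amp2
  expect_message(hs2 <- find_hotspot(m2, g), "tie")
  expect_equal(c(hs2$line_index, hs2$target_index), c(2, 6))

  m3 <- m; m3$flagged <- matrix(TRUE, 5, 7)
  expect_error(find_hotspot(m3, g), "flagged")
})

test_that("shortest latency at the hotspot is the minimum valid trial latency", {
  g <- build_grid(straight_curve())
  amp <- matrix(0.1, 5, 7); amp[2, 2] <- 2
  m <- structure(list(mean_amplitude = amp, n_valid_trials = matrix(20L, 5, 7),
                      flagged = matrix(FALSE, 5, 7)), class = "excitability_map")
  lat <- data.frame(line_index = 2, target_index = 2,
                    latency = c(23.4, 21.9, NA, 55, 22.8))
  hs <- find_hotspot(m, g, lat)
  expect_equal(hs$shortest_latency, 21.9) # NA and out-of-window excluded
})

test_that("hotspot is invariant under uniform positive rescaling of trials", {
  cfg <- generator_config(trials_per_site = 5)
  g <- default_grid(cfg)
  ses <- simulate_emg_session(simulate_subject(cfg, 3), g, cfg, muscles = "FDI")
  ana <- analyze_emg_session(ses$FDI, g)
  rec <- ana$records
  rec$amplitude <- rec$amplitude * 3.7
  m <- suppressWarnings(build_map(rec))
  hs <- find_hotspot(m, g)
  expect_equal(c(hs$line_index, hs$target_index),
               c(ana$hotspot$line_index, ana$hotspot$target_index))
})

test_that("adaptive ML threshold hunting converges on the recruitment threshold", {
  det <- estimate_rmt_pest(function(i) i >= 58)
  expect_lte(abs(det$threshold - 58), 1)
  expect_false(det$flagged_boundary)

  edge <- estimate_rmt_pest(function(i) i >= 100)
  expect_true(edge$flagged_boundary)

  all_no <- estimate_rmt_pest(function(i) FALSE)
  expect_true(all_no$flagged_boundary)
  expect_equal(all_no$threshold, 100)

  # numeric responders are compared against the MEP criterion
  num <- estimate_rmt_pest(function(i) ifelse(i >= 58, 0.2, 0.01))
  expect_lte(abs(num$threshold - 58), 1)
})

test_that("threshold estimation is accurate for a stochastic logistic responder", {
  set.seed(10)
  errs <- replicate(200, {
    est <- estimate_rmt_pest(function(i) runif(1) < plogis((i - 58) / 2))
    abs(est$threshold - 58)
  })
  expect_lte(mean(errs), 2)
})
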