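# Shared fixtures and independent oracles. Oracles are deliberately naive
# (brute-force, closed-form) and share no code with the implementation.

straight_curve <- function(len = 30, by = 5, y = 0, z = 0) {
  sulcus_curve(cbind(seq(0, len, by = by), y, z))
}

# circular arc of radius r in the x-y plane, theta in [0, theta_max] rad,
# densely sampled; tangent stays well away from the anterior (+y) axis for
# theta_max < pi/2, and r is large relative to the grid's anterior offsets
# so that offset lines keep a healthy curvature radius
arc_curve <- function(r = 60, theta_max = 0.5, n = 500) {
  th <- seq(0, theta_max, length.out = n)
  sulcus_curve(cbind(r * sin(th), -r * cos(th), 0))
}

# brute-force Pearson r and p from the textbook formulas
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# brute-force Welch t from the definition
oracle_welch <- function(a, b) {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, dof = dof, p = 2 * stats::pt(-abs(t), dof))
}

# exhaustive peak detector: checks every sample against the definitions,
# with no shortcuts (quadratic; for small test traces only)
oracle_detect_peaks <- function(x, fs, threshold = 0.6, min_distance = 0.4,
                                prominence_fraction = 1 / 3) {
  n <- length(x)
  # plateau-aware local maxima
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1L
      if (j < n && x[j + 1] < x[i]) cand <- c(cand, i + (j - i) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  cand <- cand[x[cand] >= threshold]
  keep <- logical(length(cand))
  for (ci in seq_along(cand)) {
    p <- cand[ci]; h <- x[p]
    l <- p
    while (l > 1 && x[l - 1] <= h) l <- l - 1L
    lmin <- min(x[l:p])
    rgt <- p
    while (rgt < n && x[rgt + 1] <= h) rgt <- rgt + 1L
    rmin <- min(x[p:rgt])
    keep[ci] <- (h - max(lmin, rmin)) >= prominence_fraction * max(x)
  }
  cand <- cand[keep]
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= min_distance * fs))
      kept <- c(kept, p)
  sort(kept - 1L) / fs
}

# random bumpy test signal for detector equivalence checks
random_force_signal <- function(n = 1500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- stats::filter(rnorm(n, sd = 0.5), rep(1 / 25, 25), circular = TRUE)
  x <- pmax(as.numeric(base), 0)
  n_pulse <- sample(3:8, 1)
  for (k in seq_len(n_pulse)) {
    c0 <- sample(seq(50, n - 50), 1)
    w <- sample(30:90, 1)
    a <- runif(1, 0.5, 3)
    idx <- max(1, c0 - w):min(n, c0 + w)
    x[idx] <- x[idx] + a * 0.5 * (1 + cos(pi * (idx - c0) / w))
  }
  pmin(x, 2.5)
}

# single-trial synthetic EMG trace with the package's MEP template
emg_with_mep <- function(amp = 1, onset_ms = 22.6, noise_sd = 0,
                         n_pre = 1000, n_post = 600, fs = 10000) {
  n <- n_pre + n_post + 1
  x <- if (noise_sd > 0) rnorm(n, sd = noise_sd) else numeric(n)
  tpl <- knobmap:::mep_template(fs)
  i0 <- n_pre + 1 + round(onset_ms * fs / 1000)
  i1 <- min(i0 + length(tpl) - 1, n)
  x[i0:i1] <- x[i0:i1] + amp * tpl[seq_len(i1 - i0 + 1)]
  emg_trace(x, sampling_rate = fs, stimulus_index = n_pre + 1, muscle = "FDI")
}
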