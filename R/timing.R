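# Movement-timing analysis of force traces from the 1 Hz paced visuomotor
# synchronization task: peak detection with topographic prominence, and the
# coefficient of variation of the intermovement interval.

#' Force trace container
#'
#' @param samples numeric vector, sensor voltage (0-2.5 V range).
#' @param sampling_rate Hz (default 500).
#' @param cue_times cue onsets in seconds (optional).
#' @param blocks optional data frame with `start`, `end` (s) delimiting
#'   movement blocks; intervals are never computed across block boundaries.
#' @return an object of class `force_trace`.
#' @export
force_trace <- function(samples, sampling_rate = 500, cue_times = numeric(0),
                        blocks = NULL) {
  if (!is.numeric(samples) || length(samples) == 0 || anyNA(samples))
    knob_stop("samples must be non-empty finite numeric", "knobmap_input_error")
  if (!is.null(blocks) && !all(c("start", "end") %in% names(blocks)))
    knob_stop("blocks needs columns start, end", "knobmap_input_error")
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate,
                 cue_times = cue_times, blocks = blocks),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %.1f s at %g Hz, max %.2f V, %d cues\n",
              length(x$samples) / x$sampling_rate, x$sampling_rate,
              max(x$samples), length(x$cue_times)))
  invisible(x)
}

# candidate local maxima with plateau handling: a run of equal values is a
# peak when both neighbouring runs are lower; a saturated (clipped) plateau
# is assigned its midpoint as peak time.
local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_peak <- c(FALSE, r$values[2:(k - 1)] > r$values[1:(k - 2)] &
                      r$values[2:(k - 1)] > r$values[3:k], FALSE)
  j <- which(is_peak)
  starts[j] + (r$lengths[j] - 1L) %/% 2L
}

# topographic prominence of peak at index p: extend left/right to the nearest
# sample higher than x[p] (or the trace edge), take the minimum on each side;
# the reference level is the higher of the two minima.
peak_prominence <- function(x, p) {
  h <- x[p]
  left <- if (p > 1) x[1:(p - 1)] else numeric(0)
  hi <- which(left > h)
  lmin <- if (length(left)) min(x[(if (length(hi)) max(hi) + 1L else 1L):p]) else h
  right <- if (p < length(x)) x[(p + 1):length(x)] else numeric(0)
  hi <- which(right > h)
  rmin <- if (length(right))
    min(x[p:(p + (if (length(hi)) min(hi) - 1L else length(right)))]) else h
  h - max(lmin, rmin)
}

# prominences of all candidate peaks at once. Equivalent to peak_prominence()
# but O(n + k^2) instead of O(n k): between consecutive candidates only the
# valley minimum ("col") matters, so each peak walks over candidate cols
# until it meets a strictly higher candidate or the trace edge.
peak_prominence_all <- function(x, cand) {
  k <- length(cand)
  if (!k) return(numeric(0))
  h <- x[cand]
  n <- length(x)
  cols <- if (k > 1)
    vapply(seq_len(k - 1), function(i) min(x[cand[i]:cand[i + 1]]), numeric(1))
  else numeric(0)
  head_min <- min(x[1:cand[1]])
  tail_min <- min(x[cand[k]:n])
  prom <- numeric(k)
  for (i in seq_len(k)) {
    lmin <- h[i]
    j <- i - 1L
    repeat {
      if (j < 1L) { lmin <- min(lmin, head_min); break }
      lmin <- min(lmin, cols[j])
      if (h[j] > h[i]) break
      j <- j - 1L
    }
    rmin <- h[i]
    j <- i
    repeat {
      if (j >= k) { rmin <- min(rmin, tail_min); break }
      rmin <- min(rmin, cols[j])
      if (h[j + 1L] > h[i]) break
      j <- j + 1L
    }
    prom[i] <- h[i] - max(lmin, rmin)
  }
  prom
}

#' Detect movement peaks in a force trace
#'
#' Local maxima of the force signal that (i) reach at least `threshold`
#' volts, (ii) have a topographic prominence of at least
#' `prominence_fraction` times the trace maximum (the maximum force the
#' subject exerted in that run), and (iii) are separated by at least
#' `min_distance` seconds; when two candidates are closer, the higher one is
#' retained. Saturated plateaus (force clipped at the sensor ceiling) are
#' assigned their plateau midpoint as peak time.
#'
#' @param trace a [force_trace()] (or numeric vector, then `sampling_rate`
#'   must be given).
#' @param threshold minimum peak height in V (default 0.6).
#' @param min_distance minimum peak separation in s (default 0.4).
#' @param prominence_fraction prominence floor as a fraction of the trace
#'   maximum (default 1/3).
#' @param sampling_rate Hz, used when `trace` is a bare numeric vector.
#' @return numeric vector of peak times in seconds (time of sample 1 is 0);
#'   empty, with a warning, when nothing crosses the threshold.
#' @export
detect_peaks <- function(trace, threshold = 0.6, min_distance = 0.4,
                         prominence_fraction = 1 / 3, sampling_rate = 500) {
  if (inherits(trace, "force_trace")) {
    x <- trace$samples
    fs <- trace$sampling_rate
  } else {
    x <- as.numeric(trace)
    fs <- sampling_rate
  }
  if (!length(x))
    knob_stop("empty trace", "knobmap_input_error")
  cand <- local_maxima(x)
  cand <- cand[x[cand] >= threshold]
  if (!length(cand)) {
    warning("no peaks above threshold", call. = FALSE)
    return(numeric(0))
  }
  prom_floor <- prominence_fraction * max(x)
  cand <- cand[peak_prominence_all(x, cand) >= prom_floor]
  if (!length(cand)) {
    warning("no peaks above threshold", call. = FALSE)
    return(numeric(0))
  }
  # min-distance: visit candidates from highest to lowest (earlier wins ties),
  # keep each one only if no already-kept peak lies within min_distance
  ord <- cand[order(-x[cand], cand)]
  min_sep <- min_distance * fs
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  sort((kept - 1L)) / fs
}

#' Intermovement intervals and their coefficient of variation
#'
#' Successive differences of the detected peak times, pooled within movement
#' blocks (intervals spanning a block boundary are discarded: they would be
#' dominated by the rest period, not by tapping variability). The SD is the
#' sample SD (n - 1 denominator) and CV = SD / mean.
#'
#' @param peak_times numeric vector of peak times in s (sorted).
#' @param blocks optional data frame with `start`, `end` (s); when `NULL`,
#'   all intervals are used.
#' @return an object of class `timing_result`: list with `peak_times`,
#'   `intervals`, `mean_interval`, `sd_interval`, `cv`, and `flagged`
#'   (`TRUE`, with `NA` statistics, when fewer than 2 intervals remain).
#' @examples
#' interval_cv(c(1, 1.9, 3, 4.1))$cv
#' @export
interval_cv <- function(peak_times, blocks = NULL) {
  pt <- sort(as.numeric(peak_times))
  if (is.null(blocks)) {
    intervals <- diff(pt)
  } else {
    intervals <- unlist(lapply(seq_len(nrow(blocks)), function(b) {
      diff(pt[pt >= blocks$start[b] & pt <= blocks$end[b]])
    }), use.names = FALSE)
  }
  if (length(intervals) < 2) {
    return(structure(list(peak_times = pt, intervals = intervals,
                          mean_interval = NA_real_, sd_interval = NA_real_,
                          cv = NA_real_, flagged = TRUE),
                     class = "timing_result"))
  }
  m <- mean(intervals)
  s <- stats::sd(intervals)
  structure(list(peak_times = pt, intervals = intervals,
                 mean_interval = m, sd_interval = s, cv = s / m,
                 flagged = FALSE),
            class = "timing_result")
}

#' @export
print.timing_result <- function(x, ...) {
  if (x$flagged) cat("<timing_result> flagged: fewer than 2 intervals\n")
  else cat(sprintf("<timing_result> %d intervals, mean %.3f s, SD %.3f s, CV %.4f\n",
                   length(x$intervals), x$mean_interval, x$sd_interval, x$cv))
  invisible(x)
}

#' Peak detection + interval CV in one call
#'
#' @param trace a [force_trace()]; block boundaries stored on the trace are
#'   used for the interval computation.
#' @param ... passed to [detect_peaks()].
#' @return a `timing_result`, see [interval_cv()].
#' @export
analyze_force_trace <- function(trace, ...) {
  stopifnot(inherits(trace, "force_trace"))
  pk <- detect_peaks(trace, ...)
  interval_cv(pk, blocks = trace$blocks)
}
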