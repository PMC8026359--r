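# Spatiotemporal hotspot rostrality: per-subject, per-muscle composite of
# hotspot position and corticomotor latency, plus the caudal/rostral split.

#' Min-max normalize a vector to [0, 1]
#'
#' `(v - min) / (max - min)`, applied cohort-wide within one muscle. The
#' cohort minimum (most posterior hotspot / shortest latency) maps to 0, the
#' maximum (most anterior / longest) to 1. A constant vector leaves the index
#' undefined and raises an error rather than returning anything silently.
#'
#' @param values numeric vector, length >= 2, finite.
#' @return numeric vector in `[0, 1]`.
#' @examples
#' minmax_normalize(c(-22, -16, -13)) # 0, 0.6667, 1
#' @export
minmax_normalize <- function(values) {
  if (!is.numeric(values) || length(values) < 2 || any(!is.finite(values)))
    knob_stop("need >= 2 finite values", "knobmap_input_error")
  rng <- range(values)
  if (rng[1] == rng[2])
    knob_stop("degenerate cohort: all values identical, min-max normalization undefined",
              "knobmap_analysis_error")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Caudal/rostral hotspot group from the grid line
#'
#' Hotspots on the two posterior grid lines (1-2, close to the central
#' sulcus) are labelled `"caudal"`; hotspots on the three anterior lines
#' (3-5, precentral crown) are `"rostral"`.
#'
#' @param hotspot_line integer vector of grid line indices in 1-5.
#' @return character vector, `"caudal"` or `"rostral"`.
#' @examples
#' assign_group(c(1, 3, 5))
#' @export
assign_group <- function(hotspot_line) {
  if (any(!hotspot_line %in% 1:5))
    knob_stop("hotspot_line must be in 1..5", "knobmap_input_error")
  ifelse(hotspot_line <= 2, "caudal", "rostral")
}

#' Spatiotemporal rostrality index
#'
#' For each muscle, min-max normalizes the hotspot y-coordinate (anterior =
#' larger y, MNI-like convention) and the shortest MEP latency across the
#' cohort, and multiplies the two normalized values. A subject holding both
#' cohort maxima scores 1; a subject holding both minima scores 0.
#' Normalization is always cohort-wide within muscle, never within group.
#'
#' @param cohort data frame with columns `subject`, `muscle`, `hotspot_y`
#'   (mm), `shortest_latency` (ms, within 10-40), `hotspot_line` (1-5).
#' @return the input with added columns `normalized_y`, `normalized_latency`,
#'   `rostrality_index` and `group`.
#' @examples
#' d <- data.frame(subject = 1:3, muscle = "FDI",
#'                 hotspot_y = c(-22, -16, -13),
#'                 shortest_latency = c(21.5, 22.6, 23.4),
#'                 hotspot_line = c(1, 3, 4))
#' rostrality_index(d)$rostrality_index # 0, 0.3860, 1
#' @export
rostrality_index <- function(cohort) {
  need <- c("subject", "muscle", "hotspot_y", "shortest_latency", "hotspot_line")
  if (!all(need %in% names(cohort)))
    knob_stop(paste("cohort must have columns:", paste(need, collapse = ", ")),
              "knobmap_input_error")
  if (any(cohort$shortest_latency < 10 | cohort$shortest_latency > 40, na.rm = TRUE))
    knob_stop("latencies must lie in [10, 40] ms", "knobmap_input_error")
  out <- cohort
  out$normalized_y <- NA_real_
  out$normalized_latency <- NA_real_
  for (m in unique(cohort$muscle)) {
    i <- which(cohort$muscle == m)
    if (length(i) < 2)
      knob_stop(sprintf("need >= 2 subjects per muscle (muscle %s)", m),
                "knobmap_input_error")
    out$normalized_y[i] <- minmax_normalize(cohort$hotspot_y[i])
    out$normalized_latency[i] <- minmax_normalize(cohort$shortest_latency[i])
  }
  out$rostrality_index <- out$normalized_y * out$normalized_latency
  out$group <- assign_group(out$hotspot_line)
  out
}
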