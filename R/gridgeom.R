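# Sulcus-aligned stimulation-grid geometry.
#
# Coordinates are continuous millimetres in an MNI-like frame: x increases
# laterally, y anteriorly, z superiorly. No voxel indexing anywhere.

#' Digitized sulcus curve
#'
#' An ordered 3D polyline (in mm) tracing the gyrus-sulcus border of the
#' precentral hand knob. This curve is the geometric backbone of the
#' stimulation grid: the first grid line lies on it and the remaining lines
#' are offset anteriorly.
#'
#' @param points numeric matrix or data frame with >= 2 rows and 3 columns
#'   (x, y, z) in mm.
#' @return an object of class `sulcus_curve`.
#' @examples
#' curve <- sulcus_curve(cbind(x = seq(0, 30, 5), y = 0, z = 0))
#' @export
sulcus_curve <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3L || nrow(pts) < 2L || !is.numeric(pts) || anyNA(pts))
    knob_stop("a sulcus curve needs >= 2 finite 3D points (columns x, y, z)",
              "knobmap_geometry_error")
  seg <- diff(pts)
  seglen <- sqrt(rowSums(seg^2))
  if (any(seglen == 0))
    knob_stop("consecutive curve points must be distinct", "knobmap_geometry_error")
  structure(list(points = unname(pts), seg_lengths = seglen,
                 arc_length = sum(seglen)),
            class = "sulcus_curve")
}

#' @export
print.sulcus_curve <- function(x, ...) {
  cat(sprintf("<sulcus_curve> %d points, arc length %.2f mm\n",
              nrow(x$points), x$arc_length))
  invisible(x)
}

#' Resample a polyline at equal arc-length steps
#'
#' Places `n` points from the start to the end of the curve at equal
#' arc-length spacing, linearly interpolating between input vertices. This
#' realizes the "equidistant target sites" used for the on-sulcus grid line.
#'
#' @param curve a [sulcus_curve()].
#' @param n number of output points (>= 2).
#' @return an `n` x 3 matrix of positions (mm).
#' @examples
#' curve <- sulcus_curve(cbind(seq(0, 30, 15), 0, 0))
#' arc_length_resample(curve, 7) # x = 0, 5, ..., 30
#' @export
arc_length_resample <- function(curve, n) {
  stopifnot(inherits(curve, "sulcus_curve"))
  if (!is_scalar_number(n) || n < 2)
    knob_stop("n must be a single number >= 2", "knobmap_input_error")
  if (curve$arc_length <= 0)
    knob_stop("degenerate curve: zero arc length", "knobmap_geometry_error")
  s <- c(0, cumsum(curve$seg_lengths))
  target <- seq(0, curve$arc_length, length.out = n)
  out <- vapply(1:3, function(j)
    stats::approx(s, curve$points[, j], xout = target, ties = "ordered")$y,
    numeric(length(target)))
  unname(out)
}

# Sample a curve at explicit arc-length positions (mm from the start).
arc_length_at <- function(curve, positions) {
  s <- c(0, cumsum(curve$seg_lengths))
  if (any(positions < -1e-9 | positions > curve$arc_length + 1e-9))
    knob_stop(sprintf(
      "requested arc positions up to %.2f mm exceed the curve length (%.2f mm)",
      max(positions), curve$arc_length), "knobmap_geometry_error")
  positions <- pmin(pmax(positions, 0), curve$arc_length)
  out <- vapply(1:3, function(j)
    stats::approx(s, curve$points[, j], xout = positions, ties = "ordered")$y,
    numeric(length(positions)))
  matrix(out, ncol = 3)
}

# Unit tangents of a polyline: central differences at interior vertices,
# second-order one-sided differences at the endpoints (a plain forward
# difference would tilt the endpoint normals by half a segment angle).
polyline_tangents <- function(pts) {
  n <- nrow(pts)
  tan <- matrix(0, n, 3)
  if (n == 2) {
    tan[1, ] <- tan[2, ] <- pts[2, ] - pts[1, ]
  } else {
    tan[1, ] <- -3 * pts[1, ] + 4 * pts[2, ] - pts[3, ]
    tan[n, ] <- 3 * pts[n, ] - 4 * pts[n - 1, ] + pts[n - 2, ]
    tan[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  }
  nrm <- sqrt(rowSums(tan^2))
  if (any(nrm == 0))
    knob_stop("degenerate tangent (repeated points)", "knobmap_geometry_error")
  tan / nrm
}

# In-plane anterior normal: the unit vector perpendicular to the local
# tangent within the tangent-anterior plane, pointing towards +y.
anterior_normals <- function(tangents) {
  a <- c(0, 1, 0)
  proj <- tangents %*% a               # component of +y along each tangent
  nrm_vec <- -tangents * as.numeric(proj)
  nrm_vec[, 2] <- nrm_vec[, 2] + 1
  len <- sqrt(rowSums(nrm_vec^2))
  if (any(len < 1e-9))
    knob_stop("anterior normal undefined: curve tangent parallel to the anterior axis",
              "knobmap_geometry_error")
  nrm_vec / len
}

#' Offset a grid line anteriorly
#'
#' Displaces each point of a base line by `offset` mm along the local
#' in-plane normal that points anteriorly (perpendicular to the local
#' tangent, within the tangent-anterior plane). Used to add the rostral grid
#' lines parallel to the on-sulcus line.
#'
#' @param base_points m x 3 matrix of line positions (mm).
#' @param offset non-negative offset in mm.
#' @return m x 3 matrix of displaced positions.
#' @examples
#' pts <- cbind(seq(0, 30, 5), 0, 0)
#' offset_line(pts, 5) # shifted by (0, 5, 0)
#' @export
offset_line <- function(base_points, offset) {
  pts <- as.matrix(base_points)
  if (!is_scalar_number(offset) || offset < 0)
    knob_stop("offset must be a single non-negative number", "knobmap_input_error")
  if (offset == 0) return(unname(pts))
  normals <- anterior_normals(polyline_tangents(pts))
  unname(pts + offset * normals)
}

#' Build the sulcus-aligned stimulation grid
#'
#' Constructs the `n_lines` x `n_targets` TMS target grid. Line 1 lies on the
#' digitized gyrus-sulcus border; lines 2..`n_lines` are offset anteriorly at
#' cumulative multiples of `interline` mm. Within a line, targets sit at
#' equal arc-length steps. Each site carries a unit orientation vector: the
#' direction of the effective (second-phase) induced current, i.e. the local
#' anterior normal, perpendicular to the local grid-line tangent.
#'
#' @param curve a [sulcus_curve()].
#' @param n_lines number of parallel lines (default 5; line 1 most posterior).
#' @param n_targets targets per line (default 7).
#' @param spacing on-line target spacing in mm (default 5). Ignored when
#'   `spacing_mode = "curve"`.
#' @param interline spacing between neighbouring lines in mm (default 5).
#' @param spacing_mode `"fixed"` (default) places targets at arc positions
#'   `0, spacing, 2 spacing, ...` from the curve start and requires the curve
#'   to be long enough; `"curve"` divides the full curve length into
#'   `n_targets - 1` equal arc steps.
#' @return an object of class `stimulation_grid` with a `sites` data frame
#'   (`line_index`, `target_index`, `x`, `y`, `z`, `ox`, `oy`, `oz`).
#' @examples
#' grid <- build_grid(sulcus_curve(cbind(seq(0, 30, 5), -25, 65)))
#' nrow(grid$sites) # 35
#' @export
build_grid <- function(curve, n_lines = 5, n_targets = 7, spacing = 5,
                       interline = 5, spacing_mode = c("fixed", "curve")) {
  stopifnot(inherits(curve, "sulcus_curve"))
  spacing_mode <- match.arg(spacing_mode)
  if (n_lines < 1 || n_targets < 2)
    knob_stop("need n_lines >= 1 and n_targets >= 2", "knobmap_input_error")

  used_spacing <- if (spacing_mode == "fixed") spacing else
    curve$arc_length / (n_targets - 1)

  # offsets are computed on a densely resampled border so that the discrete
  # tangents (and hence the anterior normals) are accurate everywhere,
  # including the line endpoints; the targets are then read off the dense
  # offset polyline at the exact arc positions
  oversample <- 50L
  n_dense <- (n_targets - 1L) * oversample + 1L
  s_dense <- seq(0, (n_targets - 1) * used_spacing, length.out = n_dense)
  dense_base <- arc_length_at(curve, s_dense)
  target_idx <- seq(1L, n_dense, by = oversample)

  site_rows <- vector("list", n_lines)
  for (k in seq_len(n_lines)) {
    dense_off <- offset_line(dense_base, (k - 1) * interline)
    ori_dense <- anterior_normals(polyline_tangents(dense_off))
    pts <- dense_off[target_idx, , drop = FALSE]
    ori <- ori_dense[target_idx, , drop = FALSE]
    site_rows[[k]] <- data.frame(
      line_index = k, target_index = seq_len(n_targets),
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      ox = ori[, 1], oy = ori[, 2], oz = ori[, 3])
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  structure(list(sites = sites, spacing_on_line = used_spacing,
                 interline_spacing = interline,
                 n_lines = n_lines, n_targets = n_targets),
            class = "stimulation_grid")
}

#' @export
print.stimulation_grid <- function(x, ...) {
  cat(sprintf("<stimulation_grid> %d lines x %d targets (%d sites), %.1f mm on line, %.1f mm between lines\n",
              x$n_lines, x$n_targets, nrow(x$sites),
              x$spacing_on_line, x$interline_spacing))
  invisible(x)
}

#' Position of one grid site
#'
#' @param grid a [build_grid()] result.
#' @param line_index,target_index site indices.
#' @return length-3 numeric vector (x, y, z) in mm.
#' @export
grid_site_position <- function(grid, line_index, target_index) {
  stopifnot(inherits(grid, "stimulation_grid"))
  row <- grid$sites[grid$sites$line_index == line_index &
                    grid$sites$target_index == target_index, , drop = FALSE]
  if (nrow(row) != 1L)
    knob_stop("no such site in the grid", "knobmap_input_error")
  c(x = row$x, y = row$y, z = row$z)
}

#' Write / read a grid as CSV
#'
#' @param grid a `stimulation_grid`.
#' @param path CSV file path.
#' @return `write_grid_csv()` returns `path` invisibly; `read_grid_csv()`
#'   returns the site table as a data frame.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "stimulation_grid"))
  utils::write.csv(grid$sites, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  utils::read.csv(path)
}
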