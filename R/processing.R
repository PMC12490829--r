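#' @title Minimal display processing
#' @description
#' The viewing pipeline applies only the two minimal corrections customary
#' for scanning-probe display — per-line linear leveling of topography and
#' setpoint subtraction of deflection — and otherwise guarantees raw data:
#' line profiles and labeled-array conversion copy values bit-exactly.
#' Stored document arrays are never overwritten; both operations return new
#' maps.
#' @name processing
NULL

#' Physical pixel-center coordinates along one axis
#'
#' `x_j = center - size/2 + (j + 0.5) * size / n` for 0-based pixel index j.
#'
#' @param center axis center, micrometres.
#' @param size physical extent, micrometres.
#' @param n number of pixels.
#' @return numeric vector of length `n`, micrometres.
#' @export
pixel_centers <- function(center, size, n) {
  center - size / 2 + (seq_len(n) - 0.5) * size / n
}

# residuals of a first-degree OLS fit over 0-based column index,
# NaN/NA excluded from the fit; < 2 finite points -> unchanged
level_line <- function(vals) {
  j <- seq_along(vals) - 1
  ok <- is.finite(vals)
  if (sum(ok) < 2L) return(vals)
  fit <- stats::lm.fit(cbind(1, j[ok]), vals[ok])
  vals - (fit$coefficients[1] + fit$coefficients[2] * j)
}

level_grid <- function(grid, method) {
  if (method == "line") {
    t(apply(grid, 1L, level_line))
  } else {
    rows <- nrow(grid)
    cols <- ncol(grid)
    jj <- matrix(rep(seq_len(cols) - 1, each = rows), rows, cols)
    ii <- matrix(rep(seq_len(rows) - 1, times = cols), rows, cols)
    v <- as.vector(grid)
    ok <- is.finite(v)
    if (sum(ok) < 3L) return(grid)
    fit <- stats::lm.fit(cbind(1, as.vector(jj), as.vector(ii))[ok, , drop = FALSE], v[ok])
    b <- fit$coefficients
    grid - (b[1] + b[2] * jj + b[3] * ii)
  }
}

#' Level a height map by per-line linear fit
#'
#' For each scan line independently, the ordinary-least-squares first-degree
#' fit over column index is subtracted (trace and retrace alike). This is
#' the standard removal of scanner tilt from line-by-line acquisition; a
#' global plane fit is available via `method = "plane"`. NaN pixels are
#' excluded from each fit; lines with fewer than two finite pixels pass
#' through unchanged. The operation is idempotent and shape-preserving; the
#' input map is not modified and the output gains metadata
#' `processing = "line_linear_fit"` (or `"plane_fit"`).
#'
#' @param map a [channel_map()] with channel `"Height"`.
#' @param method `"line"` (default) or `"plane"`.
#' @return a new leveled [channel_map()].
#' @export
level_height <- function(map, method = c("line", "plane")) {
  method <- match.arg(method)
  if (!identical(map$channel, "Height"))
    axz_stop("axz_wrong_channel",
             sprintf("level_height expects a Height map, got '%s'", map$channel))
  out <- map
  out$trace <- level_grid(map$trace, method)
  if (!is.null(map$retrace)) out$retrace <- level_grid(map$retrace, method)
  tag <- if (method == "line") "line_linear_fit" else "plane_fit"
  out$metadata <- c(out$metadata[names(out$metadata) != "processing"],
                    processing = tag)
  out
}

#' Subtract the deflection setpoint from a deflection map
#'
#' Every pixel of trace and retrace is decremented by the map's stored
#' deflection setpoint, so the display shows the tracking error around zero.
#' The input is not modified; the output gains metadata
#' `processing = "setpoint_subtraction"`.
#'
#' @param map a [channel_map()] with channel `"Deflection"` and a stored
#'   `deflection_setpoint`.
#' @return a new [channel_map()].
#' @export
subtract_setpoint <- function(map) {
  if (!identical(map$channel, "Deflection"))
    axz_stop("axz_wrong_channel",
             sprintf("subtract_setpoint expects a Deflection map, got '%s'", map$channel))
  if (is.null(map$deflection_setpoint))
    axz_stop("axz_missing_setpoint",
             sprintf("map '%s' has no deflection setpoint", map$label))
  out <- map
  out$trace <- map$trace - map$deflection_setpoint
  if (!is.null(map$retrace)) out$retrace <- map$retrace - map$deflection_setpoint
  out$metadata <- c(out$metadata[names(out$metadata) != "processing"],
                    processing = "setpoint_subtraction")
  out
}

#' Extract a raw trace/retrace line profile
#'
#' Values are copied untouched from the source grids — profiles always show
#' the raw data, even when the rendered map was leveled for display.
#'
#' @param map a [channel_map()].
#' @param row_index 1-based scan-line index (row 1 = first-acquired line).
#' @return an object of class `line_profile` with fields `row_index`,
#'   `positions` (pixel centers along the fast axis, micrometres),
#'   `trace_values`, `retrace_values` (or `NULL`), and `units`.
#' @export
extract_profile <- function(map, row_index) {
  rows <- nrow(map$trace)
  if (row_index < 1L || row_index > rows)
    axz_stop("axz_index_out_of_range",
             sprintf("row_index %d outside 1..%d", row_index, rows))
  structure(list(row_index = as.integer(row_index),
                 positions = pixel_centers(map$center_xy[1], map$size_xy[1],
                                           ncol(map$trace)),
                 trace_values = map$trace[row_index, ],
                 retrace_values = if (is.null(map$retrace)) NULL else map$retrace[row_index, ],
                 units = map$units),
            class = "line_profile")
}

#' Convert a channel map to a labeled array
#'
#' The labeled form pairs the raw grid with physical pixel-center
#' coordinates and descriptive attributes — the natural interchange
#' structure for downstream array tooling. Values are bit-identical to the
#' source grid.
#'
#' @param map a [channel_map()].
#' @param direction `"trace"` (default) or `"retrace"`.
#' @return an object of class `labeled_map` with fields `values`, `coord_x`,
#'   `coord_y` (micrometres) and `attrs` (units, channel, label, and
#'   wavenumber when recorded).
#' @export
to_labeled_map <- function(map, direction = c("trace", "retrace")) {
  direction <- match.arg(direction)
  grid <- if (direction == "trace") map$trace else map$retrace
  if (is.null(grid))
    axz_stop("axz_missing_direction",
             sprintf("map '%s' has no %s data", map$label, direction))
  attrs <- c(label = map$label, channel = map$channel, units = map$units,
             direction = direction)
  if (!is.null(map$ir_wavenumber))
    attrs <- c(attrs, ir_wavenumber = fmt_num(map$ir_wavenumber))
  structure(list(values = grid,
                 coord_x = pixel_centers(map$center_xy[1], map$size_xy[1], ncol(grid)),
                 coord_y = pixel_centers(map$center_xy[2], map$size_xy[2], nrow(grid)),
                 attrs = attrs),
            class = "labeled_map")
}

#' Reconstruct a spectrum's wavenumber axis
#'
#' `n_points` values linearly spaced from `wavenumber_start` to
#' `wavenumber_end` inclusive; descending axes are allowed.
#'
#' @param spec an [ir_spectrum()].
#' @return numeric vector of wavenumbers, cm^-1.
#' @export
spectrum_axis <- function(spec) {
  seq(spec$wavenumber_start, spec$wavenumber_end, length.out = spec$n_points)
}
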