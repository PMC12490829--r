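#' @title Document object model for AFM-IR AXZ files
#' @description
#' The in-memory model mirrors the file's XML structure: an
#' [anasys_document()] holds named collections of optical images, channel
#' maps and rendered spectra, plus file-level metadata. All metadata is
#' carried as an ordered named character vector of verbatim strings; nothing
#' read from a file is dropped or rewritten.
#' @name datamodel
NULL

.known_channels <- c("Height", "Deflection", "IRAmplitude", "IRPhase", "PLLFrequency")

# Merge canonical attribute strings with user/file-supplied metadata.
# Supplied values win verbatim for attribute keys; extra keys follow in
# their supplied order.
merge_metadata <- function(attrs, supplied) {
  if (is.null(supplied)) supplied <- character(0)
  supplied <- unlist(supplied)
  storage.mode(supplied) <- "character"
  out <- attrs
  hit <- names(attrs) %in% names(supplied)
  out[hit] <- supplied[names(attrs)[hit]]
  extra <- supplied[!(names(supplied) %in% names(attrs))]
  c(out, extra)
}

image_attr_strings <- function(label, center_xy, extent_xy) {
  c(Label = label,
    CenterX = fmt_num(center_xy[1]), CenterY = fmt_num(center_xy[2]),
    SizeX = fmt_num(extent_xy[1]), SizeY = fmt_num(extent_xy[2]))
}

map_attr_strings <- function(label, channel, units, center_xy, size_xy, timestamp,
                             ir_wavenumber, deflection_setpoint, phase_setpoint,
                             pll_range, scan_rate) {
  a <- c(Label = label, DataChannel = channel, Units = units,
         CenterX = fmt_num(center_xy[1]), CenterY = fmt_num(center_xy[2]),
         SizeX = fmt_num(size_xy[1]), SizeY = fmt_num(size_xy[2]),
         TimeStamp = timestamp)
  if (!is.null(ir_wavenumber)) a <- c(a, IRWavenumber = fmt_num(ir_wavenumber))
  if (!is.null(deflection_setpoint)) a <- c(a, DeflectionSetpoint = fmt_num(deflection_setpoint))
  if (!is.null(phase_setpoint)) a <- c(a, PhaseSetpoint = fmt_num(phase_setpoint))
  if (!is.null(pll_range)) a <- c(a, PLLRangeMin = fmt_num(pll_range[1]),
                                  PLLRangeMax = fmt_num(pll_range[2]))
  if (!is.null(scan_rate)) a <- c(a, ScanRate = fmt_num(scan_rate))
  a
}

spectrum_attr_strings <- function(label, location_xy, wavenumber_start,
                                  wavenumber_end, n_points) {
  c(Label = label,
    LocationX = fmt_num(location_xy[1]), LocationY = fmt_num(location_xy[2]),
    StartWavenumber = fmt_num(wavenumber_start),
    EndWavenumber = fmt_num(wavenumber_end),
    DataPoints = fmt_num(n_points))
}

#' Optical reference image
#'
#' @param label unique label within the document's image collection.
#' @param pixels integer array `rows x cols x 3` of 8-bit RGB values (0-255).
#' @param center_xy physical center, micrometres.
#' @param extent_xy physical width and height, micrometres; strictly positive.
#' @param metadata optional named character vector of verbatim metadata;
#'   canonical geometry keys are filled in when absent.
#' @return an object of class `optical_image`.
#' @export
optical_image <- function(label, pixels, center_xy = c(0, 0), extent_xy,
                          metadata = NULL) {
  pixels <- array(as.integer(pixels), dim = dim(pixels))
  attrs <- image_attr_strings(label, center_xy, extent_xy)
  structure(list(label = label, pixels = pixels,
                 center_xy = as.numeric(center_xy),
                 extent_xy = as.numeric(extent_xy),
                 metadata = merge_metadata(attrs, metadata)),
            class = "optical_image")
}

#' One recorded 2-D data channel (trace and optional retrace)
#'
#' @param label unique label within the document's map collection.
#' @param channel channel name; one of `"Height"`, `"Deflection"`,
#'   `"IRAmplitude"`, `"IRPhase"`, `"PLLFrequency"`, or any other string
#'   (unknown channels are preserved, never dropped).
#' @param trace numeric matrix, `rows x cols`; row 1 is the first-acquired
#'   scan line, columns advance along the fast scan axis.
#' @param retrace optional numeric matrix with the same shape as `trace`.
#' @param units unit string carried verbatim (nm, V, degrees, kHz, ...);
#'   never converted.
#' @param center_xy,size_xy scan center and physical size in micrometres.
#' @param timestamp acquisition time as an ISO-8601 string.
#' @param ir_wavenumber optional IR illumination wavenumber, cm^-1.
#' @param deflection_setpoint optional deflection feedback setpoint, V.
#' @param phase_setpoint optional PLL phase setpoint, degrees.
#' @param pll_range optional `c(min, max)` PLL frequency limits, kHz.
#' @param scan_rate optional line rate, Hz.
#' @param metadata optional named character vector; verbatim strings win over
#'   canonical attribute renderings.
#' @return an object of class `channel_map`.
#' @export
channel_map <- function(label, channel, trace, retrace = NULL, units = "",
                        center_xy = c(0, 0), size_xy, timestamp = "",
                        ir_wavenumber = NULL, deflection_setpoint = NULL,
                        phase_setpoint = NULL, pll_range = NULL,
                        scan_rate = NULL, metadata = NULL) {
  trace <- as.matrix(trace)
  storage.mode(trace) <- "double"
  if (!is.null(retrace)) {
    retrace <- as.matrix(retrace)
    storage.mode(retrace) <- "double"
  }
  attrs <- map_attr_strings(label, channel, units, center_xy, size_xy,
                            timestamp, ir_wavenumber, deflection_setpoint,
                            phase_setpoint, pll_range, scan_rate)
  structure(list(label = label, channel = channel, trace = trace,
                 retrace = retrace, units = units,
                 center_xy = as.numeric(center_xy),
                 size_xy = as.numeric(size_xy), timestamp = timestamp,
                 ir_wavenumber = if (is.null(ir_wavenumber)) NULL else as.numeric(ir_wavenumber),
                 deflection_setpoint = if (is.null(deflection_setpoint)) NULL else as.numeric(deflection_setpoint),
                 phase_setpoint = if (is.null(phase_setpoint)) NULL else as.numeric(phase_setpoint),
                 pll_range = if (is.null(pll_range)) NULL else as.numeric(pll_range),
                 scan_rate = if (is.null(scan_rate)) NULL else as.numeric(scan_rate),
                 metadata = merge_metadata(attrs, metadata)),
            class = "channel_map")
}

#' Rendered per-location spectrum
#'
#' Multi-channel spectral vectors over a shared linearly spaced wavenumber
#' axis (see [spectrum_axis()]); descending axes are allowed.
#'
#' @param label unique label within the document's spectra collection.
#' @param location_xy acquisition location, micrometres.
#' @param wavenumber_start,wavenumber_end axis endpoints, cm^-1; must differ.
#' @param n_points number of points per channel (>= 2).
#' @param channels named list of numeric vectors, each of length `n_points`.
#' @param metadata optional named character vector of verbatim metadata.
#' @return an object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(label, location_xy = c(0, 0), wavenumber_start,
                        wavenumber_end, n_points, channels, metadata = NULL) {
  channels <- lapply(channels, as.numeric)
  attrs <- spectrum_attr_strings(label, location_xy, wavenumber_start,
                                 wavenumber_end, n_points)
  structure(list(label = label, location_xy = as.numeric(location_xy),
                 wavenumber_start = as.numeric(wavenumber_start),
                 wavenumber_end = as.numeric(wavenumber_end),
                 n_points = as.integer(n_points), channels = channels,
                 metadata = merge_metadata(attrs, metadata)),
            class = "ir_spectrum")
}

#' Root document container
#'
#' @param images named list of [optical_image()] objects.
#' @param height_maps named list of [channel_map()] objects (the collection
#'   holds every recorded channel, not only topography; the name mirrors the
#'   file's element vocabulary).
#' @param spectra named list of [ir_spectrum()] objects.
#' @param file_metadata named character vector of file-level metadata;
#'   `FormatVersion` and `Created` are filled with defaults when absent.
#' @return an object of class `anasys_document`.
#' @export
anasys_document <- function(images = list(), height_maps = list(),
                            spectra = list(), file_metadata = NULL) {
  label_of <- function(x) x$label
  if (is.null(names(images)))
    names(images) <- vapply(images, label_of, "")
  if (is.null(names(height_maps)))
    names(height_maps) <- vapply(height_maps, label_of, "")
  if (is.null(names(spectra)))
    names(spectra) <- vapply(spectra, label_of, "")
  attrs <- c(FormatVersion = "1.0", Created = "1970-01-01T00:00:00")
  structure(list(images = images, height_maps = height_maps,
                 spectra = spectra,
                 file_metadata = merge_metadata(attrs, file_metadata)),
            class = "anasys_document")
}

#' Heuristic quality-control configuration
#'
#' Thresholds for the QC rules. The per-pixel deflection and phase limits are
#' the field's usual tracking tolerances; the trigger fraction suppresses
#' single-pixel noise (set it arbitrarily close to 0 for strict any-pixel
#' semantics).
#'
#' @param deflection_threshold maximum tolerated |deflection - setpoint|, V.
#' @param phase_threshold maximum tolerated wrapped |IR phase - setpoint|, degrees.
#' @param exceed_fraction_trigger fraction of offending pixels above which a
#'   tracking/phase flag is raised, in (0, 1].
#' @param flat_tolerance absolute per-line mean below which a map counts as
#'   flattened ("apparent processing"), in the channel's own units.
#' @param saturation_fraction fraction of saturated pixels above which the
#'   PLL saturation flag is raised, in (0, 1].
#' @param saturation_tol relative distance to a PLL range limit (as a
#'   fraction of the range span) within which a pixel counts as saturated.
#' @param flat_mode `"line"` tests every scan line's mean (the signature of
#'   line-wise leveling); `"global"` tests the global mean only.
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(deflection_threshold = 0.01, phase_threshold = 20,
                      exceed_fraction_trigger = 0.01, flat_tolerance = 1e-6,
                      saturation_fraction = 0.05, saturation_tol = 1e-6,
                      flat_mode = c("line", "global")) {
  flat_mode <- match.arg(flat_mode)
  stopifnot(deflection_threshold > 0, phase_threshold > 0, flat_tolerance > 0,
            saturation_tol > 0,
            exceed_fraction_trigger > 0, exceed_fraction_trigger <= 1,
            saturation_fraction > 0, saturation_fraction <= 1)
  structure(list(deflection_threshold = deflection_threshold,
                 phase_threshold = phase_threshold,
                 exceed_fraction_trigger = exceed_fraction_trigger,
                 flat_tolerance = flat_tolerance,
                 saturation_fraction = saturation_fraction,
                 saturation_tol = saturation_tol,
                 flat_mode = flat_mode),
            class = "qc_config")
}

#' Validate a document against the model invariants
#'
#' Validation never throws: it returns a character vector of violation
#' descriptions (empty when the document is well formed), each naming the
#' offending object and invariant. It is idempotent and side-effect-free.
#'
#' @param doc an [anasys_document()].
#' @return character vector of violations; `character(0)` if none.
#' @export
validate_document <- function(doc) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!inherits(doc, "anasys_document")) {
    return("object is not an anasys_document")
  }
  check_labels <- function(coll, what) {
    for (key in names(coll)) {
      obj <- coll[[key]]
      if (!nzchar(obj$label %||% "")) {
        add(sprintf("%s '%s': empty label", what, key))
      } else if (!identical(obj$label, key)) {
        add(sprintf("%s '%s': label '%s' differs from its key", what, key, obj$label))
      }
    }
  }
  check_labels(doc$images, "optical image")
  check_labels(doc$height_maps, "channel map")
  check_labels(doc$spectra, "spectrum")

  for (key in names(doc$images)) {
    img <- doc$images[[key]]
    d <- dim(img$pixels)
    if (length(d) != 3L || d[3] != 3L || d[1] < 1L || d[2] < 1L)
      add(sprintf("optical image '%s': pixels must be rows x cols x 3 with rows, cols >= 1", key))
    if (any(!is.finite(img$extent_xy)) || any(img$extent_xy <= 0))
      add(sprintf("optical image '%s': extent components must be strictly positive", key))
  }
  for (key in names(doc$height_maps)) {
    m <- doc$height_maps[[key]]
    if (!is.matrix(m$trace) || nrow(m$trace) < 2L || ncol(m$trace) < 2L)
      add(sprintf("channel map '%s': trace must be a matrix with rows, cols >= 2", key))
    if (!is.null(m$retrace) && !identical(dim(m$retrace), dim(m$trace)))
      add(sprintf("channel map '%s': retrace shape differs from trace shape", key))
    if (any(!is.finite(m$size_xy)) || any(m$size_xy <= 0))
      add(sprintf("channel map '%s': size components must be strictly positive", key))
  }
  for (key in names(doc$spectra)) {
    s <- doc$spectra[[key]]
    if (is.na(s$n_points) || s$n_points < 2L)
      add(sprintf("spectrum '%s': n_points must be >= 2", key))
    if (identical(s$wavenumber_start, s$wavenumber_end))
      add(sprintf("spectrum '%s': wavenumber_start equals wavenumber_end", key))
    for (ch in names(s$channels)) {
      if (length(s$channels[[ch]]) != s$n_points)
        add(sprintf("spectrum '%s': channel '%s' has length %d, expected n_points = %d",
                    key, ch, length(s$channels[[ch]]), s$n_points))
    }
  }
  v
}

#' @export
print.anasys_document <- function(x, ...) {
  cat("AFM-IR document\n")
  cat(sprintf("  optical images: %d\n", length(x$images)))
  cat(sprintf("  channel maps:   %d\n", length(x$height_maps)))
  if (length(x$height_maps)) {
    ch <- vapply(x$height_maps, function(m) m$channel, "")
    tab <- table(ch)
    cat(sprintf("    (%s)\n", paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  }
  cat(sprintf("  spectra:        %d\n", length(x$spectra)))
  invisible(x)
}

#' @export
print.channel_map <- function(x, ...) {
  cat(sprintf("channel map '%s' [%s], %d x %d px, %g x %g um%s, units '%s'\n",
              x$label, x$channel, nrow(x$trace), ncol(x$trace),
              x$size_xy[1], x$size_xy[2],
              if (is.null(x$retrace)) ", trace only" else ", trace + retrace",
              x$units))
  invisible(x)
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("spectrum '%s' at (%g, %g) um: %d points, %g..%g cm-1, channels: %s\n",
              x$label, x$location_xy[1], x$location_xy[2], x$n_points,
              x$wavenumber_start, x$wavenumber_end,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
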