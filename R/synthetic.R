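#' @title Deterministic synthetic AFM-IR documents
#' @description
#' Generates valid documents (and files) emulating multi-channel AFM-IR
#' scans and rendered spectra, with controllable artifact injection. All
#' randomness flows from the single seed in the [synthetic_spec()], so an
#' identical spec always yields a bit-identical document. Pristine specs
#' (no artifacts) are QC-clean by construction: per-channel noise amplitudes
#' are fixed at one third of the corresponding QC threshold, and each
#' injected artifact produces exactly its one corresponding QC flag.
#' @name synthetic
NULL

.artifact_kinds <- c("flattened_height", "deflection_error", "phase_error",
                     "pll_saturation")

#' Describe one injected artifact
#'
#' @param kind one of `"flattened_height"` (line-wise leveling applied at
#'   generation time — the signature the apparent-processing rule detects),
#'   `"deflection_error"` (uniform offset from the deflection setpoint, V),
#'   `"phase_error"` (uniform offset from the phase setpoint, degrees),
#'   `"pll_saturation"` (fraction of pixels pinned at the PLL range limit).
#' @param target_group 1-based index of the map group to perturb.
#' @param magnitude offset (V or degrees) or pixel fraction, depending on
#'   `kind`; defaults are 0.05 V, 30 degrees and 0.10 respectively.
#' @return an object of class `artifact_injection`.
#' @export
artifact_injection <- function(kind, target_group = 1L, magnitude = NULL) {
  kind <- match.arg(kind, .artifact_kinds)
  if (is.null(magnitude)) {
    magnitude <- switch(kind, flattened_height = 0,
                        deflection_error = 0.05, phase_error = 30,
                        pll_saturation = 0.10)
  }
  if (magnitude < 0)
    axz_stop("axz_invalid_spec", "artifact magnitude must be >= 0")
  structure(list(kind = kind, target_group = as.integer(target_group),
                 magnitude = magnitude),
            class = "artifact_injection")
}

#' Parameters fully determining a generated document
#'
#' @param seed integer seed driving all randomness.
#' @param rows,cols scan resolution in pixels (default 64 x 64).
#' @param n_map_groups number of co-temporal map groups, each sharing one
#'   timestamp.
#' @param channels channels recorded per group.
#' @param n_spectra number of rendered spectra.
#' @param peaks data frame with columns `center` (cm^-1), `width` (cm^-1,
#'   half width at half maximum) and `amplitude`; defaults are the amide-I
#'   and amide-II protein bands.
#' @param wavenumber_range spectral axis endpoints, cm^-1.
#' @param spectrum_points points per spectrum.
#' @param n_images number of optical reference images.
#' @param artifacts list of [artifact_injection()] objects.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, rows = 64L, cols = 64L,
                           n_map_groups = 2L,
                           channels = c("Height", "Deflection", "IRAmplitude",
                                        "IRPhase", "PLLFrequency"),
                           n_spectra = 3L,
                           peaks = data.frame(center = c(1655, 1545),
                                              width = c(30, 40),
                                              amplitude = c(1, 0.6)),
                           wavenumber_range = c(1000, 1800),
                           spectrum_points = 256L,
                           n_images = 1L,
                           artifacts = list()) {
  if (inherits(artifacts, "artifact_injection")) artifacts <- list(artifacts)
  for (a in artifacts) {
    if (!inherits(a, "artifact_injection"))
      axz_stop("axz_invalid_spec", "artifacts must be artifact_injection objects")
    if (a$target_group < 1L || a$target_group > n_map_groups)
      axz_stop("axz_invalid_spec",
               sprintf("artifact target_group %d outside 1..%d",
                       a$target_group, n_map_groups))
  }
  if (rows < 2L || cols < 2L)
    axz_stop("axz_invalid_spec", "rows and cols must be >= 2")
  structure(list(seed = as.integer(seed), rows = as.integer(rows),
                 cols = as.integer(cols),
                 n_map_groups = as.integer(n_map_groups),
                 channels = channels, n_spectra = as.integer(n_spectra),
                 peaks = peaks, wavenumber_range = as.numeric(wavenumber_range),
                 spectrum_points = as.integer(spectrum_points),
                 n_images = as.integer(n_images), artifacts = artifacts),
            class = "synthetic_spec")
}

# instrument-typical operating points used by the generator
.synth_const <- list(
  deflection_setpoint = 0.5,    # V
  phase_setpoint = 90,          # degrees
  pll_range = c(180, 220),      # kHz
  pll_center = 200,             # kHz
  scan_size = 10,               # um
  scan_rate = 0.5,              # Hz
  ir_wavenumber = 1655          # cm^-1
)

lorentzian <- function(x, center, width, amplitude) {
  amplitude * width^2 / ((x - center)^2 + width^2)
}

synth_height_surface <- function(rows, cols) {
  x <- matrix(rep(seq_len(cols), each = rows), rows, cols) / cols
  y <- matrix(rep(seq_len(rows), times = cols), rows, cols) / rows
  tilt <- 20 * x + 8 * y
  bumps <- 30 * exp(-((x - 0.35)^2 + (y - 0.4)^2) / 0.02) +
           18 * exp(-((x - 0.7)^2 + (y - 0.65)^2) / 0.01)
  tilt + bumps
}

synth_group_maps <- function(spec, g, cfg_noise) {
  k <- .synth_const
  rows <- spec$rows
  cols <- spec$cols
  timestamp <- sprintf("2024-05-01T12:%02d:00", (g - 1L) %% 60L)
  base_height <- synth_height_surface(rows, cols)
  maps <- list()
  for (ch in spec$channels) {
    grids <- switch(ch,
      Height = {
        list(trace = base_height + matrix(stats::rnorm(rows * cols, 0, 0.5), rows, cols),
             retrace = base_height + matrix(stats::rnorm(rows * cols, 0, 0.5), rows, cols))
      },
      Deflection = {
        sd <- cfg_noise$deflection
        list(trace = k$deflection_setpoint + matrix(stats::rnorm(rows * cols, 0, sd), rows, cols),
             retrace = k$deflection_setpoint + matrix(stats::rnorm(rows * cols, 0, sd), rows, cols))
      },
      IRAmplitude = {
        feat <- base_height / max(base_height) * 0.8
        list(trace = feat + matrix(stats::rnorm(rows * cols, 0, 0.01), rows, cols),
             retrace = feat + matrix(stats::rnorm(rows * cols, 0, 0.01), rows, cols))
      },
      IRPhase = {
        sd <- cfg_noise$phase
        list(trace = k$phase_setpoint + matrix(stats::rnorm(rows * cols, 0, sd), rows, cols),
             retrace = k$phase_setpoint + matrix(stats::rnorm(rows * cols, 0, sd), rows, cols))
      },
      PLLFrequency = {
        list(trace = k$pll_center + matrix(stats::rnorm(rows * cols, 0, 1), rows, cols),
             retrace = k$pll_center + matrix(stats::rnorm(rows * cols, 0, 1), rows, cols))
      },
      # unknown channels get generic bounded noise around zero offset 1
      list(trace = 1 + matrix(stats::rnorm(rows * cols, 0, 0.1), rows, cols),
           retrace = 1 + matrix(stats::rnorm(rows * cols, 0, 0.1), rows, cols)))
    units <- switch(ch, Height = "nm", Deflection = "V", IRAmplitude = "V",
                    IRPhase = "degrees", PLLFrequency = "kHz", "a.u.")
    maps[[ch]] <- list(grids = grids, units = units, timestamp = timestamp)
  }
  maps
}

apply_artifact <- function(maps, a, pll_range) {
  m <- switch(a$kind,
    flattened_height = "Height",
    deflection_error = "Deflection",
    phase_error = "IRPhase",
    pll_saturation = "PLLFrequency")
  if (is.null(maps[[m]])) {
    axz_stop("axz_invalid_spec",
             sprintf("artifact '%s' targets channel %s, absent from the spec", a$kind, m))
  }
  g <- maps[[m]]$grids
  if (a$kind == "flattened_height") {
    g$trace <- level_grid(g$trace, "line")
    g$retrace <- level_grid(g$retrace, "line")
  } else if (a$kind == "deflection_error") {
    g$trace <- g$trace + a$magnitude
    g$retrace <- g$retrace + a$magnitude
  } else if (a$kind == "phase_error") {
    g$trace <- g$trace + a$magnitude
    g$retrace <- g$retrace + a$magnitude
  } else {
    k <- max(1L, ceiling(a$magnitude * length(g$trace)))
    hi <- pll_range[2]
    g$trace[seq_len(k)] <- hi
    g$retrace[seq_len(k)] <- hi
  }
  maps[[m]]$grids <- g
  maps
}

#' Generate a synthetic document
#'
#' Builds a document emulating a session's data inventory: per group, one
#' co-temporal set of channel maps sharing a timestamp (height as a tilted
#' plane with smooth features plus noise, deflection and IR phase as noise
#' around their setpoints, PLL frequency comfortably inside its range);
#' rendered spectra as sums of Lorentzian bands over a linear wavenumber
#' axis plus noise; and smooth optical reference images. All grids are
#' snapped to float32, the storage type of the file format, so written
#' files round-trip bit-exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return an [anasys_document()] passing [validate_document()].
#' @export
make_document <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec"))
    axz_stop("axz_invalid_spec", "spec must be a synthetic_spec object")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  k <- .synth_const
  qc_defaults <- qc_config()
  cfg_noise <- list(deflection = qc_defaults$deflection_threshold / 3,
                    phase = qc_defaults$phase_threshold / 3)

  maps <- list()
  for (g in seq_len(spec$n_map_groups)) {
    group_maps <- synth_group_maps(spec, g, cfg_noise)
    for (a in spec$artifacts) {
      if (a$target_group == g) group_maps <- apply_artifact(group_maps, a, k$pll_range)
    }
    for (ch in names(group_maps)) {
      gm <- group_maps[[ch]]
      label <- sprintf("group%02d/%s", g, ch)
      maps[[label]] <- channel_map(
        label = label, channel = ch,
        trace = as_float32(gm$grids$trace),
        retrace = as_float32(gm$grids$retrace),
        units = gm$units,
        center_xy = c(0, 0), size_xy = c(k$scan_size, k$scan_size),
        timestamp = gm$timestamp,
        ir_wavenumber = if (ch == "IRAmplitude") k$ir_wavenumber else NULL,
        deflection_setpoint = if (ch == "Deflection") k$deflection_setpoint else NULL,
        phase_setpoint = if (ch == "IRPhase") k$phase_setpoint else NULL,
        pll_range = if (ch == "PLLFrequency") k$pll_range else NULL,
        scan_rate = k$scan_rate)
    }
  }

  axis <- seq(spec$wavenumber_range[1], spec$wavenumber_range[2],
              length.out = spec$spectrum_points)
  spectra <- list()
  for (i in seq_len(spec$n_spectra)) {
    signal <- rep(0, spec$spectrum_points)
    for (p in seq_len(nrow(spec$peaks))) {
      signal <- signal + lorentzian(axis, spec$peaks$center[p],
                                    spec$peaks$width[p], spec$peaks$amplitude[p])
    }
    scale <- stats::runif(1, 0.7, 1.3)
    label <- sprintf("spectrum%02d", i)
    spectra[[label]] <- ir_spectrum(
      label = label,
      location_xy = c(stats::runif(1, -k$scan_size / 2, k$scan_size / 2),
                      stats::runif(1, -k$scan_size / 2, k$scan_size / 2)),
      wavenumber_start = spec$wavenumber_range[1],
      wavenumber_end = spec$wavenumber_range[2],
      n_points = spec$spectrum_points,
      channels = list(
        IRAmplitude = as_float32(scale * signal +
                                 stats::rnorm(spec$spectrum_points, 0, 0.005)),
        IRPhase = as_float32(k$phase_setpoint +
                             stats::rnorm(spec$spectrum_points, 0, 2)),
        PLLFrequency = as_float32(k$pll_center +
                                  stats::rnorm(spec$spectrum_points, 0, 0.5))))
  }

  images <- list()
  for (i in seq_len(spec$n_images)) {
    n <- 32L
    gx <- matrix(rep(seq_len(n), each = n), n, n) / n
    gy <- matrix(rep(seq_len(n), times = n), n, n) / n
    base <- 0.5 + 0.4 * sin(6 * gx) * cos(5 * gy)
    px <- array(0L, dim = c(n, n, 3L))
    for (chn in 1:3) {
      layer <- base * (0.6 + 0.2 * chn) + matrix(stats::runif(n * n, 0, 0.05), n, n)
      px[, , chn] <- pmin(255L, pmax(0L, as.integer(round(layer * 255))))
    }
    label <- sprintf("optical%02d", i)
    images[[label]] <- optical_image(label = label, pixels = px,
                                     center_xy = c(0, 0),
                                     extent_xy = c(50, 50))
  }

  anasys_document(images = images, height_maps = maps, spectra = spectra,
                  file_metadata = c(FormatVersion = "1.0",
                                    Created = "2024-05-01T12:00:00",
                                    Generator = "axztools synthetic"))
}

#' Write a synthetic fixture file
#'
#' @param spec a [synthetic_spec()].
#' @param path output path.
#' @param container container kind passed to [write_axz()].
#' @return `path`, invisibly.
#' @export
make_fixture_file <- function(spec = synthetic_spec(), path,
                              container = c("gzip", "zip", "plain_xml")) {
  write_axz(make_document(spec), path, container = match.arg(container))
}
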