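#' @title QC report rendering (PDF / HTML)
#' @name report
NULL

# channel-specific color tables: topography warm, amplitude sequential dark,
# phase diverging, deflection/PLL neutral
channel_palette <- function(channel, n = 256L) {
  ramp <- switch(channel,
    Height = c("#000000", "#67001f", "#d6604d", "#fddbc7", "#ffffff"),
    IRAmplitude = c("#000004", "#51127c", "#b63679", "#fb8861", "#fcfdbf"),
    IRPhase = c("#2166ac", "#f7f7f7", "#b2182b"),
    Deflection = c("#00441b", "#f7fcf5"),
    PLLFrequency = c("#08306b", "#f7fbff"),
    c("#000000", "#ffffff"))
  grDevices::colorRampPalette(ramp)(n)
}

# grid -> rows x cols x 3 array in [0,1]; NaN pixels render mid-grey
colorize_grid <- function(grid, palette) {
  rng <- range(grid[is.finite(grid)], na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) rng <- c(rng[1] - 1, rng[1] + 1)
  idx <- as.integer(round((grid - rng[1]) / (rng[2] - rng[1]) * (length(palette) - 1L))) + 1L
  idx[!is.finite(grid)] <- NA_integer_
  cols <- palette[idx]
  cols[is.na(cols)] <- "#808080"
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, dim = c(nrow(grid), ncol(grid), 3L))
  out[, , 1] <- matrix(rgb[1, ], nrow(grid), ncol(grid))
  out[, , 2] <- matrix(rgb[2, ], nrow(grid), ncol(grid))
  out[, , 3] <- matrix(rgb[3, ], nrow(grid), ncol(grid))
  out
}

# map rendered for display: height leveled, deflection setpoint-subtracted,
# everything else raw (profiles always use the raw map)
display_map <- function(m) {
  if (identical(m$channel, "Height")) return(level_height(m))
  if (identical(m$channel, "Deflection") && !is.null(m$deflection_setpoint))
    return(subtract_setpoint(m))
  m
}

svg_profile <- function(profile, width = 360, height = 120) {
  rngx <- range(profile$positions)
  vals <- c(profile$trace_values, profile$retrace_values)
  rngy <- range(vals[is.finite(vals)])
  if (rngy[1] == rngy[2]) rngy <- rngy + c(-1, 1)
  sx <- function(x) (x - rngx[1]) / diff(rngx) * (width - 20) + 10
  sy <- function(y) height - 10 - (y - rngy[1]) / diff(rngy) * (height - 20)
  poly <- function(y, color) {
    ok <- is.finite(y)
    pts <- paste(sprintf("%.2f,%.2f", sx(profile$positions[ok]), sy(y[ok])),
                 collapse = " ")
    sprintf('<polyline fill="none" stroke="%s" stroke-width="1" points="%s"/>',
            color, pts)
  }
  lines <- poly(profile$trace_values, "#1f77b4")
  if (!is.null(profile$retrace_values))
    lines <- paste0(lines, poly(profile$retrace_values, "#ff7f0e"))
  sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">%s</svg>',
          width, height, lines)
}

png_data_uri <- function(arr) {
  paste0("data:image/png;base64,", b64_encode(png::writePNG(arr)))
}

html_report <- function(doc, report, path) {
  groups <- group_cotemporal_maps(doc)
  flags <- qc_flags_df(report)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  out <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
           "<title>AFM-IR QC report</title>",
           "<style>body{font-family:sans-serif;margin:2em}figure{display:inline-block;margin:0.5em}figcaption{font-size:80%}.warn{color:#b45f06}.fail{color:#990000}</style>",
           "</head><body>", "<h1>AFM-IR QC report</h1>",
           sprintf("<p>%d channel map(s) in %d co-temporal group(s); %d spectra; %d QC flag(s) over %d rule evaluations.</p>",
                   length(doc$height_maps), length(groups), length(doc$spectra),
                   length(report$flags), report$n_maps_checked))
  if (length(groups) == 0L) {
    out <- c(out, "<p>No maps recorded; summary only.</p>")
  }
  for (grp in groups) {
    out <- c(out, sprintf("<section><h2>Maps collected at %s</h2>",
                          esc(if (nzchar(grp$timestamp)) grp$timestamp else "(no timestamp)")))
    for (label in grp$members) {
      m <- doc$height_maps[[label]]
      disp <- display_map(m)
      pal <- channel_palette(m$channel)
      img <- png_data_uri(colorize_grid(disp$trace, pal))
      bar <- png_data_uri(colorize_grid(matrix(rev(seq_along(pal)), ncol = 1), pal))
      rng <- range(disp$trace[is.finite(disp$trace)])
      mid_row <- (nrow(m$trace) + 1L) %/% 2L
      prof <- extract_profile(m, mid_row)
      out <- c(out,
        sprintf("<figure><img src='%s' width='192' height='192' style='image-rendering:pixelated'>", img),
        sprintf("<img src='%s' width='12' height='192'>", bar),
        sprintf("<figcaption>%s [%s, %s]; display range %.6g to %.6g; raw profile of line %d below</figcaption>",
                esc(label), esc(m$channel), esc(m$units), rng[1], rng[2], mid_row),
        svg_profile(prof), "</figure>")
      fl <- flags[flags$target_label == label, , drop = FALSE]
      if (nrow(fl)) {
        for (i in seq_len(nrow(fl))) {
          out <- c(out, sprintf("<p class='%s'>[%s] %s: %s</p>",
                                fl$severity[i], esc(fl$severity[i]),
                                esc(fl$rule_id[i]), esc(fl$message[i])))
        }
      } else {
        out <- c(out, "<p>No QC flags.</p>")
      }
    }
    out <- c(out, "</section>")
  }
  out <- c(out, "</body></html>")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(out, collapse = "\n"), "\n")), con)
  path
}

pdf_report <- function(doc, report, path, deterministic) {
  groups <- group_cotemporal_maps(doc)
  flags <- qc_flags_df(report)
  grDevices::pdf(path, width = 8, height = 10, compress = FALSE,
                 useDingbats = FALSE)
  ok <- tryCatch({
    graphics::par(mfrow = c(1, 1), mar = c(1, 1, 3, 1))
    graphics::plot.new()
    graphics::title("AFM-IR QC report")
    graphics::text(0.5, 0.8, sprintf("%d channel map(s), %d group(s), %d spectra",
                                     length(doc$height_maps), length(groups),
                                     length(doc$spectra)))
    graphics::text(0.5, 0.7, sprintf("%d QC flag(s) over %d rule evaluations",
                                     length(report$flags), report$n_maps_checked))
    for (grp in groups) {
      for (label in grp$members) {
        m <- doc$height_maps[[label]]
        disp <- display_map(m)
        pal <- channel_palette(m$channel)
        mid_row <- (nrow(m$trace) + 1L) %/% 2L
        prof <- extract_profile(m, mid_row)
        graphics::par(mfrow = c(2, 1), mar = c(4, 4, 3, 6))
        z <- t(disp$trace)[, rev(seq_len(nrow(disp$trace))), drop = FALSE]
        graphics::image(x = pixel_centers(m$center_xy[1], m$size_xy[1], ncol(m$trace)),
                        y = pixel_centers(m$center_xy[2], m$size_xy[2], nrow(m$trace)),
                        z = z, col = pal, xlab = "x (um)", ylab = "y (um)",
                        main = sprintf("%s [%s] at %s", label, m$channel, grp$timestamp),
                        useRaster = TRUE)
        rng <- range(disp$trace[is.finite(disp$trace)])
        graphics::mtext(sprintf("range %.6g to %.6g %s", rng[1], rng[2], m$units),
                        side = 3, line = 0.2, cex = 0.8)
        # colorbar in the right margin
        usr <- graphics::par("usr")
        xr <- usr[2] + 0.02 * diff(usr[1:2])
        graphics::rect(rep(xr, length(pal)),
                       seq(usr[3], usr[4], length.out = length(pal) + 1)[-(length(pal) + 1)],
                       rep(xr + 0.04 * diff(usr[1:2]), length(pal)),
                       seq(usr[3], usr[4], length.out = length(pal) + 1)[-1],
                       col = pal, border = NA, xpd = TRUE)
        graphics::plot(prof$positions, prof$trace_values, type = "l",
                       col = "#1f77b4", xlab = "x (um)",
                       ylab = sprintf("raw value (%s)", m$units),
                       main = sprintf("raw line profile, line %d", mid_row))
        if (!is.null(prof$retrace_values))
          graphics::lines(prof$positions, prof$retrace_values, col = "#ff7f0e")
        fl <- flags[flags$target_label == label, , drop = FALSE]
        if (nrow(fl)) {
          graphics::mtext(paste(sprintf("[%s] %s", fl$severity, fl$rule_id),
                                collapse = "; "),
                          side = 1, line = 3.5, col = "#990000", cex = 0.8)
        }
      }
    }
    TRUE
  }, finally = grDevices::dev.off())
  if (deterministic) pdf_fix_dates(path)
  path
}

# rewrite the embedded creation/modification dates so identical inputs give
# byte-identical files; the PDF may contain non-text bytes, so work on raw
pdf_fix_dates <- function(path) {
  b <- readBin(path, raw(), file.size(path))
  fix <- function(b, key) {
    kb <- charToRaw(key)
    stamp <- charToRaw("19700101000000")
    for (h in which(b == kb[1])) {
      end <- h + length(kb) - 1L
      if (end > length(b) || !identical(b[h:end], kb)) next
      # the date that follows is D:YYYYMMDDHHMMSS, 14 digits
      b[(end + 1L):(end + 14L)] <- stamp
    }
    b
  }
  b <- fix(b, "/CreationDate (D:")
  b <- fix(b, "/ModDate (D:")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(b, con)
  invisible(path)
}

#' Render a per-group QC report document
#'
#' One section per co-temporal map group; per map, a rendered image with its
#' channel-specific colormap and colorbar, one raw trace/retrace line
#' profile (the middle scan line), and any QC flags. Height maps are shown
#' leveled and deflection maps setpoint-subtracted for display, but profiles
#' always show the raw data. A document with zero maps yields a summary page
#' only. With `deterministic = TRUE` (default) identical inputs produce
#' byte-identical output.
#'
#' @param doc an [anasys_document()].
#' @param report the [run_qc()] report for `doc`.
#' @param path output file path.
#' @param format `"pdf"` or `"html"`.
#' @param deterministic fix embedded timestamps for reproducible bytes.
#' @return `path`, invisibly.
#' @export
render_qc_report <- function(doc, report, path, format = c("pdf", "html"),
                             deterministic = TRUE) {
  format <- match.arg(format)
  res <- tryCatch({
    if (format == "html") html_report(doc, report, path)
    else pdf_report(doc, report, path, deterministic)
  }, error = function(e) e)
  if (inherits(res, "error"))
    axz_stop("axz_render_error",
             paste0("cannot render report to '", path, "': ", conditionMessage(res)))
  invisible(path)
}
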