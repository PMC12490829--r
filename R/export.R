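#' @title Export surfaces: map grouping, spectra CSV, metadata tables
#' @name export
NULL

#' Group maps collected at the same time
#'
#' Maps are partitioned by exact timestamp equality (channels of one scan
#' share their acquisition timestamp); a tolerance in seconds is available
#' for instruments that stagger channel writes. Maps without a timestamp
#' form singleton groups. Groups are ordered by timestamp, members by
#' label; every map lands in exactly one group.
#'
#' @param doc an [anasys_document()].
#' @param tolerance_s merge timestamps closer than this many seconds
#'   (default 0 = exact string equality; timestamps must be ISO-8601 to use
#'   a nonzero tolerance).
#' @return list of objects of class `map_group`, each with fields
#'   `timestamp` and `members` (character vector of labels).
#' @export
group_cotemporal_maps <- function(doc, tolerance_s = 0) {
  labels <- sort(names(doc$height_maps), method = "radix")
  if (length(labels) == 0L) return(list())
  stamps <- vapply(doc$height_maps[labels], function(m) m$timestamp %||% "", "")
  keys <- stamps
  blank <- !nzchar(keys)
  keys[blank] <- paste0("\x01singleton\x01", labels[blank])
  if (tolerance_s > 0) {
    tt <- suppressWarnings(as.POSIXct(stamps, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    ord <- order(tt)
    cluster <- keys
    last_t <- NULL
    last_key <- NULL
    for (i in ord) {
      if (is.na(tt[i])) next
      if (!is.null(last_t) && as.numeric(difftime(tt[i], last_t, units = "secs")) <= tolerance_s) {
        cluster[i] <- last_key
      } else {
        cluster[i] <- keys[i]
        last_key <- keys[i]
      }
      last_t <- tt[i]
    }
    keys <- cluster
  }
  split_members <- split(labels, keys)
  group_stamp <- vapply(split_members, function(mem) {
    s <- stamps[match(mem[1], labels)]
    unname(s)
  }, "")
  ord <- order(group_stamp, method = "radix")
  lapply(ord, function(i) {
    structure(list(timestamp = group_stamp[[i]],
                   members = sort(split_members[[i]], method = "radix")),
              class = "map_group")
  })
}

csv_quote <- function(x) {
  need <- grepl('[",\n\r]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

#' Export rendered spectra as CSV text
#'
#' The first column `wavenumber_cm-1` carries the shared axis from
#' [spectrum_axis()]; one column per (spectrum, channel) follows, named
#' `<label>/<channel>`. Values are rendered with 9 significant digits
#' (lossless for float32 data), RFC 4180 quoting, LF line endings. Raw
#' values only — spectra are never processed.
#'
#' @param doc an [anasys_document()].
#' @param labels spectra to export (default: all, in label order).
#' @param channels channels to export (default: every channel present in
#'   the first selected spectrum).
#' @return a single CSV string.
#' @export
spectra_to_csv <- function(doc, labels = NULL, channels = NULL) {
  if (is.null(labels)) labels <- sort(names(doc$spectra), method = "radix")
  missing <- setdiff(labels, names(doc$spectra))
  if (length(missing))
    axz_stop("axz_unknown_label",
             paste0("unknown spectrum label(s): ", paste(missing, collapse = ", ")))
  if (length(labels) == 0L)
    axz_stop("axz_unknown_label", "no spectra selected")
  specs <- doc$spectra[labels]
  if (is.null(channels)) channels <- names(specs[[1]]$channels)
  axis0 <- c(specs[[1]]$wavenumber_start, specs[[1]]$wavenumber_end,
             specs[[1]]$n_points)
  for (s in specs) {
    if (!identical(c(s$wavenumber_start, s$wavenumber_end, s$n_points), axis0))
      axz_stop("axz_mixed_axes",
               sprintf("spectrum '%s' has a different wavenumber axis; export spectra with shared axes only (no resampling)",
                       s$label))
    miss_ch <- setdiff(channels, names(s$channels))
    if (length(miss_ch))
      axz_stop("axz_unknown_channel",
               sprintf("spectrum '%s' lacks channel(s): %s", s$label,
                       paste(miss_ch, collapse = ", ")))
  }
  cols <- list(`wavenumber_cm-1` = spectrum_axis(specs[[1]]))
  for (s in specs) {
    for (ch in channels) {
      cols[[paste0(s$label, "/", ch)]] <- s$channels[[ch]]
    }
  }
  header <- paste(csv_quote(names(cols)), collapse = ",")
  body <- do.call(cbind, lapply(cols, function(v) sprintf("%.9g", v)))
  lines <- apply(body, 1L, paste, collapse = ",")
  paste0(paste(c(header, lines), collapse = "\n"), "\n")
}

#' Tabulate channel-map metadata
#'
#' One row per channel map in label order; requested keys become columns.
#' Keys missing from a map render as empty cells — rows are never dropped.
#'
#' @param doc an [anasys_document()].
#' @param keys metadata keys to show; default is the union of all keys
#'   observed across maps, in first-seen order.
#' @return a character data frame with a leading `label` column.
#' @export
metadata_table <- function(doc, keys = NULL) {
  labels <- sort(names(doc$height_maps), method = "radix")
  if (is.null(keys)) {
    keys <- character(0)
    for (label in labels) {
      keys <- c(keys, setdiff(names(doc$height_maps[[label]]$metadata), keys))
    }
  }
  out <- data.frame(label = labels, stringsAsFactors = FALSE)
  for (k in keys) {
    out[[k]] <- vapply(labels, function(label) {
      md <- doc$height_maps[[label]]$metadata
      if (k %in% names(md)) md[[k]] else ""
    }, "", USE.NAMES = FALSE)
  }
  out
}
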