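#' @title AXZ container and XML serialization
#' @description
#' AXZ-dialect files are XML documents, optionally wrapped in a gzip stream
#' (RFC 1952) or a zip archive; a plain-XML sibling with extension `.axd`
#' is accepted as well. Numeric arrays are embedded as base64 (RFC 4648, no
#' wrapping) of little-endian IEEE-754 float32 values in row-major order.
#' NaN/Inf values are legal and preserved bit-exactly.
#' @name axz_io
NULL

#' Detect the container kind from leading bytes
#'
#' A pure function of the file's magic bytes: gzip starts `1f 8b`, zip starts
#' `PK`, plain XML starts with `<` after an optional UTF-8 BOM and
#' whitespace.
#'
#' @param leading_bytes raw vector, at least 4 bytes.
#' @return one of `"gzip"`, `"zip"`, `"plain_xml"`.
#' @export
detect_container <- function(leading_bytes) {
  b <- as.integer(leading_bytes)
  if (length(b) < 4L)
    axz_stop("axz_unknown_container", "need at least 4 leading bytes to detect container")
  if (b[1] == 0x1f && b[2] == 0x8b) return("gzip")
  if (b[1] == 0x50 && b[2] == 0x4b) return("zip")
  # skip optional BOM then whitespace
  i <- 1L
  if (length(b) >= 3L && b[1] == 0xef && b[2] == 0xbb && b[3] == 0xbf) i <- 4L
  while (i <= length(b) && b[i] %in% c(0x20, 0x09, 0x0a, 0x0d)) i <- i + 1L
  if (i <= length(b) && b[i] == 0x3c) return("plain_xml")  # '<'
  axz_stop("axz_unknown_container", "leading bytes match no supported container (gzip, zip, plain XML)")
}

#' Construct a base64 array payload
#'
#' @param encoded base64 text (canonical, no line wrapping).
#' @param rows,cols grid shape.
#' @param value_type storage type; only `"float32le"` is defined.
#' @return an object of class `array_payload`.
#' @export
array_payload <- function(encoded, rows, cols, value_type = "float32le") {
  structure(list(encoded = encoded, rows = as.integer(rows),
                 cols = as.integer(cols), value_type = value_type),
            class = "array_payload")
}

#' Decode a base64 float32 payload into a numeric grid
#'
#' @param payload an [array_payload()].
#' @return numeric matrix `rows x cols`, filled row-major from the decoded
#'   little-endian float32 stream.
#' @export
decode_array <- function(payload) {
  bytes <- b64_decode(payload$encoded)
  expected <- payload$rows * payload$cols * 4
  if (length(bytes) != expected)
    axz_stop("axz_payload_size_mismatch",
             sprintf("decoded payload has %d bytes, expected %d (%d x %d float32)",
                     length(bytes), expected, payload$rows, payload$cols))
  f32_unpack(bytes, payload$rows, payload$cols)
}

#' Encode a numeric grid as a base64 float32 payload
#'
#' Values are stored as little-endian float32; NaN and Inf are preserved.
#' `decode_array(encode_array(g))` is the identity for any grid of
#' float32-representable values.
#'
#' @param grid numeric matrix.
#' @return an [array_payload()].
#' @export
encode_array <- function(grid) {
  grid <- as.matrix(grid)
  array_payload(b64_encode(f32_pack(grid)), nrow(grid), ncol(grid))
}

## ---- XML writing ----------------------------------------------------------

add_payload_node <- function(parent, name, grid, extra_attrs = character(0)) {
  p <- encode_array(grid)
  node <- xml2::xml_add_child(parent, name)
  xml2::xml_set_attrs(node, c(extra_attrs, Rows = as.character(p$rows),
                              Cols = as.character(p$cols),
                              ValueType = p$value_type))
  xml2::xml_set_text(node, p$encoded)
  node
}

add_metadata_node <- function(parent, metadata, attr_keys) {
  extra <- metadata[!(names(metadata) %in% attr_keys)]
  if (length(extra) == 0L) return(invisible(NULL))
  meta <- xml2::xml_add_child(parent, "Metadata")
  for (k in names(extra)) {
    e <- xml2::xml_add_child(meta, "Entry")
    xml2::xml_set_attr(e, "Key", k)
    xml2::xml_set_text(e, extra[[k]])
  }
  invisible(NULL)
}

# attribute keys each element type serializes from its metadata map
.image_attr_keys <- c("Label", "CenterX", "CenterY", "SizeX", "SizeY")
.map_attr_keys <- c("Label", "DataChannel", "Units", "CenterX", "CenterY",
                    "SizeX", "SizeY", "TimeStamp", "IRWavenumber",
                    "DeflectionSetpoint", "PhaseSetpoint", "PLLRangeMin",
                    "PLLRangeMax", "ScanRate")
.spectrum_attr_keys <- c("Label", "LocationX", "LocationY", "StartWavenumber",
                         "EndWavenumber", "DataPoints")
.doc_attr_keys <- c("FormatVersion", "Created")

set_attrs_from_metadata <- function(node, metadata, keys) {
  present <- keys[keys %in% names(metadata)]
  xml2::xml_set_attrs(node, metadata[present])
}

document_to_xml <- function(doc) {
  x <- xml2::xml_new_root("Document")
  set_attrs_from_metadata(x, doc$file_metadata, .doc_attr_keys)
  add_metadata_node(x, doc$file_metadata, .doc_attr_keys)

  images <- xml2::xml_add_child(x, "Images")
  for (img in doc$images) {
    n <- xml2::xml_add_child(images, "OpticalImage")
    set_attrs_from_metadata(n, img$metadata, .image_attr_keys)
    d <- dim(img$pixels)
    bytes <- as.raw(as.vector(aperm(img$pixels, c(3, 2, 1))))
    pn <- xml2::xml_add_child(n, "PixelsBase64")
    xml2::xml_set_attrs(pn, c(Rows = as.character(d[1]), Cols = as.character(d[2])))
    xml2::xml_set_text(pn, b64_encode(bytes))
    add_metadata_node(n, img$metadata, .image_attr_keys)
  }

  maps <- xml2::xml_add_child(x, "HeightMaps")
  for (m in doc$height_maps) {
    n <- xml2::xml_add_child(maps, "HeightMap")
    set_attrs_from_metadata(n, m$metadata, .map_attr_keys)
    add_payload_node(n, "SampleBase64", m$trace, c(Direction = "Trace"))
    if (!is.null(m$retrace))
      add_payload_node(n, "SampleBase64", m$retrace, c(Direction = "Retrace"))
    add_metadata_node(n, m$metadata, .map_attr_keys)
  }

  spectra <- xml2::xml_add_child(x, "RenderedSpectra")
  for (s in doc$spectra) {
    n <- xml2::xml_add_child(spectra, "Spectrum")
    set_attrs_from_metadata(n, s$metadata, .spectrum_attr_keys)
    for (ch in names(s$channels)) {
      add_payload_node(n, "SampleBase64",
                       matrix(s$channels[[ch]], nrow = 1L),
                       c(Channel = ch))
    }
    add_metadata_node(n, s$metadata, .spectrum_attr_keys)
  }
  x
}

#' Write a document to an AXZ-dialect file
#'
#' The document must pass [validate_document()]. Reading the file back with
#' [read_axz()] reproduces the document: metadata string-equal, arrays
#' bit-exact (values are stored as float32, so grids should hold
#' float32-representable values, as all documents read from files and all
#' synthetic documents do).
#'
#' @param doc an [anasys_document()].
#' @param path output path.
#' @param container `"gzip"` (default), `"zip"`, or `"plain_xml"`.
#' @return `path`, invisibly.
#' @export
write_axz <- function(doc, path, container = c("gzip", "zip", "plain_xml")) {
  container <- match.arg(container)
  v <- validate_document(doc)
  if (length(v))
    axz_stop("axz_validation_error",
             paste0("document fails validation: ", paste(v, collapse = "; ")))
  xml <- document_to_xml(doc)
  txt <- as.character(xml)
  bytes <- charToRaw(txt)
  ok <- tryCatch({
    switch(container,
      gzip = {
        con <- gzfile(path, "wb")
        on.exit(close(con), add = TRUE)
        writeBin(bytes, con)
      },
      zip = zip_write_single(path, "document.axd", bytes),
      plain_xml = {
        con <- file(path, "wb")
        on.exit(close(con), add = TRUE)
        writeBin(bytes, con)
      })
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    axz_stop("axz_serialization_error",
             paste0("cannot write '", path, "': ", conditionMessage(ok)))
  invisible(path)
}

## ---- XML parsing ----------------------------------------------------------

num_attr <- function(a, key) {
  if (key %in% names(a)) unname(as.numeric(a[[key]])) else NULL
}

parse_payload_node <- function(node, label) {
  a <- xml2::xml_attrs(node)
  rows <- as.integer(a[["Rows"]])
  cols <- as.integer(a[["Cols"]])
  p <- array_payload(xml2::xml_text(node), rows, cols,
                     if ("ValueType" %in% names(a)) a[["ValueType"]] else "float32le")
  tryCatch(decode_array(p), error = function(e) {
    axz_stop(class(e)[1],
             sprintf("in element '%s': %s", label, conditionMessage(e)))
  })
}

# metadata = element attributes (verbatim, document order) + <Metadata> entries
# + unknown child elements (lenient mode) under their element name
collect_metadata <- function(node, known_children, strict) {
  meta <- xml2::xml_attrs(node)
  for (child in xml2::xml_children(node)) {
    nm <- xml2::xml_name(child)
    if (nm %in% known_children) next
    if (nm == "Metadata") {
      for (e in xml2::xml_children(child)) {
        k <- xml2::xml_attr(e, "Key")
        val <- stats::setNames(xml2::xml_text(e), k)
        meta <- c(meta, val)
      }
    } else if (strict) {
      axz_stop("axz_xml_parse_error",
               sprintf("unknown element <%s> under <%s> (strict mode)",
                       nm, xml2::xml_name(node)))
    } else {
      meta <- c(meta, stats::setNames(xml2::xml_text(child), nm))
    }
  }
  meta
}

parse_image_node <- function(node, strict) {
  a <- xml2::xml_attrs(node)
  meta <- collect_metadata(node, "PixelsBase64", strict)
  pn <- xml2::xml_find_first(node, "./PixelsBase64")
  rows <- as.integer(xml2::xml_attr(pn, "Rows"))
  cols <- as.integer(xml2::xml_attr(pn, "Cols"))
  bytes <- b64_decode(xml2::xml_text(pn))
  if (length(bytes) != rows * cols * 3L)
    axz_stop("axz_payload_size_mismatch",
             sprintf("in optical image '%s': pixel payload has %d bytes, expected %d",
                     a[["Label"]], length(bytes), rows * cols * 3L))
  pixels <- aperm(array(as.integer(bytes), dim = c(3L, cols, rows)), c(3, 2, 1))
  optical_image(label = unname(a[["Label"]]), pixels = pixels,
                center_xy = c(num_attr(a, "CenterX"), num_attr(a, "CenterY")),
                extent_xy = c(num_attr(a, "SizeX"), num_attr(a, "SizeY")),
                metadata = meta)
}

parse_map_node <- function(node, strict) {
  a <- xml2::xml_attrs(node)
  label <- unname(a[["Label"]])
  meta <- collect_metadata(node, "SampleBase64", strict)
  trace <- NULL
  retrace <- NULL
  for (pn in xml2::xml_find_all(node, "./SampleBase64")) {
    dir <- xml2::xml_attr(pn, "Direction")
    grid <- parse_payload_node(pn, label)
    if (identical(dir, "Retrace")) retrace <- grid else trace <- grid
  }
  pll_min <- num_attr(a, "PLLRangeMin")
  channel_map(label = label,
              channel = unname(a[["DataChannel"]]),
              trace = trace, retrace = retrace,
              units = unname(a[["Units"]] %||% ""),
              center_xy = c(num_attr(a, "CenterX"), num_attr(a, "CenterY")),
              size_xy = c(num_attr(a, "SizeX"), num_attr(a, "SizeY")),
              timestamp = unname(a[["TimeStamp"]] %||% ""),
              ir_wavenumber = num_attr(a, "IRWavenumber"),
              deflection_setpoint = num_attr(a, "DeflectionSetpoint"),
              phase_setpoint = num_attr(a, "PhaseSetpoint"),
              pll_range = if (is.null(pll_min)) NULL else c(pll_min, num_attr(a, "PLLRangeMax")),
              scan_rate = num_attr(a, "ScanRate"),
              metadata = meta)
}

parse_spectrum_node <- function(node, strict) {
  a <- xml2::xml_attrs(node)
  label <- unname(a[["Label"]])
  meta <- collect_metadata(node, "SampleBase64", strict)
  channels <- list()
  for (pn in xml2::xml_find_all(node, "./SampleBase64")) {
    ch <- xml2::xml_attr(pn, "Channel")
    channels[[ch]] <- as.numeric(parse_payload_node(pn, label))
  }
  ir_spectrum(label = label,
              location_xy = c(num_attr(a, "LocationX"), num_attr(a, "LocationY")),
              wavenumber_start = num_attr(a, "StartWavenumber"),
              wavenumber_end = num_attr(a, "EndWavenumber"),
              n_points = as.integer(num_attr(a, "DataPoints")),
              channels = channels, metadata = meta)
}

xml_to_document <- function(x, strict) {
  root <- xml2::xml_root(x)
  file_meta <- collect_metadata(root, c("Images", "HeightMaps", "RenderedSpectra"), strict)
  images <- list()
  for (n in xml2::xml_find_all(root, "./Images/OpticalImage")) {
    img <- parse_image_node(n, strict)
    images[[img$label]] <- img
  }
  maps <- list()
  for (n in xml2::xml_find_all(root, "./HeightMaps/HeightMap")) {
    m <- parse_map_node(n, strict)
    maps[[m$label]] <- m
  }
  spectra <- list()
  for (n in xml2::xml_find_all(root, "./RenderedSpectra/Spectrum")) {
    s <- parse_spectrum_node(n, strict)
    spectra[[s$label]] <- s
  }
  anasys_document(images = images, height_maps = maps, spectra = spectra,
                  file_metadata = file_meta)
}

zip_pick_member <- function(path) {
  listing <- tryCatch(utils::unzip(path, list = TRUE),
                      error = function(e) axz_stop("axz_xml_parse_error",
                        paste0("cannot read zip archive: ", conditionMessage(e))))
  nms <- listing$Name
  axd <- nms[grepl("\\.axd$", nms)]
  if (length(axd)) return(axd[[1]])
  if (length(nms) == 1L) return(nms[[1]])
  axz_stop("axz_xml_parse_error",
           "zip archive has multiple members and none ends in '.axd'")
}

#' Read an AXZ-dialect file into a document
#'
#' Detects the container (gzip, zip, or plain XML) from the file's magic
#' bytes, decompresses, parses the embedded XML and decodes every base64
#' array. Every XML attribute and metadata entry appears verbatim in the
#' owning object's metadata map; the parsed document is independent of the
#' container kind.
#'
#' @param path input file.
#' @param max_size maximum accepted file size in bytes, checked before
#'   decompression (default 200 MB, the tool's ingest limit).
#' @param strict if `TRUE`, unknown XML elements under known parents are an
#'   error; by default they are preserved into the owner's metadata map.
#' @return an [anasys_document()] passing [validate_document()].
#' @export
read_axz <- function(path, max_size = 200e6, strict = FALSE) {
  if (!file.exists(path))
    axz_stop("axz_file_not_found", paste0("file not found: ", path))
  sz <- file.size(path)
  if (sz > max_size)
    axz_stop("axz_file_too_large",
             sprintf("file is %.0f bytes, above the %.0f byte ingest limit", sz, max_size))
  head_bytes <- readBin(path, raw(), n = 8L)
  kind <- detect_container(head_bytes)
  bytes <- switch(kind,
    gzip = {
      con <- gzfile(path, "rb")
      on.exit(close(con), add = TRUE)
      read_all_bytes(con)
    },
    zip = {
      member <- zip_pick_member(path)
      con <- unz(path, member, open = "rb")
      on.exit(close(con), add = TRUE)
      read_all_bytes(con)
    },
    plain_xml = readBin(path, raw(), n = sz))
  x <- tryCatch(xml2::read_xml(rawToChar(bytes)),
                error = function(e) axz_stop("axz_xml_parse_error",
                  paste0("XML parse failure: ", conditionMessage(e))))
  doc <- xml_to_document(x, strict = strict)
  v <- validate_document(doc)
  if (length(v))
    axz_stop("axz_validation_error",
             paste0("parsed document fails validation: ", paste(v, collapse = "; ")))
  doc
}
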