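# Internal helpers: error conditions, numeric formatting, base64, float32
# packing, CRC-32 and a minimal single-member zip writer.

axz_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "axz_error", "error", "condition")))
}

# %.17g round-trips doubles exactly through strtod
fmt_num <- function(x) sprintf("%.17g", x)

b64_encode <- function(bytes) {
  gsub("[\r\n]", "", jsonlite::base64_enc(bytes))
}

b64_decode <- function(txt) {
  tryCatch(jsonlite::base64_dec(txt),
           error = function(e) axz_stop("axz_base64_error",
                                        paste0("invalid base64 payload: ", conditionMessage(e))))
}

# float32 little-endian packing; R matrices are column-major, payloads row-major
f32_pack <- function(grid) {
  writeBin(as.numeric(t(grid)), raw(), size = 4L, endian = "little")
}

f32_unpack <- function(bytes, rows, cols) {
  v <- readBin(bytes, "numeric", n = rows * cols, size = 4L, endian = "little")
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
}

# snap doubles to the nearest float32 value (what a payload round trip yields)
as_float32 <- function(x) {
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
               "numeric", n = length(x), size = 4L, endian = "little")
  if (is.matrix(x)) dim(y) <- dim(x)
  y
}

u16le <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L))

u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

.crc_table <- local({
  tab <- integer(256L)
  for (n in 0:255) {
    crc <- n
    for (k in 1:8) {
      crc <- if (bitwAnd(crc, 1L) != 0L) {
        bitwXor(bitwShiftR(crc, 1L), -306674912L)  # 0xEDB88320
      } else {
        bitwShiftR(crc, 1L)
      }
    }
    tab[n + 1L] <- crc
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   .crc_table[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 4294967296 else as.numeric(crc)
}

# Minimal PKZIP archive with one stored (uncompressed) member. Fixed DOS
# timestamp (1980-01-01) keeps output deterministic.
zip_write_single <- function(path, name, data) {
  crc <- crc32(data)
  n <- length(data)
  nm <- charToRaw(name)
  lfh <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)),
           u16le(20L), u16le(0L), u16le(0L),          # version, flags, method=store
           u16le(0L), u16le(0x21L),                   # mod time, mod date
           u32le(crc), u32le(n), u32le(n),
           u16le(length(nm)), u16le(0L), nm)
  cdh <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)),
           u16le(20L), u16le(20L), u16le(0L), u16le(0L),
           u16le(0L), u16le(0x21L),
           u32le(crc), u32le(n), u32le(n),
           u16le(length(nm)), u16le(0L), u16le(0L),
           u16le(0L), u16le(0L), u32le(0L), u32le(0L), nm)
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),
            u16le(0L), u16le(0L), u16le(1L), u16le(1L),
            u32le(length(cdh)), u32le(length(lfh) + n), u16le(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(lfh, data, cdh, eocd), con)
  invisible(path)
}

read_all_bytes <- function(con, chunk = 1048576L) {
  out <- list()
  repeat {
    b <- readBin(con, raw(), n = chunk)
    if (length(b) == 0L) break
    out[[length(out) + 1L]] <- b
  }
  do.call(c, c(out, list(raw(0))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
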