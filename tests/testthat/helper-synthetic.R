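# Small synthetic documents keep the suite fast; the generator's scientific
# defaults (64 x 64, five channels, amide-band spectra) are exercised where a
# test depends on them.
small_spec <- function(seed = 1L, ...) {
  synthetic_spec(seed = seed, rows = 16L, cols = 16L, n_map_groups = 1L,
                 n_spectra = 1L, spectrum_points = 64L, ...)
}

read_file_bytes <- function(path) readBin(path, raw(), file.size(path))

# independent per-line leveling oracle: closed-form OLS over 0-based index
oracle_level_line <- function(v) {
  j <- seq_along(v) - 1
  ok <- is.finite(v)
  if (sum(ok) < 2) return(v)
  mj <- mean(j[ok]); mv <- mean(v[ok])
  slope <- sum((j[ok] - mj) * (v[ok] - mv)) / sum((j[ok] - mj)^2)
  intercept <- mv - slope * mj
  v - (intercept + slope * j)
}
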