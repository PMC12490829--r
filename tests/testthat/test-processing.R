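make_height <- function(trace, retrace = NULL, cols = ncol(trace)) {
  channel_map("h", "Height", trace = trace, retrace = retrace, units = "nm",
              center_xy = c(0, 0), size_xy = c(10, 10),
              timestamp = "2024-01-01T00:00:00")
}

test_that("per-line leveling removes exactly linear lines and constants", {
  ramp <- outer(rep(1, 6), 0:7) * 3.5 + 2       # value = 3.5 j + 2 on every line
  lv <- level_height(make_height(ramp))
  expect_lt(max(abs(lv$trace)), 1e-12)
  lv0 <- level_height(make_height(matrix(7, 5, 5)))
  expect_lt(max(abs(lv0$trace)), 1e-12)
  expect_identical(unname(lv$metadata[["processing"]]), "line_linear_fit")
})

test_that("leveling matches an independent per-line OLS oracle", {
  set.seed(42)
  for (rep in 1:5) {
    g <- matrix(rnorm(48, sd = 10), 6, 8) + outer(rnorm(6), 0:7)
    g[2, 5] <- g[2, 5] + 100   # spike on one line
    lv <- level_height(make_height(g))
    expected <- t(apply(g, 1, oracle_level_line))
    expect_equal(lv$trace, expected, tolerance = 1e-12)
  }
})

test_that("leveling is idempotent, NaN-aware and never modifies its input", {
  doc <- make_document(small_spec(seed = 6))
  h <- doc$height_maps[[grep("Height", names(doc$height_maps), value = TRUE)]]
  snapshot <- h
  lv <- level_height(h)
  expect_identical(h, snapshot)
  lv2 <- level_height(lv)
  expect_lt(max(abs(lv2$trace - lv$trace)), 1e-10)
  expect_identical(dim(lv$trace), dim(h$trace))

  g <- matrix(1:24 + 0, 4, 6)
  g[1, ] <- NaN                    # no finite pixels: passes through
  g[2, 3:6] <- NaN                 # fit on remaining pixels only
  lv <- level_height(make_height(g))
  expect_true(all(is.nan(lv$trace[1, ])))
  expect_equal(lv$trace[2, 1:2], oracle_level_line(g[2, ])[1:2], tolerance = 1e-12)
})

test_that("plane leveling removes an exact plane", {
  jj <- outer(rep(1, 6), 0:7)
  ii <- outer(0:5, rep(1, 8))
  lv <- level_height(make_height(2 * jj - 3 * ii + 11), method = "plane")
  expect_lt(max(abs(lv$trace)), 1e-10)
  expect_identical(unname(lv$metadata[["processing"]]), "plane_fit")
})

test_that("setpoint subtraction shifts every pixel by the stored setpoint", {
  mk <- function(g, sp = 0.5)
    channel_map("d", "Deflection", trace = g, retrace = g + 0.001, units = "V",
                size_xy = c(5, 5), deflection_setpoint = sp)
  out <- subtract_setpoint(mk(matrix(0.5, 4, 4)))
  expect_identical(out$trace, matrix(0, 4, 4))
  out <- subtract_setpoint(mk(matrix(0.52, 4, 4)))
  expect_equal(out$trace, matrix(0.02, 4, 4), tolerance = 1e-15)
  set.seed(7)
  g <- matrix(rnorm(16, 0.5, 0.05), 4, 4)
  out <- subtract_setpoint(mk(g))
  expect_identical(out$trace, g - 0.5)
  expect_identical(out$retrace, g + 0.001 - 0.5)
  expect_identical(unname(out$metadata[["processing"]]), "setpoint_subtraction")
  expect_error(subtract_setpoint(mk(g, sp = NULL)), class = "axz_missing_setpoint")
  expect_error(subtract_setpoint(make_height(g)), class = "axz_wrong_channel")
})

test_that("level_height refuses non-height channels", {
  m <- channel_map("d", "Deflection", trace = matrix(0, 4, 4), units = "V",
                   size_xy = c(1, 1), deflection_setpoint = 0.5)
  expect_error(level_height(m), class = "axz_wrong_channel")
})

test_that("line profiles copy raw values and pixel-center positions", {
  doc <- make_document(small_spec(seed = 8))
  h <- doc$height_maps[[grep("Height", names(doc$height_maps), value = TRUE)]]
  pr <- extract_profile(h, 1)
  expect_identical(pr$trace_values, h$trace[1, ])
  expect_identical(pr$retrace_values, h$retrace[1, ])
  # profiles of a leveled map differ from the raw map's when slopes exist
  pr_lv <- extract_profile(level_height(h), 1)
  expect_false(isTRUE(all.equal(pr$trace_values, pr_lv$trace_values)))
  # pixel centers: cols = 4, center 0, size 4 um
  m <- channel_map("m", "Height", trace = matrix(0, 2, 4), units = "nm",
                   center_xy = c(0, 0), size_xy = c(4, 2))
  expect_equal(extract_profile(m, 1)$positions, c(-1.5, -0.5, 0.5, 1.5))
  expect_error(extract_profile(m, 0), class = "axz_index_out_of_range")
  expect_error(extract_profile(m, 3), class = "axz_index_out_of_range")
})

test_that("labeled maps carry coordinates, attributes, and bit-identical values", {
  doc <- make_document(small_spec(seed = 9))
  amp <- doc$height_maps[[grep("IRAmplitude", names(doc$height_maps), value = TRUE)]]
  lm <- to_labeled_map(amp)
  expect_length(lm$coord_x, ncol(amp$trace))
  expect_length(lm$coord_y, nrow(amp$trace))
  expect_identical(lm$values, amp$trace)
  expect_identical(unname(lm$attrs[["units"]]), amp$units)
  expect_identical(unname(lm$attrs[["ir_wavenumber"]]), "1655")
  m <- channel_map("m", "Height", trace = matrix(0, 3, 10), units = "nm",
                   center_xy = c(5, 0), size_xy = c(10, 3))
  expect_equal(to_labeled_map(m)$coord_x, seq(0.5, 9.5, by = 1))
  m$retrace <- NULL
  expect_error(to_labeled_map(m, "retrace"), class = "axz_missing_direction")
})

test_that("spectrum axes are linear, inclusive, and may descend", {
  sp <- ir_spectrum("s", c(0, 0), 1000, 1004, 5,
                    channels = list(A = rep(0, 5)))
  expect_equal(spectrum_axis(sp), 1000:1004)
  sp2 <- ir_spectrum("s", c(0, 0), 1800, 1000, 2,
                     channels = list(A = c(0, 0)))
  expect_equal(spectrum_axis(sp2), c(1800, 1000))
  for (n in c(2, 5, 17)) {
    sp3 <- ir_spectrum("s", c(0, 0), 950, 1850, n,
                       channels = list(A = rep(0, n)))
    expect_equal(mean(spectrum_axis(sp3)), (950 + 1850) / 2)
  }
})
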