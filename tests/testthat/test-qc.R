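defl_map <- function(dev, sp = 0.5, rows = 8, cols = 8, retrace = TRUE) {
  g <- matrix(sp + dev, rows, cols)
  channel_map("d", "Deflection", trace = g,
              retrace = if (retrace) g else NULL, units = "V",
              size_xy = c(1, 1), deflection_setpoint = sp)
}

phase_map <- function(dev, sp = 90) {
  g <- matrix(sp + dev, 8, 8)
  channel_map("p", "IRPhase", trace = g, retrace = g, units = "degrees",
              size_xy = c(1, 1), phase_setpoint = sp)
}

pll_map <- function(values, range = c(180, 220)) {
  channel_map("f", "PLLFrequency", trace = values, units = "kHz",
              size_xy = c(1, 1), pll_range = range)
}

test_that("AFM tracking flags uniform deviations past 0.01 V and not at the setpoint", {
  fl <- qc_afm_tracking(defl_map(0.02))
  expect_identical(fl$rule_id, "AFM_TRACKING")
  expect_identical(fl$severity, "fail")
  expect_identical(fl$exceed_fraction, 1)
  expect_equal(fl$measured, 0.02, tolerance = 1e-12)
  expect_null(qc_afm_tracking(defl_map(0)))
  hm <- channel_map("h", "Height", trace = matrix(0, 4, 4), units = "nm",
                    size_xy = c(1, 1))
  expect_error(qc_afm_tracking(hm), class = "axz_wrong_channel")
  m <- defl_map(0.02)
  m$deflection_setpoint <- NULL
  expect_error(qc_afm_tracking(m), class = "axz_missing_setpoint")
})

test_that("phase deviations are wrapped to (-180, 180] before comparison", {
  expect_identical(qc_pll_phase(phase_map(25))$rule_id, "PLL_PHASE")
  expect_null(qc_pll_phase(phase_map(0)))
  # +350 degrees wraps to -10, inside the 20 degree tolerance
  expect_null(qc_pll_phase(phase_map(350)))
  # -350 wraps to +10; +190 wraps to -170 and flags
  expect_null(qc_pll_phase(phase_map(-350)))
  expect_identical(qc_pll_phase(phase_map(190))$rule_id, "PLL_PHASE")
})

test_that("PLL saturation flags when enough pixels pin at a range limit", {
  base <- matrix(200, 10, 10)
  sat10 <- base; sat10[1:10] <- 220          # 10% at the maximum
  expect_identical(qc_pll_saturation(pll_map(sat10))$rule_id, "PLL_SATURATION")
  expect_null(qc_pll_saturation(pll_map(base)))
  all_min <- matrix(180, 4, 4)
  fl <- qc_pll_saturation(pll_map(all_min))
  expect_identical(fl$exceed_fraction, 1)
  sat4 <- base; sat4[1:4] <- 220             # 4% stays under the 5% trigger
  expect_null(qc_pll_saturation(pll_map(sat4)))
  m <- pll_map(base); m$pll_range <- NULL
  expect_error(qc_pll_saturation(m), class = "axz_missing_range")
})

test_that("apparent processing detects flattened maps and spares raw ones", {
  doc <- make_document(small_spec(seed = 10))
  h <- doc$height_maps[[grep("Height", names(doc$height_maps), value = TRUE)]]
  lv <- level_height(h)
  fl <- qc_apparent_processing(lv)
  expect_identical(fl$rule_id, "APPARENT_PROCESSING")
  expect_identical(fl$severity, "warn")
  expect_null(qc_apparent_processing(h))  # raw map has ~50 nm line means
  zero <- channel_map("z", "Height", trace = matrix(0, 4, 4), units = "nm",
                      size_xy = c(1, 1))
  fl0 <- qc_apparent_processing(zero)
  expect_identical(fl0$measured, 0)
  phase <- phase_map(0)
  expect_error(qc_apparent_processing(phase), class = "axz_wrong_channel")
})

test_that("flagging is monotone in the injected deviation", {
  devs <- c(0.001, 0.005, 0.009, 0.011, 0.02, 0.05, 0.1)
  flagged <- vapply(devs, function(d) !is.null(qc_afm_tracking(defl_map(d))), TRUE)
  expect_true(all(diff(as.integer(flagged)) >= 0))  # never un-flags as deviation grows
  expect_identical(flagged, devs > 0.01)
  pdevs <- c(1, 10, 19, 21, 45, 90, 179)
  pflag <- vapply(pdevs, function(d) !is.null(qc_pll_phase(phase_map(d))), TRUE)
  expect_true(all(diff(as.integer(pflag)) >= 0))
})

test_that("bisection recovers the configured thresholds sharply", {
  expect_lt(abs(qc_flag_boundary("deflection", tol = 1e-6) - 0.01), 1e-6)
  expect_lt(abs(qc_flag_boundary("phase", upper = 90, tol = 1e-4) - 20), 1e-4)
  # a custom configuration moves the boundary with it
  cfg <- qc_config(deflection_threshold = 0.025)
  expect_lt(abs(qc_flag_boundary("deflection", cfg, tol = 1e-6) - 0.025), 1e-6)
})

test_that("NaN pixels are excluded from every fraction's denominator", {
  g <- matrix(0.5, 10, 10)
  g[1:80] <- NaN
  g[81:100] <- 0.53          # all finite pixels offend
  m <- channel_map("d", "Deflection", trace = g, units = "V",
                   size_xy = c(1, 1), deflection_setpoint = 0.5)
  fl <- qc_afm_tracking(m)
  expect_identical(fl$exceed_fraction, 1)
  sat <- matrix(NaN, 10, 10)
  sat[1:20] <- 220; sat[21:30] <- 200   # 20 of 30 finite pixels saturated
  fl <- qc_pll_saturation(pll_map(sat))
  expect_equal(fl$exceed_fraction, 2 / 3, tolerance = 1e-12)
})

test_that("run_qc is deterministic, ordered by (label, rule), and pure", {
  doc <- make_document(synthetic_spec(
    seed = 12, rows = 16, cols = 16, n_map_groups = 2, n_spectra = 1,
    spectrum_points = 64,
    artifacts = list(artifact_injection("deflection_error", 1),
                     artifact_injection("phase_error", 2))))
  snapshot <- doc
  r1 <- run_qc(doc)
  r2 <- run_qc(doc)
  expect_identical(r1, r2)
  expect_identical(doc, snapshot)
  df <- qc_flags_df(r1)
  expect_identical(df$rule_id, c("AFM_TRACKING", "PLL_PHASE"))
  expect_identical(df$target_label,
                   c("group01/Deflection", "group02/IRPhase"))
  expect_false(is.unsorted(df$target_label))
  # 2 groups x (Height, Deflection, PLL apparent-processing) + tracking + phase + saturation
  expect_identical(r1$n_maps_checked, 12L)
  expect_error(run_qc("not a doc"), class = "axz_validation_error")
})
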