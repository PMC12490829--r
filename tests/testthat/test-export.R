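doc_with_stamps <- function(stamps) {
  maps <- list()
  for (i in seq_along(stamps)) {
    lbl <- sprintf("m%02d", i)
    maps[[lbl]] <- channel_map(lbl, "Height", trace = matrix(i, 4, 4),
                               units = "nm", size_xy = c(1, 1),
                               timestamp = stamps[i])
  }
  anasys_document(height_maps = maps)
}

test_that("co-temporal grouping partitions maps by timestamp", {
  doc <- doc_with_stamps(c("2024-01-01T10:00:00", "2024-01-01T10:00:00",
                           "2024-01-01T10:00:00", "2024-01-01T10:05:00",
                           "2024-01-01T10:05:00"))
  groups <- group_cotemporal_maps(doc)
  expect_length(groups, 2L)
  expect_length(groups[[1]]$members, 3L)
  expect_length(groups[[2]]$members, 2L)
  # partition: every map in exactly one group
  all_members <- unlist(lapply(groups, function(g) g$members))
  expect_setequal(all_members, names(doc$height_maps))
  expect_identical(anyDuplicated(all_members), 0L)

  expect_identical(group_cotemporal_maps(anasys_document()), list())
  single <- group_cotemporal_maps(doc_with_stamps("2024-01-01T09:00:00"))
  expect_length(single, 1L)
  expect_identical(single[[1]]$members, "m01")
  # maps without timestamps form singleton groups
  blank <- group_cotemporal_maps(doc_with_stamps(c("", "")))
  expect_length(blank, 2L)
})

test_that("a timestamp tolerance merges staggered channel writes", {
  doc <- doc_with_stamps(c("2024-01-01T10:00:00", "2024-01-01T10:00:01",
                           "2024-01-01T10:01:00"))
  expect_length(group_cotemporal_maps(doc), 3L)
  expect_length(group_cotemporal_maps(doc, tolerance_s = 2), 2L)
})

test_that("CSV export is lossless at 9 significant digits with the documented layout", {
  doc <- make_document(synthetic_spec(seed = 41, rows = 8, cols = 8,
                                      n_map_groups = 1, n_spectra = 2,
                                      spectrum_points = 5))
  txt <- spectra_to_csv(doc)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  expect_length(lines, 6L)  # header + n_points
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  expect_length(header, 1L + 2L * 3L)  # axis + spectra x channels
  expect_identical(header[1], "wavenumber_cm-1")
  expect_true(all(grepl("^spectrum[0-9]+/", header[-1])))
  parsed <- utils::read.csv(text = txt, check.names = FALSE)
  for (lbl in names(doc$spectra)) {
    for (ch in names(doc$spectra[[lbl]]$channels)) {
      orig <- doc$spectra[[lbl]]$channels[[ch]]
      got <- parsed[[paste0(lbl, "/", ch)]]
      expect_lt(max(abs(got - orig) / pmax(abs(orig), 1e-12)), 1e-8)
    }
  }
  expect_equal(parsed[["wavenumber_cm-1"]], spectrum_axis(doc$spectra[[1]]))
})

test_that("CSV export rejects unknown selections and mixed axes", {
  doc <- make_document(synthetic_spec(seed = 42, rows = 8, cols = 8,
                                      n_map_groups = 1, n_spectra = 2,
                                      spectrum_points = 16))
  expect_error(spectra_to_csv(doc, labels = "nope"), class = "axz_unknown_label")
  expect_error(spectra_to_csv(doc, channels = "Kelvin"),
               class = "axz_unknown_channel")
  doc$spectra$spectrum02$wavenumber_end <- 1900
  expect_error(spectra_to_csv(doc), class = "axz_mixed_axes")
})

test_that("column names containing the CSV delimiter are RFC 4180 quoted", {
  sp <- ir_spectrum("odd,label", c(0, 0), 1000, 1010, 3,
                    channels = list(A = c(1, 2, 3)))
  doc <- anasys_document(spectra = list(`odd,label` = sp))
  txt <- spectra_to_csv(doc)
  expect_match(strsplit(txt, "\n")[[1]][1], '"odd,label/A"', fixed = TRUE)
})

test_that("metadata tables keep one row per map and never drop rows", {
  doc <- make_document(synthetic_spec(seed = 43, rows = 8, cols = 8,
                                      n_map_groups = 1, n_spectra = 1,
                                      spectrum_points = 16))
  tab <- metadata_table(doc, keys = c("Units", "TimeStamp"))
  expect_identical(dim(tab), c(5L, 3L))
  expect_identical(tab$label, sort(names(doc$height_maps)))
  expect_true(all(nzchar(tab$Units)))
  # a key absent from every map still yields a (blank) column, not an error
  tab2 <- metadata_table(doc, keys = c("Units", "NoSuchKey"))
  expect_identical(tab2$NoSuchKey, rep("", 5L))
  # default column set is the union of observed metadata keys
  tab3 <- metadata_table(doc)
  union_keys <- unique(unlist(lapply(doc$height_maps, function(m) names(m$metadata))))
  expect_setequal(setdiff(names(tab3), "label"), union_keys)
})

test_that("QC report files have one section per group and deterministic bytes", {
  doc <- make_document(synthetic_spec(seed = 44, rows = 16, cols = 16,
                                      n_map_groups = 2, n_spectra = 1,
                                      spectrum_points = 32))
  rep <- run_qc(doc)
  p1 <- tempfile(fileext = ".html")
  p2 <- tempfile(fileext = ".html")
  render_qc_report(doc, rep, p1, format = "html")
  render_qc_report(doc, rep, p2, format = "html")
  html <- rawToChar(read_file_bytes(p1))
  expect_identical(lengths(regmatches(html, gregexpr("<section>", html))), 2L)
  expect_identical(read_file_bytes(p1), read_file_bytes(p2))

  pp1 <- tempfile(fileext = ".pdf")
  pp2 <- tempfile(fileext = ".pdf")
  render_qc_report(doc, rep, pp1, format = "pdf")
  render_qc_report(doc, rep, pp2, format = "pdf")
  expect_gt(file.size(pp1), 1000)
  expect_identical(read_file_bytes(pp1), read_file_bytes(pp2))

  empty <- anasys_document()
  p3 <- tempfile(fileext = ".html")
  render_qc_report(empty, run_qc(empty), p3, format = "html")
  expect_match(rawToChar(read_file_bytes(p3)), "summary only")
  unlink(c(p1, p2, pp1, pp2, p3))
})
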