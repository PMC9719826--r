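test_that("spectrum canonicalization sorts and merges duplicate m/z", {
  s <- spectrum(c(200, 100, 100), c(10, 5, 7))
  expect_equal(s$mz, c(100, 200))
  expect_equal(s$intensity, c(12, 10))
  expect_error(spectrum(numeric(0), numeric(0)), "at least one peak")
  expect_error(spectrum(c(100), c(-1)), "non-negative")
})

test_that("MSP records round-trip field-wise", {
  lib <- toy_library()
  lib[[1]]$metadata <- list(comment = "synthetic spectrum")
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, path)
  back <- read_msp(path)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$name, lib[[i]]$name)
    expect_equal(back[[i]]$identifier, lib[[i]]$identifier)
    expect_equal(format(back[[i]]$formula), format(lib[[i]]$formula))
    expect_equal(back[[i]]$retention_index, lib[[i]]$retention_index, tolerance = 1e-9)
    expect_equal(back[[i]]$ri_source, lib[[i]]$ri_source)
    expect_equal(back[[i]]$evidence_count, lib[[i]]$evidence_count)
    expect_equal(back[[i]]$spectrum$mz, lib[[i]]$spectrum$mz, tolerance = 1e-6)
    expect_equal(back[[i]]$spectrum$intensity, lib[[i]]$spectrum$intensity,
                 tolerance = 1e-6)
  }
  expect_equal(back[[1]]$metadata$comment, "synthetic spectrum")
})

test_that("MSP reader reports format errors with context", {
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: Bad record", "Num Peaks: 3", "100 5", "200 7", ""), path)
  expect_error(read_msp(path), "declared 3 peaks")
  writeLines(c("Formula: C2H6", "Num Peaks: 1", "100 5", ""), path)
  expect_error(read_msp(path), "missing required field Name")
  writeLines(c("Name: Bad numbers", "Num Peaks: 1", "abc def", ""), path)
  expect_error(read_msp(path), "unreadable peak value")
})

test_that("feature tables parse spectra, samples and blanks and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "feature_id,rt_min,spectrum,sample_s1,sample_s2,blank_b1,blank_b2",
    "F1,5.2,50.015:100;77.039:40,1000,1100,10,12",
    "F2,6.0,91.054:999,2000,,0,0",
    "F3,7.5,105.07:500;106.07:50,500,600,5,8"), path)
  expect_warning(feats <- read_feature_table(path), "empty abundance")
  expect_length(feats, 3)
  expect_equal(length(feats[[1]]$sample_abundances), 2)
  expect_equal(length(feats[[1]]$blank_abundances), 2)
  expect_equal(feats[[1]]$spectrum$mz, c(50.015, 77.039))
  expect_equal(unname(feats[[2]]$sample_abundances["sample_s2"]), 0)

  rt <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feats, rt, header = "round-trip test")
  back <- read_feature_table(rt)
  expect_equal(vapply(back, `[[`, "", "feature_id"),
               vapply(feats, `[[`, "", "feature_id"))
  expect_equal(back[[3]]$spectrum$mz, feats[[3]]$spectrum$mz, tolerance = 1e-9)
  expect_equal(back[[1]]$blank_abundances, feats[[1]]$blank_abundances,
               ignore_attr = TRUE)
})

test_that("feature table reader rejects missing columns and bad spectra", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,rt_min,spectrum,sample_s1", "F1,5,100:1,10"), path)
  expect_error(read_feature_table(path), "feature_id")
  writeLines(c("feature_id,rt_min,spectrum,sample_s1", "F1,5,100:abc,10"), path)
  expect_error(read_feature_table(path), "F1")
})

test_that("alkane calibrations and spike sheets enforce their contracts", {
  expect_error(alkane_calibration(c(10, 10), c(1, 2)), "strictly increasing")
  expect_error(alkane_calibration(c(10), c(1)), "length")
  path <- withr::local_tempfile(fileext = ".csv")
  write_alkane_calibration(toy_calibration(), path, header = "seed: 1")
  cal <- read_alkane_calibration(path)
  expect_equal(cal$carbon_number, c(10L, 11L, 12L))

  sheet <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,identifier,equivalence_group", "A,ID1,G1", "B,ID1,G1"), sheet)
  expect_error(read_spike_sheet(sheet), "unique")
})

test_that("results writer emits one row per candidate and handles empties", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(list(), path)
  df <- read.csv(path)
  expect_equal(nrow(df), 0)
  expect_true(all(c("feature_id", "level", "rsi", "multi_hit") %in% names(df)))

  a <- structure(list(
    feature_id = "F9", level = "2", multi_hit = TRUE, blank_pass = TRUE,
    blank_threshold = 0, sample_statistic = 1e6, sample_mean_abundance = 1e6,
    blank_mean_abundance = 0, rationale = "test",
    candidates = data.frame(name = c("A", "B"), identifier = c("ID-A", "ID-B"),
                            rank = 1:2, si = c(900, 850), rsi = c(950, 900),
                            delta_ri = c(3, 40), ri_source = "experimental",
                            rhrmf = c(100, 80), molecular_ion = c(TRUE, FALSE),
                            matched_fragments = c(9L, 7L))),
    class = "level_assignment")
  write_results(list(a), path, header = c("config: default"))
  out <- read.csv(path, comment.char = "#")
  expect_equal(nrow(out), 2)
  expect_equal(as.character(out$level), c("2", "2"))
  expect_equal(out$multi_hit, c("true", "true"))
  expect_equal(out$candidate_name, c("A", "B"))
})
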