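mk_ev <- function(...) {
  do.call(candidate_evidence,
          modifyList(list(feature_id = "F1", name = "Cand", identifier = "ID-1"),
                     list(...)))
}

test_that("level assignment follows the schema's criteria with strict thresholds", {
  cfg <- scoring_config()
  # full Level-2: spectral + experimental RI + RHRMF
  ev2 <- mk_ev(si = 520, rsi = 650, delta_ri = 30, library_ri = 4000,
               ri_source = "experimental", rhrmf = 80)
  expect_equal(as.character(assign_level(ev2, cfg)), "2")
  # same evidence but no RI available: Level 3
  ev3 <- mk_ev(si = 520, rsi = 650, rhrmf = 80, ri_source = "absent")
  expect_equal(as.character(assign_level(ev3, cfg)), "3")
  # boundary: rsi exactly 600 fails the strict inequality
  ev_b <- mk_ev(si = 520, rsi = 600, delta_ri = 10, library_ri = 1000,
                ri_source = "experimental", rhrmf = 80)
  expect_true(is.na(assign_level(ev_b, cfg)))
  # alternative Level-3 path: RI within 100 + molecular ion, weak spectra
  ev_alt <- mk_ev(si = 300, rsi = 400, delta_ri = 80, library_ri = 1500,
                  ri_source = "predicted", molecular_ion = TRUE)
  expect_equal(as.character(assign_level(ev_alt, cfg)), "3")
  # CI path: >= 5 matched fragments substitutes for the EI dot products
  ev_ci <- mk_ev(si = 100, rsi = 100, ionization = "PCI", matched_fragments = 5,
                 delta_ri = 10, library_ri = 1500, ri_source = "experimental",
                 rhrmf = 90)
  expect_equal(as.character(assign_level(ev_ci, cfg)), "2")
  # relative RI criterion: delta 40 on library RI 2000 is 2% >= 1.5%
  ev_rel <- mk_ev(si = 520, rsi = 650, delta_ri = 40, library_ri = 2000,
                  ri_source = "experimental", rhrmf = 80)
  expect_equal(as.character(assign_level(ev_rel, cfg)), "3")
  # molecular-ion requirement blocks Level 2 (but not Level 3) when enabled
  cfg_mi <- scoring_config(require_molecular_ion = TRUE)
  ev_no_ion <- mk_ev(si = 520, rsi = 650, delta_ri = 30, library_ri = 4000,
                     ri_source = "experimental", rhrmf = 80)
  expect_equal(as.character(assign_level(ev_no_ion, cfg_mi)), "3")
  ev_ion <- ev_no_ion; ev_ion$molecular_ion <- TRUE
  expect_equal(as.character(assign_level(ev_ion, cfg_mi)), "2")
})

test_that("Level 2 always implies the Level-3 spectral path (nesting)", {
  set.seed(21)
  cfg <- scoring_config()
  for (i in 1:200) {
    ev <- mk_ev(si = sample(0:1000, 1), rsi = sample(0:1000, 1),
                delta_ri = runif(1, -120, 120), library_ri = runif(1, 900, 3500),
                ri_source = sample(c("experimental", "predicted", "absent"), 1),
                rhrmf = sample(c(NA, runif(1, 0, 100)), 1),
                molecular_ion = runif(1) < 0.3,
                accurate_ion_matches = sample(0:5, 1))
    if (ev$ri_source == "absent") ev$delta_ri <- NA_real_
    lv <- as.character(assign_level(ev, cfg))
    if (identical(lv, "2")) {
      ev_no_ri <- ev; ev_no_ri$delta_ri <- NA_real_; ev_no_ri$ri_source <- "absent"
      ev_no_ri$accurate_ion_matches <- 0L; ev_no_ri$molecular_ion <- FALSE
      expect_equal(as.character(assign_level(ev_no_ri, cfg)), "3")
    }
  }
})

test_that("lowering thresholds never demotes a candidate (monotonicity)", {
  set.seed(22)
  strict <- scoring_config()
  loose <- scoring_config(rsi_min = 400, si_min = 300, rhrmf_min = 50,
                          exact_mass_rsi_min = 400)
  rank_of <- function(lv) if (is.na(lv)) 99 else as.numeric(lv)
  for (i in 1:200) {
    ev <- mk_ev(si = sample(0:1000, 1), rsi = sample(0:1000, 1),
                delta_ri = runif(1, -120, 120), library_ri = runif(1, 900, 3500),
                ri_source = sample(c("experimental", "predicted"), 1),
                rhrmf = runif(1, 0, 100))
    expect_lte(rank_of(as.character(assign_level(ev, loose))),
               rank_of(as.character(assign_level(ev, strict))))
  }
})

test_that("Level-1 verification combines retention time with reference ratios", {
  lib <- toy_library()
  std <- lib[[1]]
  std$expected_rt <- 10.0
  std$metadata$reference_peaks <- std$spectrum[2:3, ]
  feat <- toy_feature(std, rt = 10.03)   # 0.3% deviation
  expect_true(check_level1(feat, std)$pass)
  # 1.5% deviation fails regardless of the spectrum
  expect_false(check_level1(toy_feature(std, rt = 10.15), std)$pass)
  # distorted ratios but an in-house spectral match above 600 still passes
  distorted <- std
  distorted$metadata$reference_peaks <- data.frame(
    mz = std$spectrum$mz[2:3], intensity = c(999, 1))
  expect_true(check_level1(feat, distorted)$pass)
  std_bad <- std; std_bad$expected_rt <- NA_real_
  expect_error(check_level1(feat, std_bad), "expected retention time")
})

test_that("Level 4A returns a formula only when exactly one candidate survives", {
  # synthetic water-like molecular ion with its isotopologues
  pat <- isotope_pattern("H2O", abundance_cutoff = 0.0001, normalize = "base")
  spec <- spectrum(pat$mass - ELECTRON_MASS, 1000 * pat$abundance)
  f <- feature_record("F4A", 5, spec, c(s1 = 1),
                      reference_mz = monoisotopic_mass("H2O") - ELECTRON_MASS)
  got <- level4a_unequivocal_formula(f, "C2H10N2O2S1", tol_ppm = 5)
  expect_equal(format(got), "H2O")
  # at a very loose tolerance several formulas survive the mass window: not
  # unequivocal, so no formula is returned
  expect_gt(length(decompose_mass(monoisotopic_mass("H2O"), 20000, "C2H20N2O2")), 1)
  expect_null(level4a_unequivocal_formula(f, "C2H20N2O2", tol_ppm = 20000))
  f_noprec <- feature_record("F0", 5, spec, c(s1 = 1))
  expect_error(level4a_unequivocal_formula(f_noprec, "C2H10N2O2"), "precursor")
})

test_that("homologous series need matching KMD, integer spacing and linear RI", {
  ch2 <- monoisotopic_mass("CH2")
  masses <- 160.125 + (0:3) * ch2
  feats <- data.frame(feature_id = paste0("H", 1:4), mass = masses,
                      ri = 1500 + 100 * (0:3))
  series <- detect_homologous_series(feats, "CH2", min_members = 3)
  expect_length(series, 1)
  expect_equal(nrow(series[[1]]), 4)
  expect_equal(series[[1]]$n_repeat, 0:3)
  # scrambled, non-linear RIs break the series
  feats_bad <- feats; feats_bad$ri <- c(1500, 1900, 1550, 1700)
  expect_length(detect_homologous_series(feats_bad, "CH2", min_members = 3), 0)
  # too few members
  expect_length(detect_homologous_series(feats[1:2, ], "CH2", min_members = 3), 0)
})

test_that("class flagging labels features by diagnostic fragments", {
  diag <- list(phthalate = c(149.0233), pah = c(252.0934, 226.0777),
               shared = c(149.0233))
  f <- feature_record("FC", 5, spectrum(c(149.0233, 310.2), c(999, 50)), c(s1 = 1))
  labels <- flag_class(f, diag, tol_ppm = 10, min_hits = 1)
  expect_setequal(labels, c("phthalate", "shared"))  # shared fragment: both labels
  f2 <- feature_record("FC2", 5, spectrum(77.04, 10), c(s1 = 1))
  expect_length(flag_class(f2, diag), 0)
  expect_length(flag_class(f, diag["pah"], min_hits = 2), 0)
})

test_that("candidate ranking applies the dominance tie-breaks", {
  cfg <- scoring_config()
  a <- mk_ev(name = "A", rsi = 700); b <- mk_ev(name = "B", rsi = 640)
  expect_true(rank_candidates(list(b, a), cfg)$preferred)   # rsi margin >= 50
  a2 <- mk_ev(name = "A", rsi = 650, delta_ri = 10)
  b2 <- mk_ev(name = "B", rsi = 650, delta_ri = 45)
  rk <- rank_candidates(list(a2, b2), cfg)
  expect_true(rk$preferred)                                  # |dRI| margin >= 30
  a3 <- mk_ev(name = "A", rsi = 650); b3 <- mk_ev(name = "B", rsi = 630)
  rk3 <- rank_candidates(list(a3, b3), cfg)
  expect_false(rk3$preferred)
  expect_true(rk3$multi_hit)
  # evidence-count dominance by a factor of 10
  a4 <- mk_ev(name = "A", rsi = 650, evidence_count = 100)
  b4 <- mk_ev(name = "B", rsi = 645, evidence_count = 8)
  expect_true(rank_candidates(list(b4, a4), cfg)$preferred)
  expect_error(rank_candidates(list(), cfg), "no candidates")
  # single candidate is preferred, not multi-hit
  single <- rank_candidates(list(a), cfg)
  expect_true(single$preferred); expect_false(single$multi_hit)
})

test_that("dedupe keeps the best assignment per identifier or normalized name", {
  mk_asg <- function(fid, level, name, id, rsi) {
    structure(list(feature_id = fid, level = level, multi_hit = FALSE,
                   blank_pass = TRUE,
                   candidates = data.frame(name = name, identifier = id,
                                           rank = 1L, rsi = rsi)),
              class = "level_assignment")
  }
  out <- dedupe(list(mk_asg("F1", "3", "Cmpd A", "CAS-1", 700),
                     mk_asg("F2", "2", "Cmpd A", "CAS-1", 650)))
  expect_length(out, 1)
  expect_equal(out[[1]]$feature_id, "F2")        # better level wins
  expect_equal(attr(out, "removed"), "F1")
  # case/whitespace-normalized names are duplicates
  out2 <- dedupe(list(mk_asg("F1", "2", "Cmpd  B", "", 700),
                      mk_asg("F2", "2", "cmpd b", "", 650)))
  expect_length(out2, 1)
  expect_equal(out2[[1]]$feature_id, "F1")       # higher rsi wins within a level
  # identical names under distinct identifiers: deduped and flagged for review
  out3 <- dedupe(list(mk_asg("F1", "2", "Cmpd C", "CAS-9", 700),
                      mk_asg("F2", "2", "Cmpd C", "CAS-8", 650)))
  expect_length(out3, 1)
  expect_setequal(attr(out3, "review"), c("CAS-9", "CAS-8"))
})

test_that("annotate_feature assigns Level 2 to an exact library copy and Level 5 to noise", {
  lib <- toy_library()
  cal <- alkane_calibration(c(8, 14), c(6, 18))  # RI span 800-1400
  # place the feature so its RI reproduces entry 1's library RI
  rt <- 6 + (1181 - 800) / 600 * 12
  feat <- toy_feature(lib[[1]], rt)
  asg <- annotate_feature(feat, lib, cal)
  expect_equal(asg$level, "2")
  expect_equal(asg$candidates$identifier[1], "TOY-1")
  expect_equal(asg$candidates$rank[1], 1)
  # unmatched feature: Level 5
  noise <- feature_record("FN", 8, spectrum(c(333.3, 444.4), c(5, 5)), c(s1 = 1))
  expect_equal(annotate_feature(noise, lib, cal)$level, "5")
  expect_warning(a_empty <- annotate_feature(noise, list(), cal), "empty library")
  expect_equal(a_empty$level, "5")
})

test_that("annotate_run withholds levels from blank-filter failures", {
  lib <- toy_library()
  cal <- alkane_calibration(c(8, 14), c(6, 18))
  rt <- 6 + (1181 - 800) / 600 * 12
  good <- toy_feature(lib[[1]], rt, feature_id = "GOOD")
  contaminated <- toy_feature(lib[[1]], rt, feature_id = "BAD",
                              samples = c(s1 = 1000, s2 = 1000),
                              blanks = c(b1 = 900, b2 = 1100, b3 = 950, b4 = 1050))
  res <- suppressWarnings(annotate_run(list(good, contaminated), lib, cal))
  expect_equal(res[[1]]$level, "2")
  expect_true(res[[1]]$blank_pass)
  expect_false(res[[2]]$blank_pass)
  expect_true(is.na(res[[2]]$level))
  smry <- summarize_assignments(res)
  expect_equal(smry$n[smry$level == "blank_fail"], 1L)
})
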