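test_that("peak matching pairs each peak at most once with stated tie-breaks", {
  w <- match_weighting()
  s <- spectrum(c(50, 77, 105), c(10, 20, 30))
  m <- match_peaks(s, s, w)
  expect_equal(nrow(m), 3)
  expect_equal(m$query_idx, m$library_idx)
  # disjoint beyond tolerance
  expect_equal(nrow(match_peaks(s, spectrum(c(60, 90), c(1, 1)), w)), 0)
  # two query peaks in one bin: higher-intensity query wins the single pair
  q <- spectrum(c(100.1, 100.4), c(5, 50))
  l <- spectrum(100.2, 10)
  m <- match_peaks(q, l, w)
  expect_equal(nrow(m), 1)
  expect_equal(m$query_idx, 2)
})

test_that("dot product satisfies identity, orthogonality and the hand example", {
  w0 <- match_weighting(mz_exponent = 0, intensity_exponent = 0.5)
  q <- spectrum(c(100, 200), c(100, 50))
  l <- spectrum(c(100, 200), c(100, 100))
  expect_equal(dot_product_score(q, q, w0), 1000)
  expect_equal(dot_product_score(q, spectrum(c(300, 400), c(1, 1)), w0), 0)
  expect_equal(dot_product_score(q, l, w0), 986)
  expect_error(dot_product_score(spectrum(100, 0), l, w0), "all-zero")
})

test_that("spectral scores are symmetric, scale-invariant, and reverse >= forward", {
  set.seed(11)
  w <- match_weighting()
  for (i in 1:25) {
    nq <- sample(3:10, 1); nl <- sample(3:10, 1)
    q <- spectrum(sort(sample(50:400, nq)) + runif(nq, -0.2, 0.2), runif(nq, 1, 100))
    l <- spectrum(sort(sample(50:400, nl)) + runif(nl, -0.2, 0.2), runif(nl, 1, 100))
    si <- dot_product_score(q, l, w)
    expect_identical(si, dot_product_score(l, q, w))
    expect_identical(si, dot_product_score(spectrum(q$mz, q$intensity * 37), l, w))
    expect_gte(reverse_dot_product_score(q, l, w), si)
  }
  # query = library + extra peaks: extras discarded, perfect reverse match
  l <- spectrum(c(100, 150), c(50, 80))
  q_plus <- spectrum(c(100, 150, 300, 350), c(50, 80, 999, 10))
  expect_equal(reverse_dot_product_score(q_plus, l, w), 1000)
  # library has unmatched peaks: residual mismatch persists
  expect_lt(reverse_dot_product_score(l, q_plus, w), 1000)
})

test_that("retention index interpolation hits anchors and increases strictly", {
  cal <- alkane_calibration(c(10, 11), c(10, 12))
  expect_equal(compute_retention_index(10, cal), 1000)
  expect_equal(compute_retention_index(11, cal), 1050)
  expect_equal(compute_retention_index(12, cal), 1100)
  expect_error(compute_retention_index(9, cal), "outside calibration span")
  ext <- compute_retention_index(9, cal, extrapolate = TRUE)
  expect_true(isTRUE(attr(ext, "extrapolated")))

  cal3 <- toy_calibration()
  for (n in seq_len(nrow(cal3))) {
    expect_equal(compute_retention_index(cal3$retention_time[n], cal3),
                 100 * cal3$carbon_number[n])
  }
  rts <- seq(10, 14.5, by = 0.1)
  ris <- vapply(rts, compute_retention_index, 0, cal = cal3)
  expect_true(all(diff(ris) > 0))
})

test_that("RI match rule applies strict absolute and relative thresholds", {
  expect_true(ri_match(4049, 4000, "experimental")$pass)   # 49 < 50, 1.23% < 1.5%
  expect_false(ri_match(2040, 2000, "experimental")$pass)  # 2.0% >= 1.5%
  expect_true(ri_match(1099, 1000, "predicted")$pass)      # 99 < 100
  expect_false(ri_match(1100, 1000, "predicted")$pass)     # boundary is strict
  expect_false(ri_match(1050, 1000, "experimental")$pass)  # 50 not < 50
  expect_error(ri_match(1000, 1000, "absent"), "no retention index")
})

test_that("HRMF equals a brute-force subformula oracle", {
  # explicable pair for ethanol-like candidate
  cation <- function(f) monoisotopic_mass(f) - ELECTRON_MASS
  s <- spectrum(c(cation("CH3"), cation("C2H5O")), c(100, 50))
  expect_equal(hrmf(s, "C2H6O", tol_ppm = 5, h_transfer = 0), 100)
  s2 <- spectrum(c(cation("CH3"), 34.9689), c(100, 50))
  expect_equal(hrmf(s2, "C2H6O", tol_ppm = 5), 50)
  expect_equal(hrmf(spectrum(cation("C1"), 10), "C1", tol_ppm = 5), 100)
  expect_error(hrmf(spectrum(100, 1, "unit"), "C2H6O"), "accurate")

  # oracle equivalence on parents up to 30 atoms, random probe spectra
  set.seed(5)
  for (parent in list(c(C = 6L, H = 6L, O = 1L), c(C = 8L, H = 10L, Cl = 2L),
                      c(C = 12L, H = 16L, N = 1L, O = 1L))) {
    oracle_tab <- brute_subformulas(parent)
    probe_mz <- c(sample(oracle_tab$mass, 6) - 0.000548579909,
                  runif(4, 40, 200))
    probe <- spectrum(probe_mz, rep(1, 10))
    oracle_hit <- vapply(probe$mz, function(x)
      any(abs(x - (oracle_tab$mass - 0.000548579909)) / x * 1e6 <= 10), logical(1))
    expect_equal(hrmf(probe, chem_formula(parent), tol_ppm = 10),
                 100 * mean(oracle_hit))
  }
})

test_that("HRMF is monotone in tolerance and bounded in [0, 100]", {
  set.seed(9)
  cand <- "C9H12O2"
  probe <- spectrum(runif(12, 40, 150), rep(1, 12))
  scores <- vapply(c(1, 5, 20, 100, 1000), function(tol)
    hrmf(probe, cand, tol_ppm = tol), 0)
  expect_true(all(diff(scores) >= 0))
  expect_true(all(scores >= 0 & scores <= 100))
  expect_gte(hrmf(probe, cand, tol_ppm = 10, h_transfer = 2),
             hrmf(probe, cand, tol_ppm = 10, h_transfer = 0))
})

test_that("RHRMF is restricted to library-matched peaks and can be unavailable", {
  cation <- function(f) monoisotopic_mass(f) - ELECTRON_MASS
  lib <- spectrum(c(cation("CH3"), cation("C2H5O")), c(100, 50))
  # query adds an inexplicable peak that is NOT in the library: unaffected
  q <- spectrum(c(cation("CH3"), cation("C2H5O"), 250.1234), c(100, 50, 80))
  expect_equal(rhrmf(q, lib, "C2H6O"), 100)
  expect_lt(hrmf(q, "C2H6O"), 100)
  # 2 matched peaks, 1 explicable
  lib2 <- spectrum(c(cation("CH3"), 34.9689), c(100, 50))
  q2 <- spectrum(c(cation("CH3"), 34.9689), c(90, 60))
  expect_equal(rhrmf(q2, lib2, "C2H6O"), 50)
  # no query-library matches: undefined, not zero
  expect_true(is.na(rhrmf(spectrum(60.05, 1), spectrum(200.1, 1), "C2H6O")))
})

test_that("molecular ion detection respects the ppm tolerance", {
  m <- monoisotopic_mass("C10H8") - ELECTRON_MASS
  hit <- detect_molecular_ion(spectrum(c(64.03, m), c(10, 5)), "C10H8", tol_ppm = 10)
  expect_true(hit$present)
  expect_equal(hit$mass_error_ppm, 0, tolerance = 1e-6)
  off <- detect_molecular_ion(spectrum(m * (1 + 20e-6), 5), "C10H8", tol_ppm = 10)
  expect_false(off$present)
  expect_false(detect_molecular_ion(spectrum(50.0, 1), "C10H8")$present)
})

test_that("matched-fragment counting supports the CI criterion", {
  s <- spectrum(50 + 10 * (0:6), rep(1, 7))
  expect_equal(count_matched_fragments(s, s), 7)
  expect_equal(count_matched_fragments(s, spectrum(200.5, 1)), 0)
  five <- spectrum(50 + 10 * (0:4), rep(1, 5))
  expect_gte(count_matched_fragments(five, s), 5)
})
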