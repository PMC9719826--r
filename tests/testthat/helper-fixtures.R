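# Shared in-code fixtures for the test suite.

# brute-force subformula table via expand.grid (independent of the package's
# depth-first enumerator)
brute_subformulas <- function(counts) {
  grid <- do.call(expand.grid, lapply(counts, function(n) 0:n))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  mono <- c(C = 12, H = 1.00782503224, N = 14.00307400443, O = 15.99491461957,
            S = 31.9720711744, P = 30.97376199842, F = 18.99840316273,
            Cl = 34.968852682, Br = 78.9183376, I = 126.9044719,
            Si = 27.97692653465)
  grid$mass <- as.matrix(grid[names(counts)]) %*% mono[names(counts)]
  grid
}

toy_calibration <- function() alkane_calibration(c(10, 11, 12), c(10, 12, 14.5))

# a minimal two-entry library plus a feature that is an exact copy of entry 1
toy_library <- function() {
  f1 <- parse_formula("C10H8")   # naphthalene-like
  m1 <- monoisotopic_mass(f1)
  subs1 <- enumerate_subformulas(f1, 40, m1 - 1)
  mz1 <- c(subs1$mass[c(5, 12, 20)], m1) - ELECTRON_MASS
  f2 <- parse_formula("C6H4Cl2") # dichlorobenzene-like
  m2 <- monoisotopic_mass(f2)
  subs2 <- enumerate_subformulas(f2, 40, m2 - 1)
  mz2 <- c(subs2$mass[c(3, 8)], m2) - ELECTRON_MASS
  list(
    library_entry("Toy naphthalene", spectrum(mz1, c(200, 600, 999, 400)),
                  identifier = "TOY-1", formula = f1,
                  retention_index = 1181, ri_source = "experimental",
                  evidence_count = 40),
    library_entry("Toy dichlorobenzene", spectrum(mz2, c(500, 800, 300)),
                  identifier = "TOY-2", formula = f2,
                  retention_index = 1015, ri_source = "experimental",
                  evidence_count = 4))
}

toy_feature <- function(entry, rt, feature_id = "F1",
                        samples = c(sample_a = 1e6, sample_b = 9e5),
                        blanks = c(blank_a = 0, blank_b = 0)) {
  feature_record(feature_id, rt, entry$spectrum, samples, blanks,
                 reference_mz = monoisotopic_mass(entry$formula) - ELECTRON_MASS)
}

small_sim <- function(seed = 7L) {
  sim_config(seed = seed, n_compounds = 12L, n_true_spikes = 4L, n_decoys = 4L,
             n_blanks = 4L)
}
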