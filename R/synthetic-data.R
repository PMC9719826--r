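# Seeded generator of spectral libraries, spiked samples, decoys, blanks and
# alkane calibrations with known ground truth, emulating a spiked-standard
# validation design so every pipeline stage is testable without instrument
# data.

#' Synthetic-run configuration
#'
#' The defaults describe the validation conditions used throughout the test
#' suite: a library of 120 compounds, 50 true spikes, 50 decoy features built
#' by perturbing other library entries (mimicking the structurally-similar-
#' isomer failure mode), 4 blanks, and low multiplicative noise.
#'
#' @param seed integer seed for the single pseudo-random stream.
#' @param n_compounds library size.
#' @param n_true_spikes number of library compounds spiked into samples.
#' @param n_decoys number of decoy features.
#' @param elements element space for random formulas.
#' @param fragment_range inclusive range of fragment counts per spectrum.
#' @param intensity_noise_sd multiplicative intensity noise sd (fraction).
#' @param rt_jitter_sd retention-time jitter sd (minutes).
#' @param blank_contamination_rate contamination features as a fraction of
#'   spike + decoy features.
#' @param n_samples,n_blanks numbers of sample and blank injections (at least
#'   four blanks recommended).
#' @param ri_noise_sd sd of the noise on the monotone mass-to-RI map (RI units).
#' @param molecular_ion_prob probability that a library spectrum includes the
#'   molecular ion.
#' @export
sim_config <- function(seed = 1L, n_compounds = 120L, n_true_spikes = 50L,
                       n_decoys = 50L, elements = c("C", "H", "N", "O", "Cl"),
                       fragment_range = c(6L, 12L), intensity_noise_sd = 0.01,
                       rt_jitter_sd = 0.005, blank_contamination_rate = 0.2,
                       n_samples = 3L, n_blanks = 4L, ri_noise_sd = 5,
                       molecular_ion_prob = 0.9) {
  stopifnot(n_compounds >= n_true_spikes + n_decoys, n_true_spikes >= 0,
            n_decoys >= 0, intensity_noise_sd >= 0, rt_jitter_sd >= 0,
            blank_contamination_rate >= 0, n_samples >= 1, n_blanks >= 0,
            seed == round(seed))
  structure(list(seed = as.integer(seed), n_compounds = n_compounds,
                 n_true_spikes = n_true_spikes, n_decoys = n_decoys,
                 elements = elements, fragment_range = fragment_range,
                 intensity_noise_sd = intensity_noise_sd,
                 rt_jitter_sd = rt_jitter_sd,
                 blank_contamination_rate = blank_contamination_rate,
                 n_samples = n_samples, n_blanks = n_blanks,
                 ri_noise_sd = ri_noise_sd,
                 molecular_ion_prob = molecular_ion_prob),
            class = "sim_config")
}

# Monotone mass -> RI map used by the generator (plus configured noise).
ri_from_mass <- function(mass) 500 + 4 * mass

random_formula <- function(elements) {
  nC <- sample(6:20, 1L)
  counts <- c(C = nC, H = sample(seq(nC, 2L * nC + 2L), 1L))
  if ("O" %in% elements) counts["O"] <- sample(0:3, 1L)
  if ("N" %in% elements) counts["N"] <- sample(0:2, 1L)
  if ("Cl" %in% elements) counts["Cl"] <- sample(0:3, 1L)
  if ("Br" %in% elements && stats::runif(1) < 0.2) counts["Br"] <- sample(1:2, 1L)
  chem_formula(counts[counts > 0])
}

#' Generate a synthetic spectral library
#'
#' Each compound receives a random valid formula within the element space, an
#' EI-like accurate-mass spectrum whose fragment m/z values are true
#' subformula cation masses (so RHRMF is 100 for a self-match by
#' construction), a molecular ion with the configured probability, and an RI
#' from the monotone mass-to-RI model with noise. Deterministic under a fixed
#' seed.
#'
#' @param config a [sim_config()].
#' @return list of [library_entry()] objects.
#' @export
generate_library <- function(config = sim_config()) {
  set.seed(config$seed)
  lapply(seq_len(config$n_compounds), function(i) {
    f <- random_formula(config$elements)
    mono <- monoisotopic_mass(f)
    subs <- enumerate_subformulas(f, 50, mono - 1)
    k <- min(sample(seq(config$fragment_range[1L], config$fragment_range[2L]), 1L),
             nrow(subs))
    idx <- sample(nrow(subs), k)
    mz <- subs$mass[idx] - ELECTRON_MASS
    int <- stats::runif(k, 20, 1000)
    if (stats::runif(1) < config$molecular_ion_prob) {
      mz <- c(mz, mono - ELECTRON_MASS)
      int <- c(int, stats::runif(1, 50, 500))
    }
    library_entry(
      name = sprintf("Synthetic compound %03d", i),
      identifier = sprintf("SYN-%04d", i),
      formula = f,
      spectrum = spectrum(mz, int, "accurate"),
      retention_index = ri_from_mass(mono) + stats::rnorm(1, 0, config$ri_noise_sd),
      ri_source = "experimental",
      evidence_count = sample(1:50, 1L),
      ionization = "EI")
  })
}

#' Generate a synthetic run with known ground truth
#'
#' True spikes appear as features with jittered retention times (placed so
#' their retention index reproduces the library RI), multiplicative intensity
#' noise, sample abundances far above the blank threshold, and zero blank
#' signal. Decoys are perturbed copies of non-spiked library entries (peak
#' dropout and an RI offset of 150-400 units) and are absent from the truth
#' sheet. Contamination features carry comparable abundance in blanks and
#' samples, so they fail blank feature filtering at the default multiplier.
#'
#' @param library list of [library_entry()] objects from [generate_library()].
#' @param config the same [sim_config()].
#' @return list with `features` (list of [feature_record()]), `calibration`
#'   (an [alkane_calibration()]), `truth` (data frame: `feature_id`, `name`,
#'   `identifier`, `equivalence_group`), and `config`.
#' @export
generate_run <- function(library, config = sim_config()) {
  stopifnot(config$n_true_spikes <= length(library))
  set.seed(config$seed + 1L)
  cal <- alkane_calibration(8:40, 2 + 0.5 * (8:40 - 8))
  rt_from_ri <- function(ri) 2 + 0.5 * (ri / 100 - 8)
  sample_ids <- sprintf("sample_%02d", seq_len(config$n_samples))
  blank_ids <- sprintf("blank_%02d", seq_len(config$n_blanks))
  features <- list()
  truth <- list()
  noisy <- function(int) pmax(int * (1 + stats::rnorm(length(int), 0, config$intensity_noise_sd)),
                              1e-6)
  feat_no <- 0L
  next_id <- function() { feat_no <<- feat_no + 1L; sprintf("F%04d", feat_no) }

  for (i in seq_len(config$n_true_spikes)) {
    e <- library[[i]]
    fid <- next_id()
    s <- e$spectrum
    features[[fid]] <- feature_record(
      fid,
      retention_time = rt_from_ri(e$retention_index) +
        stats::rnorm(1, 0, config$rt_jitter_sd),
      spectrum = spectrum(s$mz, noisy(s$intensity), "accurate"),
      sample_abundances = structure(stats::rlnorm(config$n_samples, log(1e6), 0.2),
                                    names = sample_ids),
      blank_abundances = structure(rep(0, config$n_blanks), names = blank_ids),
      reference_mz = monoisotopic_mass(e$formula) - ELECTRON_MASS)
    truth[[fid]] <- data.frame(feature_id = fid, name = e$name,
                               identifier = e$identifier,
                               equivalence_group = e$identifier)
  }
  decoy_pool <- seq(config$n_true_spikes + 1L,
                    length.out = config$n_decoys)
  for (i in decoy_pool) {
    e <- library[[i]]
    fid <- next_id()
    s <- e$spectrum
    keep <- stats::runif(nrow(s)) > 0.2
    if (!any(keep)) keep[1L] <- TRUE
    # offset the RI by at least 150 units, away from the calibration edge,
    # so a decoy can never satisfy the RI criterion for its source compound
    direction <- if (e$retention_index <= 2200) 1 else -1
    ri <- e$retention_index + direction * stats::runif(1, 150, 400)
    features[[fid]] <- feature_record(
      fid,
      retention_time = rt_from_ri(ri),
      spectrum = spectrum(s$mz[keep] + stats::rnorm(sum(keep), 0, 1e-4),
                          noisy(s$intensity[keep]), "accurate"),
      sample_abundances = structure(stats::rlnorm(config$n_samples, log(5e5), 0.2),
                                    names = sample_ids),
      blank_abundances = structure(rep(0, config$n_blanks), names = blank_ids))
  }
  n_contam <- round(config$blank_contamination_rate *
                      (config$n_true_spikes + config$n_decoys))
  for (i in seq_len(n_contam)) {
    fid <- next_id()
    k <- sample(4:8, 1L)
    blank_level <- stats::rlnorm(1, log(1e6), 0.3)
    features[[fid]] <- feature_record(
      fid,
      retention_time = stats::runif(1, 2.5, 17.5),
      spectrum = spectrum(sort(stats::runif(k, 50, 450)),
                          stats::runif(k, 50, 800), "accurate"),
      sample_abundances = structure(blank_level * stats::runif(config$n_samples, 0.8, 1.2),
                                    names = sample_ids),
      blank_abundances = structure(blank_level * stats::runif(config$n_blanks, 0.9, 1.1),
                                   names = blank_ids))
  }
  list(features = unname(features), calibration = cal,
       truth = do.call(rbind, unname(truth)), config = config)
}

#' Write a generated run to disk
#'
#' Emits the library (MSP), feature table, alkane calibration and truth sheet
#' in the formats read back by the package's readers; every file header
#' records the seed.
#'
#' @param library,run outputs of [generate_library()] and [generate_run()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_run <- function(library, run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("seed: %d", run$config$seed)
  paths <- c(library = file.path(dir, "library.msp"),
             features = file.path(dir, "features.csv"),
             calibration = file.path(dir, "alkanes.csv"),
             truth = file.path(dir, "truth.csv"))
  write_msp(library, paths[["library"]])
  write_feature_table(run$features, paths[["features"]], header = hdr)
  write_alkane_calibration(run$calibration, paths[["calibration"]], header = hdr)
  write_csv_with_header(run$truth, paths[["truth"]], header = hdr)
  paths
}
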