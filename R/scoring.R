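# Confidence-level assignment (1, 2, 3, 4A/4B/4C, 5), candidate ranking with
# tie-breaks, multi-hit flagging, and duplicate removal.

#' Scoring configuration
#'
#' Thresholds of the five-level schema. All spectral/RHRMF comparisons are
#' strict (a score exactly at a threshold fails), matching the schema's `<` /
#' `>` notation; the chemical-ionization fragment criterion is "at least
#' five", i.e. non-strict.
#'
#' @param rsi_min reverse dot-product threshold for Levels 2/3 (default 600).
#' @param si_min forward dot-product threshold (default 500).
#' @param rhrmf_min RHRMF percentage threshold (default 75).
#' @param exact_mass_rsi_min reverse dot-product threshold against an exact
#'   mass library (default 600).
#' @param inhouse_match_min in-house spectral-match threshold for Level 1
#'   (default 600).
#' @param ci_min_fragments minimum matched fragments on the CI path (default 5).
#' @param level3_alt_ri_max RI window for the alternative Level-3 path
#'   (default 100).
#' @param level3_alt_min_accurate_ions minimum rule-based accurate-mass ion
#'   matches on the alternative Level-3 path (default 3).
#' @param level1_rt_max_rel_dev maximum relative retention-time deviation from
#'   the in-house standard (default 0.01).
#' @param level1_ratio_tol tolerance on reference-peak intensity ratios
#'   (default 0.20).
#' @param require_molecular_ion require the molecular ion for Level 2
#'   (default `FALSE`; recommended only for stable classes such as PAHs, since
#'   requiring it sharply increases false negatives).
#' @param tie_break list of dominance margins used by [rank_candidates()]:
#'   `evidence_count_factor` (10), `delta_ri_margin` (30), `rsi_margin` (50),
#'   `rhrmf_margin` (10).
#' @param ri_rule an [ri_match_rule()].
#' @export
scoring_config <- function(rsi_min = 600, si_min = 500, rhrmf_min = 75,
                           exact_mass_rsi_min = 600, inhouse_match_min = 600,
                           ci_min_fragments = 5, level3_alt_ri_max = 100,
                           level3_alt_min_accurate_ions = 3,
                           level1_rt_max_rel_dev = 0.01, level1_ratio_tol = 0.20,
                           require_molecular_ion = FALSE,
                           tie_break = list(evidence_count_factor = 10,
                                            delta_ri_margin = 30,
                                            rsi_margin = 50,
                                            rhrmf_margin = 10),
                           ri_rule = ri_match_rule()) {
  stopifnot(rsi_min > 0, si_min > 0, rhrmf_min > 0, ci_min_fragments > 0,
            level3_alt_ri_max > 0, level1_rt_max_rel_dev > 0, level1_ratio_tol > 0)
  structure(list(rsi_min = rsi_min, si_min = si_min, rhrmf_min = rhrmf_min,
                 exact_mass_rsi_min = exact_mass_rsi_min,
                 inhouse_match_min = inhouse_match_min,
                 ci_min_fragments = ci_min_fragments,
                 level3_alt_ri_max = level3_alt_ri_max,
                 level3_alt_min_accurate_ions = level3_alt_min_accurate_ions,
                 level1_rt_max_rel_dev = level1_rt_max_rel_dev,
                 level1_ratio_tol = level1_ratio_tol,
                 require_molecular_ion = require_molecular_ion,
                 tie_break = tie_break, ri_rule = ri_rule),
            class = "scoring_config")
}

#' Per-candidate evidence bundle
#'
#' Collects the evidence layers computed for one feature-candidate pair.
#' Optional layers use `NA` when unavailable, which simply fails the
#' corresponding criterion (and leaves the RHRMF criterion "unavailable"
#' rather than 0).
#'
#' @param feature_id feature identifier.
#' @param name,identifier candidate name and identifier.
#' @param si,rsi forward/reverse dot-product scores (0-1000).
#' @param delta_ri observed minus library RI (`NA` if unavailable).
#' @param library_ri library RI value (needed for the relative criterion).
#' @param ri_source `"experimental"`, `"predicted"`, or `"absent"`.
#' @param rhrmf RHRMF percentage (`NA` if unavailable).
#' @param exact_mass_library_rsi reverse score against an exact-mass library
#'   (`NA` if the library spectrum is unit resolution).
#' @param molecular_ion logical: molecular ion observed.
#' @param matched_fragments integer matched-fragment count.
#' @param ionization `"EI"`, `"PCI"`, `"ECNI"`, or `"APCI"`.
#' @param accurate_ion_matches rule-based accurate-mass ion matches (for the
#'   alternative Level-3 path).
#' @param evidence_count optional metadata occurrence count.
#' @export
candidate_evidence <- function(feature_id, name, identifier = "",
                               si = NA_real_, rsi = NA_real_,
                               delta_ri = NA_real_, library_ri = NA_real_,
                               ri_source = "absent", rhrmf = NA_real_,
                               exact_mass_library_rsi = NA_real_,
                               molecular_ion = FALSE, matched_fragments = 0L,
                               ionization = "EI", accurate_ion_matches = 0L,
                               evidence_count = NA_real_) {
  structure(list(feature_id = feature_id, name = name, identifier = identifier,
                 si = si, rsi = rsi, delta_ri = delta_ri, library_ri = library_ri,
                 ri_source = ri_source, rhrmf = rhrmf,
                 exact_mass_library_rsi = exact_mass_library_rsi,
                 molecular_ion = isTRUE(molecular_ion),
                 matched_fragments = matched_fragments, ionization = ionization,
                 accurate_ion_matches = accurate_ion_matches,
                 evidence_count = evidence_count),
            class = "candidate_evidence")
}

isTRUE_na <- function(x) !is.na(x) && x

#' Assign a confidence level to one candidate's evidence
#'
#' Level 2 requires (i) the spectral path: EI reverse score > `rsi_min` and
#' forward score > `si_min`, or the CI path: PCI/ECNI/APCI ionization with at
#' least `ci_min_fragments` matched fragments; (ii) an RI match per the
#' library RI provenance; (iii) accurate-mass evidence: exact-mass-library
#' reverse score > `exact_mass_rsi_min` or RHRMF > `rhrmf_min`; and (iv) the
#' molecular ion when `require_molecular_ion` is set. Level 3 holds when the
#' spectral and accurate-mass conditions hold without an RI pass, or
#' alternatively when the RI is within `level3_alt_ri_max` and at least
#' `level3_alt_min_accurate_ions` rule-based accurate-mass ions (or the
#' molecular ion) are observed.
#'
#' @param ev a [candidate_evidence()].
#' @param config a [scoring_config()].
#' @return `"2"`, `"3"`, or `NA_character_`, with attribute `rationale`
#'   (named logical vector of the criteria evaluated).
#' @export
assign_level <- function(ev, config = scoring_config()) {
  ei_spectral <- isTRUE_na(ev$rsi > config$rsi_min) && isTRUE_na(ev$si > config$si_min)
  ci_spectral <- ev$ionization %in% c("PCI", "ECNI", "APCI") &&
    isTRUE_na(ev$matched_fragments >= config$ci_min_fragments)
  spectral_ok <- ei_spectral || ci_spectral
  exact_ok <- isTRUE_na(ev$exact_mass_library_rsi > config$exact_mass_rsi_min) ||
    isTRUE_na(ev$rhrmf > config$rhrmf_min)
  ri_ok <- if (ev$ri_source == "absent" || is.na(ev$delta_ri) || is.na(ev$library_ri)) {
    FALSE
  } else {
    ri_match(ev$library_ri + ev$delta_ri, ev$library_ri, ev$ri_source,
             config$ri_rule)$pass
  }
  mol_ok <- !config$require_molecular_ion || ev$molecular_ion
  alt3 <- isTRUE_na(abs(ev$delta_ri) < config$level3_alt_ri_max) &&
    (isTRUE_na(ev$accurate_ion_matches >= config$level3_alt_min_accurate_ions) ||
       ev$molecular_ion)
  rationale <- c(spectral = spectral_ok, ri = ri_ok, exact_mass = exact_ok,
                 molecular_ion = mol_ok, level3_alternative = alt3)
  level <- if (spectral_ok && ri_ok && exact_ok && mol_ok) {
    "2"
  } else if ((spectral_ok && exact_ok) || alt3) {
    "3"
  } else {
    NA_character_
  }
  structure(level, rationale = rationale)
}

#' Verify a Level-1 identification against an in-house standard
#'
#' The feature's retention time must match the standard's within
#' `level1_rt_max_rel_dev` (relative), and either at least two reference peaks
#' must be observed with intensity ratios (relative to the most intense
#' reference peak) within `level1_ratio_tol` of the expected ratios, or the
#' spectrum must match the in-house record above `inhouse_match_min`.
#'
#' @param feature a [feature_record()].
#' @param standard a [library_entry()] with `expected_rt` set; its
#'   `metadata$reference_peaks` may hold a data frame (`mz`, `intensity`) of
#'   reference ions, otherwise the entry's spectrum is used for the spectral
#'   route.
#' @param config a [scoring_config()].
#' @param weighting a [match_weighting()] for the spectral route.
#' @return list with `pass` and `rationale` (character).
#' @export
check_level1 <- function(feature, standard, config = scoring_config(),
                         weighting = match_weighting()) {
  if (is.na(standard$expected_rt)) {
    stop("Level-1 standard ", sQuote(standard$name), " has no expected retention time",
         call. = FALSE)
  }
  ref <- standard$metadata$reference_peaks
  if (is.null(ref) && is.null(standard$spectrum)) {
    stop("Level-1 standard ", sQuote(standard$name),
         " provides neither reference peaks nor an in-house spectrum", call. = FALSE)
  }
  rationale <- character(0)
  rt_dev <- abs(feature$retention_time - standard$expected_rt) / standard$expected_rt
  rt_ok <- rt_dev <= config$level1_rt_max_rel_dev
  rationale <- c(rationale, sprintf("rt_deviation=%.4f%% (max %.4f%%)",
                                    100 * rt_dev, 100 * config$level1_rt_max_rel_dev))
  ratio_ok <- FALSE
  if (!is.null(ref) && nrow(ref) >= 2L) {
    base <- which.max(ref$intensity)
    exp_ratio <- ref$intensity / ref$intensity[base]
    obs <- vapply(ref$mz, function(m) {
      d <- abs(feature$spectrum$mz - m)
      i <- which.min(d)
      tol <- if (is.null(weighting$tol_ppm)) weighting$bin_width / 2 else
        m * weighting$tol_ppm * 1e-6
      if (d[i] <= tol) feature$spectrum$intensity[i] else NA_real_
    }, numeric(1))
    if (sum(!is.na(obs)) >= 2L && !is.na(obs[base]) && obs[base] > 0) {
      obs_ratio <- obs / obs[base]
      dev <- abs(obs_ratio - exp_ratio) / exp_ratio
      ratio_ok <- all(!is.na(dev)) && all(dev <= config$level1_ratio_tol)
      rationale <- c(rationale, sprintf("reference_peak_ratio_max_dev=%.3f", max(dev, na.rm = TRUE)))
    } else {
      rationale <- c(rationale, "reference_peaks_not_all_observed")
    }
  }
  spectral_ok <- FALSE
  if (!ratio_ok) {
    score <- dot_product_score(feature$spectrum, standard$spectrum, weighting)
    spectral_ok <- score > config$inhouse_match_min
    rationale <- c(rationale, sprintf("inhouse_match=%d (min >%d)", score,
                                      config$inhouse_match_min))
  }
  list(pass = rt_ok && (ratio_ok || spectral_ok), rationale = rationale)
}

#' Level 4A: unequivocal molecular formula from the precursor ion
#'
#' Decomposes the feature's designated precursor (radical-cation) m/z into
#' candidate formulas within the element bounds, then removes candidates whose
#' simulated isotope pattern disagrees with the observed spectrum or that
#' cannot explain all dominant fragment ions as subformula cations. The
#' formula is returned iff exactly one candidate survives.
#'
#' @param feature a [feature_record()] with `reference_mz` designating the
#'   accurate-mass precursor peak.
#' @param bounds element upper bounds ([chem_formula()] or string).
#' @param tol_ppm mass tolerance in ppm.
#' @param isotope_abundance_tol maximum relative deviation of an observed
#'   isotopologue abundance from the simulated one.
#' @param isotope_cutoff simulated isotope peaks below this fraction of the
#'   base peak are not required to be observed.
#' @param dominant_fraction fragments at or above this fraction of the base
#'   peak must be explicable as subformulas.
#' @param h_transfer hydrogen-transfer allowance for fragment explanation.
#' @return the surviving [chem_formula()], or `NULL` when zero or several
#'   candidates survive (the formula is not unequivocal).
#' @export
level4a_unequivocal_formula <- function(feature, bounds, tol_ppm = 5,
                                        isotope_abundance_tol = 0.3,
                                        isotope_cutoff = 0.05,
                                        dominant_fraction = 0.1,
                                        h_transfer = 1) {
  if (is.na(feature$reference_mz)) {
    stop("feature ", feature$feature_id, " has no designated precursor m/z", call. = FALSE)
  }
  if (spectrum_resolution(feature$spectrum) != "accurate") {
    stop("Level 4A requires an accurate-resolution spectrum", call. = FALSE)
  }
  neutral <- feature$reference_mz + ELECTRON_MASS
  candidates <- decompose_mass(neutral, tol_ppm, bounds)
  spec <- feature$spectrum
  prec_idx <- which.min(abs(spec$mz - feature$reference_mz))
  prec_int <- spec$intensity[prec_idx]
  dominant <- spec$mz[spec$intensity >= dominant_fraction * max(spec$intensity) &
                        spec$mz < feature$reference_mz - 0.5]
  survives <- vapply(candidates, function(f) {
    pat <- isotope_pattern(f, abundance_cutoff = isotope_cutoff, normalize = "base")
    ok_iso <- all(vapply(seq_len(nrow(pat)), function(i) {
      target <- pat$mass[i] - ELECTRON_MASS
      j <- which.min(abs(spec$mz - target))
      if (abs(spec$mz[j] - target) / target * 1e6 > tol_ppm) return(FALSE)
      obs_rel <- spec$intensity[j] / prec_int
      abs(obs_rel - pat$abundance[i]) / pat$abundance[i] <= isotope_abundance_tol
    }, logical(1)))
    if (!ok_iso) return(FALSE)
    if (length(dominant) == 0L) return(TRUE)
    cm <- fragment_cation_masses(f, h_transfer)
    all(peaks_explained(dominant, cm, tol_ppm))
  }, logical(1))
  survivors <- candidates[survives]
  if (length(survivors) == 1L) survivors[[1L]] else NULL
}

#' Level 4B: detect homologous series by Kendrick mass defect
#'
#' Groups features whose Kendrick mass defects (for the given repeat unit)
#' agree within `kmd_tol` and whose masses differ by integer multiples of the
#' repeat mass; each group must show linear retention indices versus repeat
#' count (R^2 at or above `r2_min`). Groups smaller than `min_members` are
#' discarded.
#'
#' @param features data frame with columns `feature_id`, `mass` (designated
#'   neutral mass, Da) and `ri`.
#' @param repeat_unit repeat-unit formula (object or string), e.g. CH2 or CF2.
#' @param kmd_tol Kendrick-mass-defect agreement tolerance in Da.
#' @param min_members minimum series size (>= 3).
#' @param r2_min minimum coefficient of determination of the RI-vs-repeat-count
#'   fit.
#' @return list of data frames (one per detected series) with columns of
#'   `features` plus `kmd` and `n_repeat`.
#' @export
detect_homologous_series <- function(features, repeat_unit = "CH2",
                                     kmd_tol = 0.002, min_members = 3,
                                     r2_min = 0.99) {
  stopifnot(min_members >= 3)
  if (is.character(repeat_unit)) repeat_unit <- parse_formula(repeat_unit)
  rep_mass <- monoisotopic_mass(repeat_unit)
  kmd <- vapply(features$mass, function(m)
    kendrick_mass_defect(m, repeat_unit)$kendrick_mass_defect, numeric(1))
  o <- order(kmd)
  grp <- cumsum(c(1, diff(kmd[o]) > kmd_tol))
  out <- list()
  for (g in unique(grp)) {
    idx <- o[grp == g]
    if (length(idx) < min_members) next
    sub <- features[idx, , drop = FALSE]
    sub$kmd <- kmd[idx]
    n_rep <- round((sub$mass - min(sub$mass)) / rep_mass)
    resid <- sub$mass - (min(sub$mass) + n_rep * rep_mass)
    keep <- abs(resid) <= kmd_tol * 2
    sub <- sub[keep, , drop = FALSE]; n_rep <- n_rep[keep]
    if (nrow(sub) < min_members || length(unique(n_rep)) < min_members) next
    fit <- stats::lm(sub$ri ~ n_rep)
    ss_tot <- sum((sub$ri - mean(sub$ri))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
    if (is.na(r2) || r2 < r2_min) next
    sub$n_repeat <- n_rep
    out[[length(out) + 1L]] <- sub[order(sub$n_repeat), , drop = FALSE]
  }
  out
}

#' Level 4C: flag chemical classes by diagnostic fragments
#'
#' A feature receives each class label whose diagnostic accurate-mass
#' fragments are matched at least `min_hits` times within `tol_ppm`.
#'
#' @param feature a [feature_record()].
#' @param diagnostics named list: class name -> numeric vector of diagnostic
#'   fragment m/z values.
#' @param tol_ppm mass tolerance in ppm.
#' @param min_hits minimum number of matched diagnostic fragments (>= 1).
#' @return character vector of class labels (possibly several: shared
#'   fragments yield ambiguous, multiply-labeled features).
#' @export
flag_class <- function(feature, diagnostics, tol_ppm = 10, min_hits = 1) {
  stopifnot(length(diagnostics) > 0, min_hits >= 1)
  mz <- feature$spectrum$mz
  hits <- vapply(diagnostics, function(frags) {
    sum(vapply(frags, function(f) any(abs(mz - f) / f * 1e6 <= tol_ppm), logical(1)))
  }, numeric(1))
  names(hits)[hits >= min_hits]
}

#' Rank candidates within a level and flag multi-hits
#'
#' Baseline order is by descending reverse dot-product score (ties broken by
#' descending evidence count, then name, for determinism). The top candidate
#' is "preferred" iff any dominance margin over the runner-up holds: evidence
#' count at least `evidence_count_factor` times higher, absolute RI delta
#' smaller by at least `delta_ri_margin`, reverse score larger by at least
#' `rsi_margin`, or RHRMF larger by at least `rhrmf_margin`. Otherwise the
#' feature is a multi-hit.
#'
#' @param cands list of [candidate_evidence()] for one feature at one level.
#' @param config a [scoring_config()].
#' @return list with `ranked` (the input, reordered), `preferred` (logical),
#'   `multi_hit` (logical).
#' @export
rank_candidates <- function(cands, config = scoring_config()) {
  if (length(cands) == 0L) stop("no candidates to rank", call. = FALSE)
  ec <- vapply(cands, function(x) if (is.na(x$evidence_count)) 0 else x$evidence_count, numeric(1))
  rsi <- vapply(cands, function(x) if (is.na(x$rsi)) -Inf else x$rsi, numeric(1))
  nm <- vapply(cands, `[[`, "", "name")
  o <- order(-rsi, -ec, nm)
  ranked <- cands[o]
  if (length(ranked) == 1L) {
    return(list(ranked = ranked, preferred = TRUE, multi_hit = FALSE))
  }
  a <- ranked[[1L]]; b <- ranked[[2L]]
  tb <- config$tie_break
  dom_ec <- !is.na(a$evidence_count) && !is.na(b$evidence_count) &&
    a$evidence_count > b$evidence_count &&
    a$evidence_count >= tb$evidence_count_factor * b$evidence_count
  dom_ri <- !is.na(a$delta_ri) && !is.na(b$delta_ri) &&
    (abs(b$delta_ri) - abs(a$delta_ri)) >= tb$delta_ri_margin
  dom_rsi <- !is.na(a$rsi) && !is.na(b$rsi) && (a$rsi - b$rsi) >= tb$rsi_margin
  dom_rh <- !is.na(a$rhrmf) && !is.na(b$rhrmf) && (a$rhrmf - b$rhrmf) >= tb$rhrmf_margin
  preferred <- dom_ec || dom_ri || dom_rsi || dom_rh
  list(ranked = ranked, preferred = preferred, multi_hit = !preferred)
}

normalize_name <- function(x) gsub("[[:space:]]+", " ", trimws(tolower(x)))

.LEVEL_ORDER <- c("1" = 1, "2" = 2, "3" = 3, "4A" = 4, "4B" = 4, "4C" = 4, "5" = 5)

#' Remove duplicate compound annotations
#'
#' Among assignments whose top candidates share an identifier (or, lacking
#' identifiers, a case/whitespace-normalized name), only the best one is
#' retained (best level first, then highest top reverse score). Removals and
#' name-collisions across distinct identifiers are reported in the
#' `removed` / `review` attributes.
#'
#' @param assignments list of `level_assignment` objects (ranked).
#' @return the retained assignments, with attributes `removed` (character
#'   feature ids) and `review` (identifiers flagged for manual review).
#' @export
dedupe <- function(assignments) {
  has_cand <- vapply(assignments, function(a)
    !is.null(a$candidates) && nrow(a$candidates) > 0L, logical(1))
  keyed <- assignments[has_cand]
  ids <- vapply(keyed, function(a) as.character(a$candidates$identifier[1L]), "")
  nms <- vapply(keyed, function(a) normalize_name(a$candidates$name[1L]), "")
  key <- ifelse(nzchar(ids), paste0("id:", ids), paste0("name:", nms))
  lvl <- vapply(keyed, function(a) .LEVEL_ORDER[[a$level]], numeric(1))
  top_rsi <- vapply(keyed, function(a) {
    v <- suppressWarnings(as.numeric(a$candidates$rsi[1L]))
    if (is.na(v)) -Inf else v
  }, numeric(1))
  keep <- rep(TRUE, length(keyed))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[order(lvl[idx], -top_rsi[idx])][1L]
    keep[setdiff(idx, best)] <- FALSE
  }
  # identical names under distinct identifiers: duplicates by the name rule
  review <- character(0)
  for (nm in unique(nms[duplicated(nms) & nzchar(nms)])) {
    idx <- which(nms == nm & keep)
    if (length(unique(ids[idx])) > 1L) {
      best <- idx[order(lvl[idx], -top_rsi[idx])][1L]
      keep[setdiff(idx, best)] <- FALSE
      review <- c(review, unique(ids[idx]))
    }
  }
  removed <- vapply(keyed[!keep], `[[`, "", "feature_id")
  out <- c(keyed[keep], assignments[!has_cand])
  attr(out, "removed") <- removed
  attr(out, "review") <- review
  out
}

evidence_to_row <- function(ev, rank) {
  data.frame(name = ev$name, identifier = ev$identifier, rank = rank,
             si = ev$si, rsi = ev$rsi, delta_ri = ev$delta_ri,
             ri_source = ev$ri_source, rhrmf = ev$rhrmf,
             molecular_ion = ev$molecular_ion,
             matched_fragments = ev$matched_fragments,
             evidence_count = ev$evidence_count,
             stringsAsFactors = FALSE)
}

#' Annotate one feature against a spectral library
#'
#' Builds [candidate_evidence()] for every library entry, assigns levels with
#' [assign_level()], ranks the candidates at the best achieved level, and
#' returns a `level_assignment`. Features matching nothing are Level 5
#' (reproducibly detected unknown). Blank filtering must have been applied
#' upstream (see [annotate_run()]); this function assumes the feature passed.
#'
#' @param feature a [feature_record()].
#' @param library list of [library_entry()] objects.
#' @param cal optional [alkane_calibration()]; without it (or with the RT out
#'   of span) all RI criteria are unavailable.
#' @param config a [scoring_config()].
#' @param weighting a [match_weighting()] for spectral similarity.
#' @param tol_ppm accurate-mass tolerance for RHRMF / molecular ion.
#' @param h_transfer hydrogen-transfer allowance for RHRMF.
#' @return a `level_assignment`: list with `feature_id`, `level`,
#'   `candidates` (ranked evidence data frame), `multi_hit`, `rationale`,
#'   `blank_pass`.
#' @export
annotate_feature <- function(feature, library, cal = NULL,
                             config = scoring_config(),
                             weighting = match_weighting(),
                             tol_ppm = 10, h_transfer = 1) {
  if (length(library) == 0L) {
    warning("empty library: feature ", feature$feature_id,
            " is Level 5 by definition", call. = FALSE)
  }
  observed_ri <- NA_real_
  if (!is.null(cal)) {
    observed_ri <- tryCatch(as.numeric(compute_retention_index(feature$retention_time, cal)),
                            error = function(e) NA_real_)
  }
  accurate_query <- spectrum_resolution(feature$spectrum) == "accurate"
  evs <- vector("list", length(library))
  levels <- character(length(library))
  for (i in seq_along(library)) {
    entry <- library[[i]]
    si <- dot_product_score(feature$spectrum, entry$spectrum, weighting)
    rsi <- reverse_dot_product_score(feature$spectrum, entry$spectrum, weighting)
    nfrag <- count_matched_fragments(feature$spectrum, entry$spectrum, weighting)
    delta_ri <- if (!is.na(observed_ri) && !is.na(entry$retention_index)) {
      observed_ri - entry$retention_index
    } else NA_real_
    # expensive accurate-mass layers only where they can matter
    rh <- NA_real_
    mol <- FALSE
    acc_ions <- 0L
    spectral_plausible <- (rsi > config$rsi_min && si > config$si_min) ||
      (entry$ionization %in% c("PCI", "ECNI", "APCI") && nfrag >= config$ci_min_fragments)
    alt_plausible <- !is.na(delta_ri) && abs(delta_ri) < config$level3_alt_ri_max
    if (accurate_query && !is.null(entry$formula) &&
        (spectral_plausible || alt_plausible)) {
      rh <- rhrmf(feature$spectrum, entry$spectrum, entry$formula, weighting,
                  tol_ppm, h_transfer)
      mol <- detect_molecular_ion(feature$spectrum, entry$formula, tol_ppm)$present
    }
    if (accurate_query && alt_plausible &&
        spectrum_resolution(entry$spectrum) == "accurate") {
      acc_ions <- count_matched_fragments(feature$spectrum, entry$spectrum,
                                          match_weighting(tol_ppm = tol_ppm))
    }
    exact_rsi <- if (spectrum_resolution(entry$spectrum) == "accurate") rsi else NA_real_
    evs[[i]] <- candidate_evidence(
      feature_id = feature$feature_id, name = entry$name,
      identifier = entry$identifier, si = si, rsi = rsi, delta_ri = delta_ri,
      library_ri = entry$retention_index, ri_source = entry$ri_source,
      rhrmf = rh, exact_mass_library_rsi = exact_rsi, molecular_ion = mol,
      matched_fragments = nfrag, ionization = entry$ionization,
      accurate_ion_matches = acc_ions, evidence_count = entry$evidence_count)
    levels[i] <- as.character(assign_level(evs[[i]], config))
  }
  best <- if (any(levels == "2", na.rm = TRUE)) "2" else
    if (any(levels == "3", na.rm = TRUE)) "3" else "5"
  if (best == "5") {
    return(structure(list(feature_id = feature$feature_id, level = "5",
                          candidates = NULL, multi_hit = FALSE,
                          rationale = "no candidate met Level 1-4 criteria",
                          blank_pass = TRUE, observed_ri = observed_ri),
                     class = "level_assignment"))
  }
  at_level <- evs[!is.na(levels) & levels == best]
  rk <- rank_candidates(at_level, config)
  cand_df <- do.call(rbind, lapply(seq_along(rk$ranked), function(i)
    evidence_to_row(rk$ranked[[i]], i)))
  structure(list(feature_id = feature$feature_id, level = best,
                 candidates = cand_df, multi_hit = rk$multi_hit,
                 rationale = sprintf("%d candidate(s) at Level %s%s",
                                     nrow(cand_df), best,
                                     if (rk$multi_hit) "; multiple top hits" else ""),
                 blank_pass = TRUE, observed_ri = observed_ri),
            class = "level_assignment")
}

#' @export
print.level_assignment <- function(x, ...) {
  cat("<assignment> ", x$feature_id, ": Level ", x$level,
      if (isTRUE(x$multi_hit)) " (multi-hit)" else "", "\n", sep = "")
  if (!is.null(x$candidates)) {
    print(utils::head(x$candidates, 3))
  }
  invisible(x)
}

#' Annotate a whole run: blank filter, score, rank, dedupe
#'
#' Applies [passes_blank_filter()] to every feature; features failing it
#' receive no level (`blank_pass = FALSE`). Passing features are annotated
#' with [annotate_feature()] and optionally deduplicated on top-candidate
#' identifiers.
#'
#' @param features list of [feature_record()] objects.
#' @param library list of [library_entry()] objects.
#' @param cal optional [alkane_calibration()].
#' @param config a [scoring_config()].
#' @param bff a [bff_config()].
#' @param weighting a [match_weighting()].
#' @param deduplicate remove duplicate compound annotations (default `FALSE`;
#'   validation metrics expect ranked, deduplicated input).
#' @param tol_ppm,h_transfer accurate-mass parameters, as in
#'   [annotate_feature()].
#' @return list of `level_assignment` objects, each carrying `blank_pass`,
#'   `blank_threshold`, `sample_statistic` and mean abundances.
#' @export
annotate_run <- function(features, library, cal = NULL,
                         config = scoring_config(), bff = bff_config(),
                         weighting = match_weighting(), deduplicate = FALSE,
                         tol_ppm = 10, h_transfer = 1) {
  out <- lapply(features, function(f) {
    bf <- passes_blank_filter(f, bff)
    if (!bf$pass) {
      a <- structure(list(feature_id = f$feature_id, level = NA_character_,
                          candidates = NULL, multi_hit = FALSE,
                          rationale = "failed blank feature filter",
                          blank_pass = FALSE), class = "level_assignment")
    } else {
      a <- annotate_feature(f, library, cal, config, weighting, tol_ppm, h_transfer)
    }
    a$blank_threshold <- bf$threshold
    a$sample_statistic <- bf$statistic_value
    a$sample_mean_abundance <- mean(f$sample_abundances)
    a$blank_mean_abundance <- if (length(f$blank_abundances) > 0L)
      mean(f$blank_abundances) else NA_real_
    a
  })
  if (deduplicate) out <- dedupe(out)
  out
}

#' Summarize a set of assignments
#'
#' Counts per level, the multi-hit fraction, and blank-filter failures.
#' @param assignments list of `level_assignment` objects.
#' @return data frame with one row per level plus `blank_fail`.
#' @export
summarize_assignments <- function(assignments) {
  lvl <- vapply(assignments, function(a)
    if (isTRUE(a$blank_pass)) a$level else "blank_fail", "")
  mh <- vapply(assignments, function(a) isTRUE(a$multi_hit), logical(1))
  tab <- table(factor(lvl, levels = c("1", "2", "3", "4A", "4B", "4C", "5", "blank_fail")))
  data.frame(level = names(tab), n = as.integer(tab),
             multi_hit = as.integer(tapply(mh, factor(lvl, levels = names(tab)), sum,
                                           default = 0L)))
}
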