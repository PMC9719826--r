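# Per-candidate evidence layers: peak matching, dot / reverse dot product,
# retention index, RI match rule, (R)HRMF, molecular ion, fragment counting.

#' Peak-matching and weighting configuration
#'
#' Spectral similarity is computed on weighted intensities
#' `w = mz^mz_exponent * intensity^intensity_exponent`. Peak matching uses
#' integer binning of width `bin_width` Th (unit-resolution mode) or a ppm
#' tolerance (accurate mode, selected by supplying `tol_ppm`).
#'
#' @param mz_exponent,intensity_exponent non-negative weighting exponents;
#'   defaults 0 and 0.5 (square-root intensity, the common library-search
#'   convention on the 0-1000 scale).
#' @param bin_width bin width in Th for unit-resolution matching.
#' @param tol_ppm if non-`NULL`, accurate-mass matching at this ppm tolerance.
#' @export
match_weighting <- function(mz_exponent = 0, intensity_exponent = 0.5,
                            bin_width = 1, tol_ppm = NULL) {
  stopifnot(mz_exponent >= 0, intensity_exponent >= 0)
  if (is.null(tol_ppm)) stopifnot(bin_width > 0) else stopifnot(tol_ppm > 0)
  structure(list(mz_exponent = mz_exponent, intensity_exponent = intensity_exponent,
                 bin_width = bin_width, tol_ppm = tol_ppm),
            class = "match_weighting")
}

#' Pair query and library peaks
#'
#' Greedy nearest-m/z pairing within the bin (unit mode) or ppm tolerance
#' (accurate mode); each peak is used at most once. Candidate pairs are
#' accepted in order of increasing m/z distance, ties broken toward higher
#' combined intensity, then lower m/z, making the pairing symmetric in its two
#' arguments.
#'
#' @param query,library [spectrum()] objects.
#' @param weighting a [match_weighting()].
#' @return data frame with columns `query_idx`, `library_idx`.
#' @export
match_peaks <- function(query, library, weighting = match_weighting()) {
  stopifnot(nrow(query) > 0, nrow(library) > 0)
  dmz <- abs(outer(query$mz, library$mz, `-`))
  if (is.null(weighting$tol_ppm)) {
    qb <- round(query$mz / weighting$bin_width)
    lb <- round(library$mz / weighting$bin_width)
    ok <- outer(qb, lb, `==`)
    dist <- matrix(0, nrow(query), nrow(library))  # same bin: equal distance
  } else {
    ok <- dmz / outer(rep(1, nrow(query)), library$mz) * 1e6 <= weighting$tol_ppm
    dist <- dmz
  }
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(query_idx = integer(0), library_idx = integer(0)))
  }
  qi <- idx[, 1L]; li <- idx[, 2L]
  combined <- query$intensity[qi] + library$intensity[li]
  o <- order(dist[idx], -combined, pmin(query$mz[qi], library$mz[li]),
             pmax(query$mz[qi], library$mz[li]))
  qi <- qi[o]; li <- li[o]
  q_used <- logical(nrow(query)); l_used <- logical(nrow(library))
  keep_q <- integer(0); keep_l <- integer(0)
  for (k in seq_along(qi)) {
    if (!q_used[qi[k]] && !l_used[li[k]]) {
      q_used[qi[k]] <- TRUE; l_used[li[k]] <- TRUE
      keep_q <- c(keep_q, qi[k]); keep_l <- c(keep_l, li[k])
    }
  }
  o2 <- order(keep_q)
  data.frame(query_idx = keep_q[o2], library_idx = keep_l[o2])
}

peak_weights <- function(s, weighting) {
  s$mz^weighting$mz_exponent * s$intensity^weighting$intensity_exponent
}

cosine_1000 <- function(wq, wl, pairs) {
  # aligned vectors over the union of matched positions plus unmatched peaks
  dot <- sum(wq[pairs$query_idx] * wl[pairs$library_idx])
  nq <- sqrt(sum(wq^2)); nl <- sqrt(sum(wl^2))
  if (nq == 0 || nl == 0) {
    stop("undefined spectral score: all-zero weighted intensity vector", call. = FALSE)
  }
  round(1000 * dot / (nq * nl))
}

#' Forward dot-product spectral similarity (SI)
#'
#' Cosine of the weighted intensity vectors over the union of matched
#' positions, scaled to 0-1000 and rounded; symmetric in its arguments.
#'
#' @inheritParams match_peaks
#' @return integer score in 0-1000.
#' @export
dot_product_score <- function(query, library, weighting = match_weighting()) {
  pairs <- match_peaks(query, library, weighting)
  cosine_1000(peak_weights(query, weighting), peak_weights(library, weighting), pairs)
}

#' Reverse dot-product spectral similarity (RSI)
#'
#' The same cosine after discarding query peaks not matched to any library
#' peak, so that deconvolution artifacts absent from the library do not
#' penalize the score. Always at least the forward score.
#'
#' @inheritParams match_peaks
#' @return integer score in 0-1000.
#' @export
reverse_dot_product_score <- function(query, library, weighting = match_weighting()) {
  pairs <- match_peaks(query, library, weighting)
  wq <- peak_weights(query, weighting)
  wl <- peak_weights(library, weighting)
  if (sum(wq) == 0 || sum(wl) == 0) {
    stop("undefined spectral score: all-zero weighted intensity vector", call. = FALSE)
  }
  if (nrow(pairs) == 0L) return(0L)  # nothing matched: zero overlap
  wq[setdiff(seq_len(nrow(query)), pairs$query_idx)] <- 0
  cosine_1000(wq, wl, pairs)
}

#' Kovats retention index by linear interpolation
#'
#' Van den Dool & Kratz: `RI = 100*n + 100*(N - n)*(rt - t_n)/(t_N - t_n)` for
#' the bracketing calibration alkanes with carbon numbers n and N. By default
#' retention times outside the calibration span raise an error; with
#' `extrapolate = TRUE` the first/last segment is extended and the result
#' carries attribute `extrapolated = TRUE`.
#'
#' @param rt retention time in minutes.
#' @param cal an [alkane_calibration()].
#' @param extrapolate allow extrapolation beyond the alkane span.
#' @return dimensionless retention index.
#' @export
compute_retention_index <- function(rt, cal, extrapolate = FALSE) {
  tmin <- cal$retention_time[1L]
  tmax <- cal$retention_time[nrow(cal)]
  out_of_range <- rt < tmin || rt > tmax
  if (out_of_range && !extrapolate) {
    stop(sprintf("retention time %.4g min outside calibration span [%.4g, %.4g]",
                 rt, tmin, tmax), call. = FALSE)
  }
  i <- findInterval(rt, cal$retention_time, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(cal) - 1L)
  n1 <- cal$carbon_number[i]; n2 <- cal$carbon_number[i + 1L]
  t1 <- cal$retention_time[i]; t2 <- cal$retention_time[i + 1L]
  ri <- 100 * n1 + 100 * (n2 - n1) * (rt - t1) / (t2 - t1)
  if (out_of_range) attr(ri, "extrapolated") <- TRUE
  ri
}

#' Retention-index match rule
#'
#' Thresholds for accepting an RI match: experimental library RI must agree
#' within 50 units and 1.5 percent; predicted library RI within 100 units.
#' All comparisons are strict.
#'
#' @param max_abs_delta_experimental,max_rel_delta_experimental,max_abs_delta_predicted
#'   positive thresholds.
#' @export
ri_match_rule <- function(max_abs_delta_experimental = 50,
                          max_rel_delta_experimental = 0.015,
                          max_abs_delta_predicted = 100) {
  stopifnot(max_abs_delta_experimental > 0, max_rel_delta_experimental > 0,
            max_abs_delta_predicted > 0)
  structure(list(max_abs_delta_experimental = max_abs_delta_experimental,
                 max_rel_delta_experimental = max_rel_delta_experimental,
                 max_abs_delta_predicted = max_abs_delta_predicted),
            class = "ri_match_rule")
}

#' Test an observed retention index against a library value
#'
#' @param observed_ri,library_ri positive retention indices.
#' @param source `"experimental"` or `"predicted"` library RI provenance.
#' @param rule an [ri_match_rule()].
#' @return list with `pass` (logical) and `delta` (observed - library).
#' @export
ri_match <- function(observed_ri, library_ri, source = c("experimental", "predicted"),
                     rule = ri_match_rule()) {
  if (identical(source, "absent") || is.na(observed_ri) || is.na(library_ri)) {
    stop("no retention index available for RI matching", call. = FALSE)
  }
  source <- match.arg(source)
  stopifnot(observed_ri > 0, library_ri > 0)
  delta <- observed_ri - library_ri
  pass <- if (source == "experimental") {
    abs(delta) < rule$max_abs_delta_experimental &&
      abs(delta) / library_ri < rule$max_rel_delta_experimental
  } else {
    abs(delta) < rule$max_abs_delta_predicted
  }
  list(pass = pass, delta = delta)
}

# Sorted fragment-cation mass set for a candidate formula: monoisotopic masses
# of all subformulas, with the hydrogen count adjustable by +/- h_transfer
# within the parent bounds (EI rearrangements), minus the electron mass.
# Because adjusted counts stay within the parent bounds, every adjusted
# formula is itself a subformula, so the full subformula set already covers
# all h_transfer values.
fragment_cation_masses <- function(candidate, h_transfer = 1) {
  stopifnot(h_transfer >= 0)
  tab <- enumerate_subformulas(candidate)
  sort(unique(tab$mass)) - ELECTRON_MASS
}

peaks_explained <- function(mz, cation_masses, tol_ppm) {
  vapply(mz, function(x) {
    i <- findInterval(x, cation_masses)
    lo <- if (i >= 1L) cation_masses[i] else -Inf
    hi <- if (i < length(cation_masses)) cation_masses[i + 1L] else Inf
    min(abs(x - lo), abs(hi - x)) / x * 1e6 <= tol_ppm
  }, logical(1))
}

#' High-resolution mass filter score (HRMF)
#'
#' Percentage of spectrum peaks whose accurate m/z can be explained, within
#' `tol_ppm`, as the cation of a subformula of the candidate molecular
#' formula (hydrogen count adjustable by `h_transfer` within the parent
#' bounds to admit common EI rearrangements).
#'
#' @param spectrum accurate-resolution [spectrum()].
#' @param candidate candidate molecular formula (object or string).
#' @param tol_ppm mass tolerance in ppm.
#' @param h_transfer allowed hydrogen-transfer range.
#' @return percentage in 0-100.
#' @export
hrmf <- function(spectrum, candidate, tol_ppm = 10, h_transfer = 1) {
  if (spectrum_resolution(spectrum) != "accurate") {
    stop("HRMF requires an accurate-resolution spectrum", call. = FALSE)
  }
  if (is.character(candidate)) candidate <- parse_formula(candidate)
  cm <- fragment_cation_masses(candidate, h_transfer)
  100 * mean(peaks_explained(spectrum$mz, cm, tol_ppm))
}

#' Reverse high-resolution mass filter score (RHRMF)
#'
#' [hrmf()] restricted to the query peaks matched to library peaks by
#' [match_peaks()], so unmatched deconvolution artifacts cannot lower the
#' score. When no query-library peak match exists the score is undefined and
#' `NA` is returned (criterion unavailable, not 0).
#'
#' @inheritParams hrmf
#' @param query,library [spectrum()] objects (query accurate-resolution).
#' @param weighting [match_weighting()] used for the query-library pairing.
#' @return percentage in 0-100, or `NA` if no peaks match.
#' @export
rhrmf <- function(query, library, candidate, weighting = match_weighting(),
                  tol_ppm = 10, h_transfer = 1) {
  if (spectrum_resolution(query) != "accurate") {
    stop("RHRMF requires an accurate-resolution query spectrum", call. = FALSE)
  }
  pairs <- match_peaks(query, library, weighting)
  if (nrow(pairs) == 0L) return(NA_real_)
  if (is.character(candidate)) candidate <- parse_formula(candidate)
  cm <- fragment_cation_masses(candidate, h_transfer)
  100 * mean(peaks_explained(query$mz[pairs$query_idx], cm, tol_ppm))
}

#' Detect the molecular ion of a candidate formula
#'
#' Tests whether a peak lies within `tol_ppm` of the radical-cation m/z
#' (monoisotopic mass minus one electron mass) of the candidate.
#'
#' @inheritParams hrmf
#' @return list with `present` (logical), `mass_error_ppm` of the nearest
#'   peak, and `expected_mz`.
#' @export
detect_molecular_ion <- function(spectrum, candidate, tol_ppm = 10) {
  if (is.character(candidate)) candidate <- parse_formula(candidate)
  expected <- monoisotopic_mass(candidate) - ELECTRON_MASS
  err <- (spectrum$mz - expected) / expected * 1e6
  i <- which.min(abs(err))
  list(present = abs(err[i]) <= tol_ppm, mass_error_ppm = err[i],
       expected_mz = expected)
}

#' Count matched fragments between two spectra
#'
#' Size of the [match_peaks()] pairing; used for the chemical-ionization
#' criterion (at least five fragments matched to a library record).
#'
#' @inheritParams match_peaks
#' @export
count_matched_fragments <- function(query, library, weighting = match_weighting()) {
  nrow(match_peaks(query, library, weighting))
}
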