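# Blank feature filtering: threshold computation and feature gating.
# Required before any confidence-level assignment.

#' Blank-feature-filter configuration
#'
#' @param c positive multiplier on the blank signal (common practice ranges
#'   2-10; default 3).
#' @param statistic sample statistic compared against the threshold: `"mean"`
#'   (default) or `"percentile"`.
#' @param percentile percentile in (0, 1] when `statistic = "percentile"`.
#' @param min_blanks minimum recommended number of blanks; fewer triggers a
#'   warning, not an error.
#' @export
bff_config <- function(c = 3, statistic = c("mean", "percentile"),
                       percentile = 0.5, min_blanks = 4) {
  statistic <- match.arg(statistic)
  stopifnot(c > 0, percentile > 0, percentile <= 1, min_blanks >= 1)
  structure(list(c = c, statistic = statistic, percentile = percentile,
                 min_blanks = min_blanks), class = "bff_config")
}

#' Blank-feature-filter threshold
#'
#' `threshold = c * (blank_mean + 3 * blank_sd)`; zero when all blank
#' abundances are zero.
#'
#' @param blank_mean,blank_sd mean and standard deviation of the blank
#'   abundances (abundance units, `blank_sd >= 0`).
#' @param config a [bff_config()].
#' @return threshold in abundance units.
#' @export
bff_threshold <- function(blank_mean, blank_sd, config = bff_config()) {
  stopifnot(blank_sd >= 0, blank_mean >= 0)
  config$c * (blank_mean + 3 * blank_sd)
}

#' Gate a feature through the blank filter
#'
#' Computes blank statistics from the feature's blank abundances (missing
#' values treated as 0 with a warning upstream at read time), the sample
#' statistic per config, and passes the feature iff the statistic is strictly
#' greater than the threshold.
#'
#' @param feature a [feature_record()].
#' @param config a [bff_config()].
#' @return list with `pass`, `threshold`, `statistic_value`, `n_blanks`.
#' @export
passes_blank_filter <- function(feature, config = bff_config()) {
  if (length(feature$sample_abundances) == 0L) {
    stop("feature ", feature$feature_id, " has no sample abundances", call. = FALSE)
  }
  blanks <- feature$blank_abundances
  n_blanks <- length(blanks)
  if (n_blanks < config$min_blanks) {
    warning("feature ", feature$feature_id, ": only ", n_blanks,
            " blank measurement(s); at least ", config$min_blanks,
            " blanks are recommended", call. = FALSE)
  }
  bmean <- if (n_blanks > 0L) mean(blanks) else 0
  bsd <- if (n_blanks > 1L) stats::sd(blanks) else 0
  threshold <- bff_threshold(bmean, bsd, config)
  value <- switch(config$statistic,
    mean = mean(feature$sample_abundances),
    percentile = as.numeric(stats::quantile(feature$sample_abundances,
                                            probs = config$percentile, type = 7)))
  list(pass = value > threshold, threshold = threshold,
       statistic_value = value, n_blanks = n_blanks)
}
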