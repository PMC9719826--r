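# Validation metrics: per-level false-positive / false-negative rates against
# a spiked-standard truth sheet, per-filter candidate-retention summaries,
# total spectral ion abundance.

#' Evaluate assignments against a truth sheet
#'
#' For each confidence level L: the false-positive rate is the fraction of
#' features assigned L whose top-ranked candidate is not the true compound;
#' the false-negative rate is the fraction of detected truth compounds not
#' assigned L. With `isomer_mode = "equivalence"` a top candidate within the
#' truth compound's equivalence group (close isomers) is not counted as a
#' false positive.
#'
#' @param assignments ranked (and deduplicated, if desired) list of
#'   `level_assignment` objects.
#' @param truth data frame with columns `name`, `identifier`,
#'   `equivalence_group`, and `feature_id` linking each truth compound to its
#'   feature. Without `feature_id`, false positives fall back to membership
#'   (top candidate's identifier must belong to some truth compound), which
#'   cannot detect cross-assignments between truth compounds.
#' @param isomer_mode `"exact"` or `"equivalence"`.
#' @return data frame with one row per level: `level`, `n_assigned`,
#'   `n_false_positive`, `fp_rate` (percent), `n_truth_detected`,
#'   `n_false_negative`, `fn_rate` (percent).
#' @export
evaluate <- function(assignments, truth, isomer_mode = c("exact", "equivalence")) {
  isomer_mode <- match.arg(isomer_mode)
  if (nrow(truth) == 0L) stop("empty truth sheet", call. = FALSE)
  if (anyDuplicated(truth$identifier)) {
    stop("truth identifiers must be unique", call. = FALSE)
  }
  has_link <- "feature_id" %in% names(truth)
  fid <- vapply(assignments, `[[`, "", "feature_id")
  lvl <- vapply(assignments, function(a) a$level %||% NA_character_, "")
  blank_pass <- vapply(assignments, function(a) isTRUE(a$blank_pass), logical(1))
  top_id <- vapply(assignments, function(a) {
    if (is.null(a$candidates) || nrow(a$candidates) == 0L) NA_character_
    else as.character(a$candidates$identifier[1L])
  }, "")
  detected <- if (has_link) truth$feature_id %in% fid[blank_pass] else
    rep(TRUE, nrow(truth))
  levels_seen <- c("1", "2", "3", "4A", "4B", "4C", "5")
  rows <- lapply(levels_seen, function(L) {
    at <- which(!is.na(lvl) & lvl == L & blank_pass)
    correct <- vapply(at, function(i) {
      if (is.na(top_id[i])) return(FALSE)
      if (has_link) {
        tr <- truth[truth$feature_id == fid[i], , drop = FALSE]
        if (nrow(tr) == 0L) return(FALSE)
        if (isomer_mode == "exact") {
          top_id[i] == tr$identifier[1L]
        } else {
          grp <- truth$equivalence_group[truth$identifier == top_id[i]]
          top_id[i] == tr$identifier[1L] ||
            (length(grp) == 1L && grp == tr$equivalence_group[1L])
        }
      } else {
        top_id[i] %in% truth$identifier
      }
    }, logical(1))
    n_assigned <- length(at)
    n_fp <- sum(!correct)
    if (has_link) {
      truth_feats <- truth$feature_id[detected]
      assigned_L <- fid[!is.na(lvl) & lvl == L & blank_pass]
      n_fn <- sum(!truth_feats %in% assigned_L)
      n_det <- sum(detected)
    } else {
      n_fn <- NA_integer_; n_det <- NA_integer_
    }
    data.frame(level = L, n_assigned = n_assigned, n_false_positive = n_fp,
               fp_rate = if (n_assigned > 0L) 100 * n_fp / n_assigned else NA_real_,
               n_truth_detected = n_det, n_false_negative = n_fn,
               fn_rate = if (!is.na(n_det) && n_det > 0L) 100 * n_fn / n_det else NA_real_)
  })
  do.call(rbind, rows)
}

#' Read a filter-count table
#'
#' CSV with columns `compound`, `total_detected`, one retained-count column
#' per filter, and optionally `Yes`/`No` (or logical) flag columns recording
#' whether the correct candidate was retained by a filter.
#'
#' @param path file path.
#' @export
read_filter_counts <- function(path) {
  df <- read_csv_skip_comments(path)
  for (col in c("compound", "total_detected")) {
    if (!col %in% names(df)) stop("filter-count table missing column ", sQuote(col), call. = FALSE)
  }
  df
}

#' Percent of candidates removed per filter
#'
#' Per compound and filter: `100 * (1 - retained / total_detected)`. The
#' summary is the equally-weighted arithmetic mean and sample standard
#' deviation across compounds (`aggregate = "per_compound"`), or the pooled
#' percentage over summed counts (`aggregate = "pooled"`, sd `NA`).
#'
#' @param rows filter-count data frame (see [read_filter_counts()]).
#' @param filters names of the retained-count columns; default all numeric
#'   columns other than `total_detected`.
#' @param aggregate summary mode.
#' @return list with `summary` (data frame: `filter`, `mean_percent_removed`,
#'   `sd_percent_removed`) and `per_compound` (compound x filter percent
#'   matrix as a data frame).
#' @export
percent_filtered <- function(rows, filters = NULL,
                             aggregate = c("per_compound", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (is.null(filters)) {
    num <- vapply(rows, is.numeric, logical(1))
    filters <- setdiff(names(rows)[num], c("total_detected"))
  }
  bad <- rows$total_detected == 0
  if (any(bad)) {
    warning(sum(bad), " compound(s) with zero detected candidates excluded", call. = FALSE)
    rows <- rows[!bad, , drop = FALSE]
  }
  for (f in filters) {
    if (any(rows[[f]] > rows$total_detected | rows[[f]] < 0)) {
      stop("retained counts for filter ", sQuote(f),
           " outside [0, total_detected]", call. = FALSE)
    }
  }
  pct <- as.data.frame(lapply(rows[filters], function(r)
    100 * (1 - r / rows$total_detected)))
  pct <- cbind(compound = rows$compound, pct)
  summary <- if (aggregate == "per_compound") {
    data.frame(filter = filters,
               mean_percent_removed = vapply(filters, function(f) mean(pct[[f]]), numeric(1)),
               sd_percent_removed = vapply(filters, function(f) stats::sd(pct[[f]]), numeric(1)),
               row.names = NULL)
  } else {
    data.frame(filter = filters,
               mean_percent_removed = vapply(filters, function(f)
                 100 * (1 - sum(rows[[f]]) / sum(rows$total_detected)), numeric(1)),
               sd_percent_removed = NA_real_, row.names = NULL)
  }
  list(summary = summary, per_compound = pct)
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  f <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(f))
  out[f %in% c("YES", "TRUE", "1")] <- TRUE
  out[f %in% c("NO", "FALSE", "0")] <- FALSE
  out
}

#' False-negative rate of a filter from correct-retained flags
#'
#' A false negative is a validated compound whose correct assignment was
#' removed by the filter: `100 * (# flags FALSE) / (# rows)`.
#'
#' @param rows filter-count data frame.
#' @param flag_column name of the Yes/No (or logical) flag column.
#' @return percentage in 0-100.
#' @export
false_negative_rate_from_flags <- function(rows, flag_column) {
  if (!flag_column %in% names(rows)) {
    stop("missing flag column ", sQuote(flag_column), call. = FALSE)
  }
  flags <- as_flag(rows[[flag_column]])
  if (any(is.na(flags))) {
    stop("flag column ", sQuote(flag_column), " has unreadable values", call. = FALSE)
  }
  100 * sum(!flags) / length(flags)
}

#' Number of compounds with a single retained candidate
#'
#' @param rows filter-count data frame.
#' @param filter retained-count column name.
#' @return integer count of rows with exactly one candidate retained.
#' @export
single_candidate_count <- function(rows, filter) {
  sum(rows[[filter]] == 1)
}

#' Total spectral ion abundance from peak area or height
#'
#' Scales an integrated peak area (or height) by the run's average ratio of
#' total spectral ion abundance to area/height.
#'
#' @param peak_area_or_height positive abundance.
#' @param avg_ratio positive dimensionless ratio.
#' @export
total_spectral_ion_abundance <- function(peak_area_or_height, avg_ratio) {
  if (any(avg_ratio <= 0)) stop("avg_ratio must be positive", call. = FALSE)
  if (any(peak_area_or_height <= 0)) stop("peak area/height must be positive", call. = FALSE)
  peak_area_or_height * avg_ratio
}
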