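# Readers/writers: MSP spectral libraries, feature tables, alkane
# calibrations, spike sheets, results tables. All tables are UTF-8 CSV with
# "." decimal separator; lines starting with "#" carry provenance headers and
# are skipped on read.

#' Construct a spectral-library entry
#'
#' @param name compound name (required).
#' @param identifier CAS-RN or other identifier string (may be `""`).
#' @param spectrum a [spectrum()] object.
#' @param formula optional [chem_formula()] (or string).
#' @param retention_index optional dimensionless RI.
#' @param ri_source `"experimental"`, `"predicted"`, or `"absent"`.
#' @param evidence_count optional non-negative metadata occurrence count.
#' @param ionization one of `"EI"`, `"PCI"`, `"ECNI"`, `"APCI"`.
#' @param expected_rt optional retention time (min) for in-house standards.
#' @param metadata named list of extra header fields (preserved on round-trip).
#' @export
library_entry <- function(name, spectrum, identifier = "", formula = NULL,
                          retention_index = NA_real_,
                          ri_source = c("absent", "experimental", "predicted"),
                          evidence_count = NA_integer_,
                          ionization = c("EI", "PCI", "ECNI", "APCI"),
                          expected_rt = NA_real_, metadata = list()) {
  ri_source <- match.arg(ri_source)
  ionization <- match.arg(ionization)
  if (!nzchar(name)) stop("library entry requires a non-empty name", call. = FALSE)
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!is.na(retention_index) && ri_source == "absent") {
    stop("retention_index present but ri_source is 'absent'", call. = FALSE)
  }
  if (!is.na(evidence_count) && evidence_count < 0) {
    stop("evidence_count must be non-negative", call. = FALSE)
  }
  structure(list(name = name, identifier = identifier, formula = formula,
                 spectrum = spectrum, retention_index = retention_index,
                 ri_source = ri_source, evidence_count = evidence_count,
                 ionization = ionization, expected_rt = expected_rt,
                 metadata = metadata),
            class = "library_entry")
}

#' Construct a feature record
#'
#' A deconvoluted GC-HRMS feature: spectrum, retention time, and per-sample /
#' per-blank abundances.
#'
#' @param feature_id identifier string.
#' @param retention_time retention time in minutes (> 0).
#' @param spectrum a [spectrum()] object.
#' @param sample_abundances named numeric vector (>= 1 value).
#' @param blank_abundances named numeric vector (may be empty).
#' @param reference_mz optional designated precursor / reference m/z (Th).
#' @export
feature_record <- function(feature_id, retention_time, spectrum,
                           sample_abundances, blank_abundances = numeric(0),
                           reference_mz = NA_real_) {
  stopifnot(retention_time > 0)
  if (length(sample_abundances) == 0L) {
    stop("feature ", feature_id, " has no sample abundances", call. = FALSE)
  }
  structure(list(feature_id = feature_id, retention_time = retention_time,
                 spectrum = spectrum, sample_abundances = sample_abundances,
                 blank_abundances = blank_abundances, reference_mz = reference_mz),
            class = "feature_record")
}

#' Construct an alkane calibration
#'
#' @param carbon_number strictly increasing integer carbon numbers (>= 2 points).
#' @param retention_time strictly increasing retention times in minutes.
#' @export
alkane_calibration <- function(carbon_number, retention_time) {
  stopifnot(length(carbon_number) == length(retention_time), length(carbon_number) >= 2)
  if (any(diff(carbon_number) <= 0) || any(diff(retention_time) <= 0)) {
    stop("carbon numbers and retention times must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(carbon_number = as.integer(carbon_number),
                       retention_time = retention_time),
            class = c("alkane_calibration", "data.frame"))
}

# ---- MSP (NIST text dialect) ----------------------------------------------

.MSP_KNOWN <- c("name", "id", "cas#", "formula", "ri", "ri_type", "ionization",
                "evidence_count", "resolution", "expected_rt", "num peaks")

#' Read an MSP spectral library
#'
#' NIST text dialect: `Name:`, optional `CAS#:`/`ID:`, `Formula:`, `RI:`,
#' `RI_Type:`, `Ionization:`, `Evidence_Count:`, `Resolution:`,
#' `Expected_RT:` headers, then `Num Peaks: n` followed by n `mz intensity`
#' pairs. Unknown headers are preserved in each entry's `metadata`.
#'
#' @param path file path.
#' @return list of [library_entry()] objects.
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  entries <- list()
  i <- 1L; n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    fields <- list(); meta <- list()
    start_line <- i
    while (i <= n && nzchar(trimws(lines[i]))) {
      line <- lines[i]
      sep <- regexpr(":", line, fixed = TRUE)
      if (sep < 0) stop("MSP format error at line ", i, ": missing ':' header separator", call. = FALSE)
      key <- tolower(trimws(substr(line, 1L, sep - 1L)))
      val <- trimws(substr(line, sep + 1L, nchar(line)))
      if (key == "num peaks") {
        npk <- suppressWarnings(as.integer(val))
        if (is.na(npk) || npk < 1L) {
          stop("MSP format error at line ", i, ": bad Num Peaks value", call. = FALSE)
        }
        peak_lines <- character(0)
        j <- i + 1L
        while (j <= n && nzchar(trimws(lines[j]))) { peak_lines <- c(peak_lines, lines[j]); j <- j + 1L }
        toks <- unlist(strsplit(trimws(peak_lines), "[[:space:];]+"))
        toks <- toks[nzchar(toks)]
        vals <- suppressWarnings(as.numeric(toks))
        if (any(is.na(vals))) {
          stop("MSP format error in record ", sQuote(fields$name %||% "<unnamed>"),
               ": unreadable peak value near line ", i, call. = FALSE)
        }
        if (length(vals) != 2L * npk) {
          stop("MSP format error in record ", sQuote(fields$name %||% "<unnamed>"),
               " at line ", i, ": declared ", npk, " peaks, found ", length(vals) / 2,
               call. = FALSE)
        }
        fields$peaks <- matrix(vals, ncol = 2L, byrow = TRUE)
        i <- j
        break
      }
      if (key %in% .MSP_KNOWN) fields[[key]] <- val else meta[[key]] <- val
      i <- i + 1L
    }
    if (is.null(fields$name)) {
      stop("MSP record starting at line ", start_line, " is missing required field Name", call. = FALSE)
    }
    if (is.null(fields$peaks)) {
      stop("MSP record ", sQuote(fields$name), " has no Num Peaks section", call. = FALSE)
    }
    ri <- if (!is.null(fields$ri)) as.numeric(fields$ri) else NA_real_
    ri_source <- tolower(fields$ri_type %||% if (is.na(ri)) "absent" else "experimental")
    entries[[length(entries) + 1L]] <- library_entry(
      name = fields$name,
      identifier = fields[["cas#"]] %||% fields$id %||% "",
      formula = fields$formula,
      spectrum = spectrum(fields$peaks[, 1L], fields$peaks[, 2L],
                          resolution = fields$resolution %||% "accurate"),
      retention_index = ri,
      ri_source = ri_source,
      evidence_count = as.integer(fields$evidence_count %||% NA_integer_),
      ionization = fields$ionization %||% "EI",
      expected_rt = as.numeric(fields$expected_rt %||% NA_real_),
      metadata = meta)
    i <- i + 1L
  }
  entries
}

#' Write an MSP spectral library
#'
#' @param entries list of [library_entry()] objects.
#' @param path output path.
#' @param header optional character vector written as leading comment-free
#'   `Comment:`-style metadata is not used; provenance goes in the results CSV.
#' @export
write_msp <- function(entries, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (e in entries) {
    writeLines(paste0("Name: ", e$name), con)
    if (nzchar(e$identifier)) writeLines(paste0("CAS#: ", e$identifier), con)
    if (!is.null(e$formula)) writeLines(paste0("Formula: ", format(e$formula)), con)
    if (!is.na(e$retention_index)) {
      writeLines(paste0("RI: ", format(e$retention_index, digits = 10)), con)
      writeLines(paste0("RI_Type: ", e$ri_source), con)
    }
    writeLines(paste0("Ionization: ", e$ionization), con)
    if (!is.na(e$evidence_count)) writeLines(paste0("Evidence_Count: ", e$evidence_count), con)
    if (!is.na(e$expected_rt)) writeLines(paste0("Expected_RT: ", format(e$expected_rt, digits = 10)), con)
    writeLines(paste0("Resolution: ", spectrum_resolution(e$spectrum)), con)
    for (k in names(e$metadata)) writeLines(paste0(k, ": ", e$metadata[[k]]), con)
    writeLines(paste0("Num Peaks: ", nrow(e$spectrum)), con)
    writeLines(sprintf("%.6f %.6g", e$spectrum$mz, e$spectrum$intensity), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---- feature tables --------------------------------------------------------

#' Feature-table dialect configuration
#'
#' Maps the column names of a feature CSV onto the fields of a
#' [feature_record()]. Abundance columns are recognized by name pattern; all
#' remaining unmatched columns are ignored.
#'
#' @param feature_id,rt,spectrum,reference_mz column names.
#' @param sample_pattern,blank_pattern regular expressions identifying sample
#'   and blank abundance columns.
#' @param resolution resolution class of the encoded spectra.
#' @export
feature_dialect <- function(feature_id = "feature_id", rt = "rt_min",
                            spectrum = "spectrum", reference_mz = "reference_mz",
                            sample_pattern = "^sample", blank_pattern = "^blank",
                            resolution = "accurate") {
  list(feature_id = feature_id, rt = rt, spectrum = spectrum,
       reference_mz = reference_mz, sample_pattern = sample_pattern,
       blank_pattern = blank_pattern, resolution = resolution)
}

read_csv_skip_comments <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Read a feature table
#'
#' CSV with one row per deconvoluted feature; the spectrum cell is encoded as
#' `"mz:intensity;mz:intensity;..."`. Blank and sample abundance columns are
#' identified by the dialect's name patterns; empty abundance cells are
#' treated as 0 with a warning.
#'
#' @param path file path.
#' @param dialect a [feature_dialect()].
#' @return list of [feature_record()] objects.
#' @export
read_feature_table <- function(path, dialect = feature_dialect()) {
  df <- read_csv_skip_comments(path)
  for (col in c(dialect$feature_id, dialect$rt, dialect$spectrum)) {
    if (!col %in% names(df)) {
      stop("feature table ", sQuote(path), " is missing mapped column ", sQuote(col), call. = FALSE)
    }
  }
  sample_cols <- grep(dialect$sample_pattern, names(df), value = TRUE)
  blank_cols <- grep(dialect$blank_pattern, names(df), value = TRUE)
  if (length(sample_cols) == 0L) {
    stop("feature table has no sample abundance columns matching ",
         sQuote(dialect$sample_pattern), call. = FALSE)
  }
  n_empty <- 0L
  get_abund <- function(row, cols) {
    v <- suppressWarnings(as.numeric(row[cols]))
    n_empty <<- n_empty + sum(is.na(v))
    v[is.na(v)] <- 0
    names(v) <- cols
    v
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    fid <- as.character(row[[dialect$feature_id]])
    spec <- tryCatch(decode_spectrum(row[[dialect$spectrum]], dialect$resolution),
                     error = function(e) {
                       stop("feature ", sQuote(fid), ": ", conditionMessage(e), call. = FALSE)
                     })
    ref <- if (dialect$reference_mz %in% names(df)) {
      suppressWarnings(as.numeric(row[[dialect$reference_mz]]))
    } else NA_real_
    feature_record(fid, as.numeric(row[[dialect$rt]]), spec,
                   get_abund(row, sample_cols), get_abund(row, blank_cols),
                   reference_mz = ref %||% NA_real_)
  })
  if (n_empty > 0L) {
    warning(n_empty, " empty abundance cell(s) treated as 0", call. = FALSE)
  }
  out
}

#' Write a feature table
#'
#' Inverse of [read_feature_table()] under the default dialect.
#'
#' @param features list of [feature_record()] objects.
#' @param path output path.
#' @param header optional character vector of provenance lines written as
#'   `# ...` comments.
#' @export
write_feature_table <- function(features, path, header = character(0)) {
  sample_cols <- sort(unique(unlist(lapply(features, function(f) names(f$sample_abundances)))))
  blank_cols <- sort(unique(unlist(lapply(features, function(f) names(f$blank_abundances)))))
  rows <- lapply(features, function(f) {
    row <- c(feature_id = f$feature_id,
             rt_min = format(f$retention_time, digits = 10),
             spectrum = encode_spectrum(f$spectrum),
             reference_mz = if (is.na(f$reference_mz)) "" else format(f$reference_mz, digits = 10))
    ab <- function(v, cols) {
      x <- structure(rep("0", length(cols)), names = cols)
      x[names(v)] <- format(v, digits = 10, trim = TRUE)
      x
    }
    c(row, ab(f$sample_abundances, sample_cols), ab(f$blank_abundances, blank_cols))
  })
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  write_csv_with_header(df, path, header)
}

write_csv_with_header <- function(df, path, header = character(0)) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header) > 0L) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read an alkane calibration table
#'
#' CSV with columns `carbon_number`, `rt_min`.
#' @param path file path.
#' @export
read_alkane_calibration <- function(path) {
  df <- read_csv_skip_comments(path)
  for (col in c("carbon_number", "rt_min")) {
    if (!col %in% names(df)) {
      stop("calibration file missing column ", sQuote(col), call. = FALSE)
    }
  }
  alkane_calibration(df$carbon_number, df$rt_min)
}

#' Write an alkane calibration table
#' @param cal an [alkane_calibration()].
#' @param path output path.
#' @param header optional provenance comment lines.
#' @export
write_alkane_calibration <- function(cal, path, header = character(0)) {
  write_csv_with_header(data.frame(carbon_number = cal$carbon_number,
                                   rt_min = cal$retention_time), path, header)
}

#' Read a spike (truth) sheet
#'
#' CSV with columns `name`, `identifier`, `equivalence_group` and optionally
#' `feature_id` (linking each truth compound to its feature for validation).
#' @param path file path.
#' @export
read_spike_sheet <- function(path) {
  df <- read_csv_skip_comments(path)
  for (col in c("name", "identifier", "equivalence_group")) {
    if (!col %in% names(df)) stop("spike sheet missing column ", sQuote(col), call. = FALSE)
  }
  if (anyDuplicated(df$identifier)) {
    stop("spike sheet identifiers must be unique", call. = FALSE)
  }
  df
}

#' Write the results table
#'
#' One row per feature-candidate pair at the assigned level (features with no
#' candidate get a single row with empty candidate fields): feature id,
#' candidate name/identifier, level, SI, RSI, delta RI, RI source, RHRMF,
#' molecular-ion flag, matched-fragment count, rank, multi-hit flag,
#' blank-filter status, and mean sample/blank abundances.
#'
#' @param assignments list of `level_assignment` objects (see
#'   [annotate_feature()]).
#' @param path output path.
#' @param header optional provenance comment lines (resolved config echo).
#' @export
write_results <- function(assignments, path, header = character(0)) {
  cols <- c("feature_id", "candidate_name", "candidate_id", "level", "rank",
            "si", "rsi", "delta_ri", "ri_source", "rhrmf", "molecular_ion",
            "matched_fragments", "multi_hit", "blank_pass", "blank_threshold",
            "sample_statistic", "sample_mean_abundance", "blank_mean_abundance",
            "rationale")
  rows <- list()
  fmt <- function(x) {
    if (is.null(x) || length(x) == 0L || is.na(x)) "" else
      if (is.logical(x)) tolower(as.character(x)) else
        if (is.numeric(x)) format(x, digits = 10, trim = TRUE) else as.character(x)
  }
  for (a in assignments) {
    base <- c(feature_id = a$feature_id, level = fmt(a$level),
              multi_hit = fmt(a$multi_hit), blank_pass = fmt(a$blank_pass),
              blank_threshold = fmt(a$blank_threshold),
              sample_statistic = fmt(a$sample_statistic),
              sample_mean_abundance = fmt(a$sample_mean_abundance),
              blank_mean_abundance = fmt(a$blank_mean_abundance),
              rationale = paste(a$rationale, collapse = "|"))
    if (!is.null(a$candidates) && nrow(a$candidates) > 0L) {
      for (i in seq_len(nrow(a$candidates))) {
        cc <- a$candidates[i, ]
        rows[[length(rows) + 1L]] <- c(base,
          candidate_name = fmt(cc$name), candidate_id = fmt(cc$identifier),
          rank = fmt(cc$rank), si = fmt(cc$si), rsi = fmt(cc$rsi),
          delta_ri = fmt(cc$delta_ri), ri_source = fmt(cc$ri_source),
          rhrmf = fmt(cc$rhrmf), molecular_ion = fmt(cc$molecular_ion),
          matched_fragments = fmt(cc$matched_fragments))
      }
    } else {
      rows[[length(rows) + 1L]] <- c(base, candidate_name = "", candidate_id = "",
        rank = "", si = "", rsi = "", delta_ri = "", ri_source = "", rhrmf = "",
        molecular_ion = "", matched_fragments = "")
    }
  }
  if (length(rows) == 0L) {
    df <- as.data.frame(matrix(character(0), ncol = length(cols),
                               dimnames = list(NULL, cols)), check.names = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)[, cols]
  }
  write_csv_with_header(df, path, header)
}
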