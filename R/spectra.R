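# Spectrum container and canonicalization.

#' Construct a spectrum
#'
#' Canonicalizes a peak list: peaks sorted by m/z, duplicate m/z merged by
#' intensity summation (deconvolution artifacts), non-negative intensities
#' required.
#'
#' @param mz numeric vector of m/z values (Th).
#' @param intensity numeric vector of intensities (arbitrary units, >= 0).
#' @param resolution `"unit"` or `"accurate"`.
#' @return data frame of class `spectrum` with columns `mz`, `intensity` and a
#'   `resolution` attribute.
#' @export
spectrum <- function(mz, intensity, resolution = c("accurate", "unit")) {
  resolution <- match.arg(resolution)
  if (length(mz) == 0L) stop("a spectrum needs at least one peak", call. = FALSE)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity lengths differ", call. = FALSE)
  }
  if (any(is.na(mz)) || any(is.na(intensity)) || any(intensity < 0)) {
    stop("peaks must have finite m/z and non-negative intensity", call. = FALSE)
  }
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(data.frame(mz = mz, intensity = intensity),
            resolution = resolution, class = c("spectrum", "data.frame"))
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", nrow(x), " peaks (", attr(x, "resolution"), " resolution), m/z ",
      sprintf("%.4f", min(x$mz)), "-", sprintf("%.4f", max(x$mz)), "\n", sep = "")
  invisible(x)
}

spectrum_resolution <- function(s) attr(s, "resolution") %||% "accurate"

`%||%` <- function(a, b) if (is.null(a)) b else a

# "mz:intensity;mz:intensity" <-> spectrum
encode_spectrum <- function(s) {
  paste(sprintf("%.6g:%.6g", s$mz, s$intensity), collapse = ";")
}

decode_spectrum <- function(text, resolution = "accurate") {
  pairs <- strsplit(trimws(text), ";", fixed = TRUE)[[1]]
  pairs <- pairs[nzchar(pairs)]
  if (length(pairs) == 0L) stop("empty spectrum string", call. = FALSE)
  parts <- strsplit(pairs, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed spectrum string: ", sQuote(text), call. = FALSE)
  mz <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  int <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (any(is.na(mz)) || any(is.na(int))) {
    stop("non-numeric value in spectrum string: ", sQuote(text), call. = FALSE)
  }
  spectrum(mz, int, resolution)
}
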