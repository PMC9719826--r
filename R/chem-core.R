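# Molecular-formula algebra: parsing, monoisotopic masses, subformula
# enumeration, formula decomposition from accurate mass, isotope patterns,
# Kendrick mass defect.

# IUPAC 2021 isotopic masses (Da) and abundances; first row per element is
# the lightest (monoisotopic reference) isotope.
.ISOTOPES <- list(
  C  = list(mass = c(12.0, 13.00335483507),
            abundance = c(0.9893, 0.0107)),
  H  = list(mass = c(1.00782503224, 2.01410177812),
            abundance = c(0.999885, 0.000115)),
  N  = list(mass = c(14.00307400443, 15.00010889888),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
            abundance = c(0.99757, 0.00038, 0.00205)),
  S  = list(mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P  = list(mass = 30.97376199842, abundance = 1.0),
  F  = list(mass = 18.99840316273, abundance = 1.0),
  Cl = list(mass = c(34.968852682, 36.965902602),
            abundance = c(0.7576, 0.2424)),
  Br = list(mass = c(78.9183376, 80.9162897),
            abundance = c(0.5069, 0.4931)),
  I  = list(mass = 126.9044719, abundance = 1.0),
  Si = list(mass = c(27.97692653465, 28.97649466490, 29.973770136),
            abundance = c(0.92223, 0.04685, 0.03092))
)

.MONO_MASS <- vapply(.ISOTOPES, function(x) x$mass[1], numeric(1))

#' Electron rest mass in daltons
#'
#' Used to convert between neutral-formula monoisotopic masses and the m/z of
#' the corresponding radical cations observed in EI spectra.
#' @export
ELECTRON_MASS <- 0.000548579909

#' Default element alphabet
#'
#' Elements admitted by [parse_formula()] and the formula-decomposition
#' routines unless an alternative alphabet is supplied. The default covers the
#' analyte classes typical of environmental GC-HRMS work (PAHs, halogenated
#' flame retardants, PCBs, organophosphate esters, PFAS, siloxanes).
#' @export
DEFAULT_ELEMENTS <- c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I", "Si")

# Canonical Hill order: C, H, then remaining elements alphabetically.
hill_order <- function(elements) {
  rest <- sort(setdiff(elements, c("C", "H")))
  intersect(c("C", "H", rest), elements)
}

#' Construct a molecular formula from element counts
#'
#' @param counts named integer vector (element symbol -> count). Zero counts
#'   are dropped; at least one positive count is required.
#' @return an object of class `chem_formula`: a named integer vector in Hill
#'   order (C first, then H, then alphabetical).
#' @export
chem_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0L) {
    stop("empty formula: at least one element count must be positive", call. = FALSE)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("formula counts must be named by element symbol", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  bad <- setdiff(names(counts), names(.ISOTOPES))
  if (length(bad) > 0L) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- counts[hill_order(names(counts))]
  structure(as.integer(round(counts)), names = names(counts), class = "chem_formula")
}

#' Parse a Hill-notation formula string
#'
#' @param text formula string such as `"C6H5Cl"`; multipliers default to 1.
#' @param alphabet allowed element symbols.
#' @return a [chem_formula()] object.
#' @examples
#' parse_formula("C6H6")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text, alphabet = DEFAULT_ELEMENTS) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("empty formula string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula string: ", sQuote(text), call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(nzchar(nums), as.integer(nums), 1L)
  bad <- setdiff(syms, alphabet)
  if (length(bad) > 0L) {
    stop("unknown element ", sQuote(bad[1]), " in formula ", sQuote(text), call. = FALSE)
  }
  total <- tapply(counts, syms, sum)
  chem_formula(structure(as.integer(total), names = names(total)))
}

#' @export
format.chem_formula <- function(x, ...) {
  paste0(names(x), ifelse(x == 1L, "", x), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format(x), "  (", sprintf("%.6f", monoisotopic_mass(x)), " Da)\n", sep = "")
  invisible(x)
}

#' @export
as.character.chem_formula <- function(x, ...) format(x)

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the exact mass of the lightest isotope
#' (IUPAC 2021 values, embedded).
#'
#' @param f a [chem_formula()] object or formula string.
#' @return mass in Da.
#' @examples
#' monoisotopic_mass("H2O")  # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0L) stop("empty formula", call. = FALSE)
  sum(.MONO_MASS[names(f)] * as.numeric(f))
}

#' Enumerate subformulas of a parent formula within a mass window
#'
#' Depth-first enumeration over the Hill-ordered elements with mass-bound
#' pruning. Yields every non-empty count vector that is component-wise at most
#' the parent and whose monoisotopic mass lies in `[min_mass, max_mass]`, in
#' lexicographic order over the Hill-sorted elements.
#'
#' @param parent parent [chem_formula()] (or string).
#' @param min_mass,max_mass inclusive monoisotopic-mass window in Da.
#' @return data frame with one column per parent element (counts) plus a
#'   `mass` column, one row per subformula.
#' @export
enumerate_subformulas <- function(parent, min_mass = 0, max_mass = Inf) {
  if (is.character(parent)) parent <- parse_formula(parent)
  stopifnot(min_mass >= 0, min_mass <= max_mass)
  elems <- names(parent)
  k <- length(elems)
  masses <- .MONO_MASS[elems]
  # max mass attainable from elements i..k
  suffix_max <- rev(cumsum(rev(as.numeric(parent) * masses)))
  suffix_max <- c(suffix_max, 0)

  acc <- vector("list", 256L)
  n_acc <- 0L
  counts <- integer(k)
  push <- function(row) {
    n_acc <<- n_acc + 1L
    acc[[n_acc]] <<- row
  }
  recurse <- function(i, mass_so_far) {
    if (i > k) {
      if (mass_so_far >= min_mass && any(counts > 0L)) {
        push(c(counts, mass_so_far))
      }
      return(invisible())
    }
    for (ci in 0:parent[[i]]) {
      m <- mass_so_far + ci * masses[[i]]
      if (m > max_mass) break
      if (m + suffix_max[i + 1L] < min_mass) {
        counts[i] <<- ci
        next
      }
      counts[i] <<- ci
      recurse(i + 1L, m)
    }
    counts[i] <<- 0L
    invisible()
  }
  recurse(1L, 0)
  if (n_acc == 0L) {
    out <- as.data.frame(matrix(numeric(0), ncol = k + 1L))
  } else {
    out <- as.data.frame(do.call(rbind, acc[seq_len(n_acc)]))
  }
  names(out) <- c(elems, "mass")
  out
}

#' Convert a subformula-table row to a formula object
#' @param row one row of the data frame returned by [enumerate_subformulas()].
#' @export
row_to_formula <- function(row) {
  elems <- setdiff(names(row), "mass")
  chem_formula(structure(as.integer(row[elems]), names = elems))
}

#' Decompose an accurate mass into candidate formulas
#'
#' All and only formulas within the element bounds whose monoisotopic mass lies
#' within `tol_ppm` of `target`, sorted by absolute mass error.
#'
#' @param target neutral monoisotopic mass in Da.
#' @param tol_ppm mass tolerance in ppm.
#' @param bounds upper element bounds as a [chem_formula()] (or string).
#' @return list of `chem_formula` objects with attribute `error_ppm`.
#' @export
decompose_mass <- function(target, tol_ppm, bounds) {
  stopifnot(target > 0, tol_ppm > 0)
  if (is.character(bounds)) bounds <- parse_formula(bounds)
  win <- target * tol_ppm * 1e-6
  tab <- enumerate_subformulas(bounds, target - win, target + win)
  if (nrow(tab) == 0L) return(list())
  err <- abs(tab$mass - target)
  tab <- tab[order(err), , drop = FALSE]
  out <- lapply(seq_len(nrow(tab)), function(i) row_to_formula(tab[i, ]))
  attr(out, "error_ppm") <- sort(err) / target * 1e6
  out
}

# Merge isotope peaks closer than merge_tol Da (abundance-weighted mean mass).
merge_peaks <- function(mass, abundance, merge_tol) {
  o <- order(mass)
  mass <- mass[o]; abundance <- abundance[o]
  grp <- cumsum(c(1, diff(mass) > merge_tol))
  ab <- as.numeric(tapply(abundance, grp, sum))
  mz <- as.numeric(tapply(mass * abundance, grp, sum)) / ab
  list(mass = mz, abundance = ab)
}

#' Simulate the isotope pattern of a formula
#'
#' Iterative convolution of per-element isotope distributions. Peaks are
#' aggregated within `merge_tol` Da; after aggregation, peaks below
#' `abundance_cutoff` (relative to the base peak) are pruned.
#'
#' @param f formula (object or string).
#' @param abundance_cutoff prune threshold relative to the base peak, in
#'   `[0, 1)`.
#' @param merge_tol mass-merge window in Da.
#' @param normalize `"sum"` keeps probability scale (pre-pruning abundances sum
#'   to 1); `"base"` rescales so the base peak is 1.
#' @return data frame of class `isotope_pattern` with columns `mass`,
#'   `abundance`, masses strictly increasing.
#' @export
isotope_pattern <- function(f, abundance_cutoff = 0, merge_tol = 1e-8,
                            normalize = c("sum", "base")) {
  normalize <- match.arg(normalize)
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0L) stop("empty formula", call. = FALSE)
  stopifnot(abundance_cutoff >= 0, abundance_cutoff < 1)
  pat <- list(mass = 0, abundance = 1)
  for (el in names(f)) {
    iso <- .ISOTOPES[[el]]
    for (i in seq_len(f[[el]])) {
      mass <- as.vector(outer(pat$mass, iso$mass, `+`))
      ab <- as.vector(outer(pat$abundance, iso$abundance, `*`))
      pat <- merge_peaks(mass, ab, merge_tol)
      # drop numerically negligible states to bound growth (far below any
      # reportable cutoff; total abundance stays 1 within 1e-9)
      keep <- pat$abundance > 1e-12
      if (!all(keep)) pat <- list(mass = pat$mass[keep], abundance = pat$abundance[keep])
    }
  }
  total <- sum(pat$abundance)
  keep <- pat$abundance >= abundance_cutoff * max(pat$abundance)
  mass <- pat$mass[keep]; ab <- pat$abundance[keep]
  if (normalize == "base") ab <- ab / max(ab)
  structure(data.frame(mass = mass, abundance = ab),
            total_abundance = total, class = c("isotope_pattern", "data.frame"))
}

#' Kendrick mass and Kendrick mass defect
#'
#' Rescales an observed mass so that members of a homologous series sharing the
#' given repeat unit (for example CH2 or CF2) have a common mass defect.
#'
#' @param mass observed (neutral) mass in Da.
#' @param repeat_unit repeat-unit formula (object or string), default CH2.
#' @param convention `"round"` (nominal mass by round-to-nearest, the common
#'   choice) or `"floor"`.
#' @return list of class `kendrick_point` with `observed_mass`,
#'   `kendrick_mass`, `kendrick_mass_defect`, `repeat_unit`.
#' @export
kendrick_mass_defect <- function(mass, repeat_unit = "CH2",
                                 convention = c("round", "floor")) {
  convention <- match.arg(convention)
  stopifnot(mass > 0)
  if (is.character(repeat_unit)) repeat_unit <- parse_formula(repeat_unit)
  exact <- monoisotopic_mass(repeat_unit)
  nominal <- round(exact)
  km <- mass * nominal / exact
  nom_fun <- if (convention == "round") round else floor
  kmd <- nom_fun(km) - km
  structure(list(observed_mass = mass, kendrick_mass = km,
                 kendrick_mass_defect = kmd, repeat_unit = repeat_unit),
            class = "kendrick_point")
}
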