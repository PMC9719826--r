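---
title: "Methods: five-level confidence scoring for GC-HRMS annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: five-level confidence scoring for GC-HRMS annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcannotate)
```

## The scoring model and its assumptions

`gcannotate` assigns each deconvoluted GC-HRMS feature one of five confidence
levels by combining independent evidence layers: blank filtering, spectral
similarity, retention index (RI), accurate-mass fragment evidence, and the
molecular ion. The package assumes its input is *post-deconvolution*: each
feature already carries a consolidated spectrum, a retention time, and
per-sample/per-blank abundances. Deconvolution quality is therefore an
upstream assumption, not something the scores can repair — a poorly
deconvoluted spectrum will depress both forward similarity and RHRMF, which
is the intended failure direction (toward lower confidence).

The schema is *qualitative by design*: each criterion is a filter with a
fixed threshold, and candidate ranking within a level is a separate,
quantitative step. This separation keeps level assignments comparable across
laboratories even when ranking heuristics differ.

## Evidence layers and their tunable parameters

**Blank feature filtering** (`bff_config()`). A feature is retained iff its
sample statistic (mean by default) is *strictly greater* than
`c × (blank mean + 3 × blank sd)`. `c` defaults to 3, the midpoint of common
practice (2–10). The percentile statistic is available for skewed designs;
its default probe (0.5, the median) is a package choice, not a community
standard, so runs using it should report the percentile. Missing blank cells
are read as 0 with a warning — conservative toward *retaining* features.
Fewer than four blanks triggers a warning rather than an error, because
pilot data with two blanks is still worth screening, but the blank SD is then
poorly estimated.

**Spectral similarity** (`match_weighting()`, `dot_product_score()`,
`reverse_dot_product_score()`). Similarity is the cosine of weighted
intensity vectors `w = mz^a · I^b`, scaled to 0–1000. Defaults `a = 0`,
`b = 0.5` (square-root intensity) are the common library-search convention on
which the 600/500 thresholds are calibrated; plain cosine rather than a
squared (match-factor-style) cosine is used, and both exponents are
configurable for users who want NIST-style weighting (`a = 3`, `b = 0.6` is
a popular alternative). Unit-resolution matching bins m/z by rounding
(`bin_width = 1` Th); accurate matching uses a ppm tolerance. Peak pairing is
greedy nearest-m/z with each peak used at most once; ties are broken toward
the higher combined intensity, then lower m/z, which makes the pairing — and
hence the forward score — exactly symmetric in its two arguments. When *no*
peaks pair, the reverse score is 0 (zero overlap), consistent with the
forward score; an error is reserved for genuinely all-zero weighted spectra.

**Retention index** (`compute_retention_index()`, `ri_match()`). Kovats RI by
van den Dool & Kratz linear interpolation between bracketing alkanes,
generalized to non-consecutive carbon numbers. Extrapolation beyond the
alkane span is off by default — temperature-programmed runs are only
piecewise-linear near the calibrated range — and, when enabled, flags the
value. The match rule is strict: experimental library RI requires |ΔRI| < 50
*and* < 1.5 % of the library value; predicted RI requires |ΔRI| < 100.

**Accurate-mass fragment evidence** (`hrmf()`, `rhrmf()`). HRMF is the
percentage of spectrum peaks explicable, within `tol_ppm` (default 10), as
cations of subformulas of the candidate's molecular formula (subformula
monoisotopic mass minus the electron mass). The `h_transfer` parameter
(default 1) admits hydrogen rearrangements; because transfers are constrained
to stay within the parent's element bounds, every adjusted formula is itself
a subformula, so the explicable mass set is the full subformula set for any
`h_transfer` — the parameter is retained in the interface for symmetry and
forward compatibility with looser bounds. RHRMF restricts scoring to query
peaks matched to the library record, so deconvolution artifacts cannot
depress it; when no peaks match, RHRMF is *unavailable* (`NA`), not 0 — an
absent criterion must not masquerade as strong negative evidence.

**Molecular ion** (`detect_molecular_ion()`). A peak within `tol_ppm` of the
candidate's radical-cation m/z. Requiring it for Level 2
(`require_molecular_ion`) is off by default: EI spectra of many compound
classes lack the molecular ion, and requiring it sharply raises false
negatives; it is recommended only for stable classes such as PAHs, hence the
switch.

## Level assignment, ranking, and duplicates

All spectral/RHRMF/RI comparisons are strict inequalities, so a score exactly
at a threshold fails — boundary behaviour is part of the contract and is
tested. Level evaluation is 1 (only when standards are supplied) → 2 → 3 →
4A/4B/4C → 5. The 4A–4C flags are not ordered by confidence relative to each
other and never suppress a 2/3 assignment. Level-2 evidence strictly nests
Level-3's spectral path (Level 2 = Level 3 main path + RI pass), and lowering
any threshold can only grow the set of features at or above a level; both
properties are enforced as tests.

Two readings of the schema were genuinely open and are resolved as follows.
First, the chemical-ionization path (≥ 5 matched fragments) is implemented as
a substitute for the EI dot-product pair only; the accurate-mass condition is
still required for Level 2 on both paths (a config relaxation exists).
Second, the Level-1 reference-peak ratio criterion does not define its ratio
base; ratios are computed relative to the most intense reference peak, and
the 20 % tolerance is applied to each peak's observed/expected ratio.

Ranking within a level orders candidates by reverse score (ties: higher
evidence count, then name, for byte-stable output). The top candidate is
*preferred* only under a dominance margin over the runner-up — evidence count
≥ 10×, |ΔRI| smaller by ≥ 30, reverse score larger by ≥ 50, or RHRMF larger
by ≥ 10 — otherwise the feature is flagged multi-hit. A pluggable weighted
total score was considered and deliberately not made the default: reverse
score plus explicit dominance margins is transparent and reproduces the
intended reporting semantics without hiding weights. Duplicate annotations
are collapsed on identifier (or, failing that, case/whitespace-normalized
name), keeping the best level and then the best reverse score; identical
names under distinct identifiers are also collapsed and flagged for manual
review.

## Validation metrics

False-positive rates at a level are computed over features *assigned* that
level (top candidate wrong ⇒ FP); false-negative rates over detected truth
compounds whose feature did not reach the level. A feature annotated at the
level with the wrong compound is an FP, not an FN. The equivalence mode
treats a top candidate inside the truth compound's equivalence group (close
isomers, supplied externally — isomer equivalence cannot be derived from
names) as correct; it can only lower FP rates, never raise them.

Per-filter candidate-retention summaries use equal-weight per-compound
percentages (mean ± sample SD); a pooled-count aggregation is available
because published summaries of this kind are not always consistent about the
aggregation, and the package reports raw values alongside rounded ones
(display rounding is half-up to integer percent).

## The synthetic-data generator

`generate_library()` draws random CHNOCl formulas (C6–C20), builds EI-like
accurate-mass spectra whose fragments are *true subformula cation masses* —
guaranteeing RHRMF = 100 and dot product = 1000 on self-match — adds a
molecular ion with probability 0.9, and assigns RIs from a monotone
mass-to-RI map (RI = 500 + 4·mass + noise, SD 5) that lands inside a C8–C40
alkane calibration. `generate_run()` places true spikes at retention times
that reproduce their library RI (jitter SD 0.005 min), applies 1 %
multiplicative intensity noise, and gives them high sample abundances with
zero blank signal. Decoys are perturbed copies of *other* library entries
(20 % peak dropout, small m/z jitter) offset by 150–400 RI units so they can
satisfy spectral criteria but never the RI criterion — mimicking the
structurally-similar-isomer failure mode that dominates real false positives.
Contamination features carry comparable abundance in blanks and samples
(samples at 0.8–1.2× the blank level), placing them safely below the default
threshold `3 × (mean + 3 × sd)`.

What the generator does *not* emulate: physically realistic EI fragmentation
and rearrangement chemistry, chromatographic peak shapes and co-elution,
matrix effects, library spectra measured on different instruments, and
isomers with genuinely identical spectra *and* retention indices. Passing the
end-to-end recovery test therefore demonstrates that the pipeline's logic is
correct under its own assumptions — perfect Level-2 recovery at 1 % noise —
not that real-data false-positive rates will be low; on real data those are
dominated by close isomers, which the decoy design only approximates.

Default study conditions for the end-to-end checks: 120-compound library, 50
spikes, 50 decoys, 20 contamination features, 3 samples, 4 blanks. These
sizes exercise every code path (including multi-candidate ranking) while
keeping a full annotate-and-evaluate cycle around half a minute on one core;
they are also the sizes used by the acceptance script.

## Numerical choices and degenerate inputs

* Monoisotopic masses use embedded IUPAC 2021 values; the electron mass is
  subtracted for all cation m/z comparisons.
* Isotope patterns are built by iterative convolution with peak merging
  within 1e-8 Da and a 1e-12 floor on retained states; pre-pruning abundance
  is conserved to 1 ± 1e-9, which is asserted.
* Kendrick mass defect uses round-to-nearest nominal mass by default; the
  floor convention (also common in the literature) is selectable.
* Subformula enumeration is depth-first with suffix-mass pruning in a fixed
  lexicographic (Hill) order, so outputs are deterministic and equal to
  exhaustive enumeration (tested against an `expand.grid` oracle).
* Formula decomposition for Level 4A applies two survivor filters: the
  simulated isotope pattern must match observed isotopologue peaks within a
  30 % relative-abundance tolerance (peaks below 5 % of base are not
  required), and all dominant fragments (≥ 10 % of base peak below the
  precursor) must be explicable as subformulas. "Unequivocal" means exactly
  one survivor; element bounds and tolerance are user-visible parameters and
  are echoed in output.
* Homologous-series detection requires matching KMD within 0.002 Da, integer
  repeat spacing, at least 3 members at distinct repeat counts, and an
  RI-versus-repeat-count fit with R² ≥ 0.99 (computed directly from residuals
  so that perfect fits are handled exactly).
* Empty assignment lists serialize to header-only CSVs; empty libraries put
  every feature at Level 5 with a warning; identical inputs and configuration
  produce byte-identical result files.

## Known limitations

Ring/double-bond-equivalent (SENIOR) plausibility filtering of formulas is
not applied — decomposition within element bounds can propose
valence-impossible formulas at loose tolerances. In-silico EI spectrum
prediction is accepted only as ordinary library input. Orbitrap gas-phase
reaction artifacts can produce fragments that no subformula explains,
depressing RHRMF for genuine hits; the threshold (75) leaves headroom but the
effect is instrument-dependent. Level-1 batch verification policy (which
samples, how many ions) is the user's responsibility; the package verifies
single feature-standard pairs.
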