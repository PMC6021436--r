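# Reporter-assay quantification formulas and the geometry arithmetic used
# to reason about activator reach from CRISPR target sites.

#' Miller units from a beta-galactosidase (LacZ) assay
#'
#' Miller Units = (1000 * A420) / (OD600 * volume * time). The culture
#' volume defaults to the standard 0.02 mL aliquot; it is a parameter so
#' the formula stays reusable for other protocols.
#'
#' @param a420 Absorbance at 420 nm after the stopped reaction.
#' @param od600 Culture density (absorbance at 600 nm).
#' @param culture_volume Assayed culture volume in mL (default 0.02).
#' @param time Reaction time in minutes.
#' @return Miller units (vectorized).
#' @examples
#' miller_units(a420 = 0.4, od600 = 0.5, time = 20)  # 2000
#' @export
miller_units <- function(a420, od600, culture_volume = 0.02, time) {
  if (any(od600 <= 0)) stop("od600 must be positive", call. = FALSE)
  if (any(time <= 0)) stop("time must be positive", call. = FALSE)
  if (any(culture_volume <= 0))
    stop("culture_volume must be positive", call. = FALSE)
  if (any(a420 < 0)) stop("a420 must be non-negative", call. = FALSE)
  1000 * a420 / (od600 * culture_volume * time)
}

#' Relative expression fold change by the delta-delta-Ct method
#'
#' Per condition, dCt = Ct(target) - Ct(reference); ddCt = dCt(test) -
#' dCt(control); fold change = efficiency^(-ddCt). The reference gene is
#' fixed per experiment (16S rRNA in the standard bacterial protocol). The
#' amplification efficiency defaults to 2 (perfect doubling per cycle),
#' matching the classic single-efficiency method.
#'
#' @param ct_target_test,ct_ref_test Ct of target and reference gene in the
#'   test condition.
#' @param ct_target_control,ct_ref_control Same in the control condition.
#' @param efficiency Per-cycle amplification factor (default 2).
#' @return Fold change of the target, test relative to control (vectorized).
#' @examples
#' ddct_fold_change(20, 15, 21, 15)  # ddCt = -1 -> fold 2
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_control, ct_ref_control,
                             efficiency = 2) {
  cts <- c(ct_target_test, ct_ref_test, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite", call. = FALSE)
  if (any(efficiency <= 1))
    stop("efficiency must exceed 1", call. = FALSE)
  dct_test <- ct_target_test - ct_ref_test
  dct_control <- ct_target_control - ct_ref_control
  efficiency^(-(dct_test - dct_control))
}

#' OD-normalized fluorescence
#'
#' Plate-reader fluorescence divided by cell density (fluorescence/OD600).
#'
#' @param fluor Raw fluorescence reading.
#' @param od600 Culture density; must be positive.
#' @return Normalized fluorescence (vectorized).
#' @export
od_normalized_fluorescence <- function(fluor, od600) {
  if (any(od600 <= 0)) stop("od600 must be positive", call. = FALSE)
  fluor / od600
}

#' Ethanol yield relative to initial glucose
#'
#' Yield in g ethanol per g glucose, relative to the initial glucose in the
#' fermentation medium (default 2% = 20 g/L).
#'
#' @param titer_g_per_L Measured ethanol titer in g/L.
#' @param initial_glucose_g_per_L Initial glucose in g/L (default 20).
#' @return Yield, g ethanol / g glucose (vectorized).
#' @export
ethanol_yield <- function(titer_g_per_L, initial_glucose_g_per_L = 20) {
  if (any(initial_glucose_g_per_L <= 0))
    stop("initial glucose must be positive", call. = FALSE)
  if (any(titer_g_per_L < 0))
    stop("titer must be non-negative", call. = FALSE)
  titer_g_per_L / initial_glucose_g_per_L
}

#' Geometry parameters for linker/DNA reach arithmetic
#'
#' Contour-length approximations: 3.8 Angstrom per amino acid residue for a
#' flexible peptide linker (worm-like chain contour), 3.3 Angstrom rise per
#' base pair for B-form DNA.
#'
#' @param aa_contour Angstrom per residue (default 3.8).
#' @param bp_rise Angstrom per base pair (default 3.3).
#' @return A list with class `geometry_params`.
#' @export
geometry_params <- function(aa_contour = 3.8, bp_rise = 3.3) {
  if (aa_contour <= 0 || bp_rise <= 0)
    stop("geometry parameters must be positive", call. = FALSE)
  structure(list(aa_contour = aa_contour, bp_rise = bp_rise),
            class = "geometry_params")
}

#' Added contour length when extending a peptide linker
#'
#' Extending a linker from `aa_from` to `aa_to` residues adds
#' `(aa_to - aa_from) * aa_contour` Angstroms of contour length; e.g.
#' extending a 5-residue linker to 20 residues adds 57 Angstroms at 3.8
#' Angstrom/residue.
#'
#' @param aa_from,aa_to Linker lengths in residues, `0 <= aa_from <= aa_to`.
#' @param geometry A [geometry_params()].
#' @return Length in Angstroms.
#' @export
linker_extension_length <- function(aa_from, aa_to,
                                    geometry = geometry_params()) {
  if (any(aa_from < 0) || any(aa_to < aa_from))
    stop("need 0 <= aa_from <= aa_to", call. = FALSE)
  (aa_to - aa_from) * geometry$aa_contour
}

#' Physical span of a stretch of B-DNA
#'
#' `n_bp * bp_rise` Angstroms: 10 bp spacing between adjacent tiling-array
#' target sites corresponds to ~33 Angstroms.
#'
#' @param n_bp Number of base pairs (non-negative).
#' @param geometry A [geometry_params()].
#' @return Length in Angstroms.
#' @export
bp_span_length <- function(n_bp, geometry = geometry_params()) {
  if (any(n_bp < 0)) stop("n_bp must be non-negative", call. = FALSE)
  n_bp * geometry$bp_rise
}

#' Reach of a physical length expressed in base pairs
#'
#' `floor(length / bp_rise)`: partial base pairs are meaningless, so the
#' result is rounded down. A 57-Angstrom linker extension reaches 17 bp of
#' B-DNA.
#'
#' @param length_A Length in Angstroms (non-negative).
#' @param geometry A [geometry_params()].
#' @return Integer number of base pairs.
#' @export
reach_in_bp <- function(length_A, geometry = geometry_params()) {
  if (any(length_A < 0)) stop("length must be non-negative", call. = FALSE)
  # small tolerance so an exact multiple of bp_rise is not floored down by
  # floating-point representation (e.g. 3 * 3.3 / 3.3)
  as.integer(floor(length_A / geometry$bp_rise + 1e-9))
}

#' Summarize replicate measurements
#'
#' Central value plus standard deviation. Flow-cytometry fluorescence data
#' are conventionally summarized as median +/- s.d. and plate-reader data
#' as mean +/- s.d.; the assay type picks the default, or pass `method`
#' explicitly.
#'
#' @param x Numeric replicate values.
#' @param assay `"cytometry"` (median) or `"plate_reader"` (mean).
#' @param method Override: `"mean"` or `"median"`.
#' @return A list with `center`, `sd`, `n`, `method`.
#' @export
summarize_replicates <- function(x, assay = c("plate_reader", "cytometry"),
                                 method = NULL) {
  assay <- match.arg(assay)
  if (is.null(method))
    method <- if (assay == "cytometry") "median" else "mean"
  method <- match.arg(method, c("mean", "median"))
  center <- if (method == "median") stats::median(x) else mean(x)
  list(center = center, sd = stats::sd(x), n = length(x), method = method)
}
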