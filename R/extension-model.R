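#' Length gain on unfolding an alpha helix
#'
#' A residue advances 1.5 Angstrom along the axis in a helix and
#' 3.6 Angstrom in the extended conformation, so unfolding an n-residue
#' helix gains `n * (rise_extended - rise_helix)` Angstrom: about 40
#' Angstrom for a 20-residue helix.
#'
#' @param residue_count Number of residues (non-negative, vectorised).
#' @param constants An [axial_constants()] object.
#' @return Length gain in Angstrom.
#' @examples
#' helix_unfolding_gain(20)   # 42 A, i.e. "about 40 A"
#' @export
helix_unfolding_gain <- function(residue_count, constants = axial_constants()) {
  stopifnot(inherits(constants, "axial_constants"))
  if (any(residue_count < 0)) stop("`residue_count` must be non-negative")
  residue_count * (constants$rise_extended - constants$rise_helix)
}

#' Fully extended filament length and extension ratio
#'
#' Extension arithmetic of the straightened filament: helical linkers are
#' taken as unfolded chains at the C-alpha spacing (3.8 Angstrom per
#' residue, *not* the AFM contour calibration constant), while Ig domains
#' stay folded but are straightened into one common orientation, each
#' contributing its folded axial extent. The architecture's element list
#' already reflects its symmetry (a dimer lists both protomers), so sums
#' run over all elements.
#'
#' @param arch A [filament_architecture()].
#' @param resting_length Resting (zero-force) length of the filament in
#'   Angstrom; default 340 Angstrom, the length of the folded tail-to-tail
#'   dimer model.
#' @param constants An [axial_constants()] object.
#' @return A one-row tibble of class `extension_report` with columns
#'   `resting_length`, `extended_domains`, `extended_linkers`,
#'   `extended_total` (all Angstrom), `ratio`, and `ratio_reported`
#'   (rounded to one decimal).
#' @examples
#' extended_filament_length(straightened_reference_architecture())
#' @export
extended_filament_length <- function(arch,
                                     resting_length = 340,
                                     constants = axial_constants()) {
  stopifnot(inherits(arch, "filament_architecture"))
  if (!is.numeric(resting_length) || resting_length <= 0) {
    stop("`resting_length` must be positive (Angstrom)")
  }
  # folded_extent is stored in nm; report in Angstrom
  extended_domains <- 10 * sum(arch$folded_extent[arch$kind == "ig_domain"])
  extended_linkers <- constants$ca_spacing_unfolded *
    sum(arch$residues[arch$kind == "helix_linker"])
  extended_total <- extended_domains + extended_linkers
  report <- tibble::tibble(
    resting_length = resting_length,
    extended_domains = extended_domains,
    extended_linkers = extended_linkers,
    extended_total = extended_total,
    ratio = extended_total / resting_length,
    ratio_reported = extension_ratio(extended_total, resting_length)
  )
  class(report) <- c("extension_report", class(report))
  stopifnot(isTRUE(all.equal(report$extended_total,
                             report$extended_domains + report$extended_linkers)),
            isTRUE(all.equal(report$ratio, report$extended_total / report$resting_length)))
  report
}

#' Extension ratio of a filament
#'
#' @param extended_total Fully extended length, Angstrom.
#' @param resting_length Resting length, Angstrom.
#' @return The quotient rounded to one decimal (the raw value is the
#'   plain division; see [extended_filament_length()] for both).
#' @examples
#' extension_ratio(860, 340)  # 2.5
#' @export
extension_ratio <- function(extended_total, resting_length) {
  if (any(resting_length <= 0)) stop("`resting_length` must be positive")
  round(extended_total / resting_length, 1)
}

#' Expected contour-length gain from unfolding an Ig domain
#'
#' The standard AFM estimate: the contour length of the unfolded chain
#' (residues times the per-residue contour calibration, 0.365 nm/aa)
#' minus the end-to-end distance already contributed by the folded
#' domain.
#'
#' @param residue_count Number of residues (non-negative).
#' @param folded_end_to_end End-to-end distance of the folded domain, nm.
#' @param constants An [axial_constants()] object.
#' @return Expected contour-length increase Delta-L in nm.
#' @examples
#' expected_ig_contour_gain(89, 4.0)    # 28.485 nm
#' expected_ig_contour_gain(92, 3.88)   # 29.7 nm, the canonical Ig default
#' @export
expected_ig_contour_gain <- function(residue_count, folded_end_to_end,
                                     constants = axial_constants()) {
  stopifnot(inherits(constants, "axial_constants"))
  if (any(residue_count < 0)) stop("`residue_count` must be non-negative")
  if (any(folded_end_to_end < 0)) stop("`folded_end_to_end` must be non-negative")
  gain <- residue_count * constants$contour_per_aa - folded_end_to_end
  if (any(gain < 0)) {
    stop("negative expected contour gain: folded end-to-end exceeds the unfolded contour length (unphysical input combination)")
  }
  gain
}
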