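#' Axial and polymer constants for Ig-helix filament arithmetic
#'
#' Bundles the per-residue axial rises and worm-like-chain calibration
#' constants used throughout the package. Two distinct unfolded-residue
#' spacings coexist on purpose and are never interchanged:
#' `ca_spacing_unfolded` (3.8 Angstrom per residue, the C-alpha--C-alpha
#' spacing used by the straightened-filament length model) and
#' `contour_per_aa` (0.365 nm per residue, the AFM contour-length
#' calibration used when converting residue counts to worm-like-chain
#' contour length). Each function documents which one it uses.
#'
#' @param rise_helix Axial rise per residue in an alpha helix, Angstrom.
#' @param rise_extended Axial rise per residue in the extended (fully
#'   stretched) conformation, Angstrom.
#' @param ca_spacing_unfolded C-alpha spacing of an unfolded chain,
#'   Angstrom per residue.
#' @param contour_per_aa Contour length per residue used in AFM
#'   worm-like-chain calibration, nm per residue.
#' @param persistence_length Persistence length of unfolded polypeptide, nm.
#'
#' @return A list of class `axial_constants`.
#' @examples
#' axial_constants()
#' @export
axial_constants <- function(rise_helix = 1.5,
                            rise_extended = 3.6,
                            ca_spacing_unfolded = 3.8,
                            contour_per_aa = 0.365,
                            persistence_length = 0.5) {
  const <- list(
    rise_helix = rise_helix,
    rise_extended = rise_extended,
    ca_spacing_unfolded = ca_spacing_unfolded,
    contour_per_aa = contour_per_aa,
    persistence_length = persistence_length
  )
  bad <- names(const)[!vapply(const, function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("axial constants must be single positive finite numbers: ", paste(bad, collapse = ", "))
  }
  if (rise_extended <= rise_helix) {
    stop("`rise_extended` must exceed `rise_helix`")
  }
  structure(const, class = "axial_constants")
}

#' Thermal energy kT in pN nm
#'
#' @param temperature Temperature in Kelvin. Default 298 K (room
#'   temperature), giving kT = 4.114 pN nm.
#' @return Thermal energy in pN nm.
#' @examples
#' thermal_energy()       # 4.114 pN nm
#' thermal_energy(310)
#' @export
thermal_energy <- function(temperature = 298) {
  if (!is.numeric(temperature) || any(temperature <= 0)) {
    stop("`temperature` must be positive (Kelvin)")
  }
  # Boltzmann constant 1.380649e-23 J/K = 1.380649e-2 pN nm / K
  1.380649e-2 * temperature
}
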