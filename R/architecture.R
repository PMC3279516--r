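#' Describe one mechanical element of a modular filament
#'
#' An element is either a folded immunoglobulin-like domain
#' (`kind = "ig_domain"`: stochastic, irreversible unfolding on the
#' experimental timescale, Bell-Evans kinetics) or an alpha-helical linker
#' (`kind = "helix_linker"`: reversible two-state unfolding close to
#' equilibrium, characterised by a midpoint force).
#'
#' `contour_gain` is the net increase in effective contour length when the
#' element unfolds (the Delta-L that worm-like-chain fitting of a
#' force-extension trace recovers); it is a direct parameter rather than a
#' quantity derived from residue counts, but [expected_ig_contour_gain()]
#' provides the standard consistency formula.
#'
#' @param kind `"ig_domain"` or `"helix_linker"`.
#' @param label Element label.
#' @param residues Residue count (integer, >= 1).
#' @param folded_extent Axial extent of the folded element, nm.
#' @param contour_gain Net contour-length gain on unfolding, nm.
#' @param midpoint_force Two-state midpoint force for helices, pN
#'   (ignored for Ig domains).
#' @param k0 Zero-force unfolding rate for Ig domains, 1/s.
#' @param delta_x Bell-Evans distance to the transition state, nm.
#' @param foldable Can this element unfold at all? The central
#'   dimerisation module of a tail-to-tail dimer is typically kept rigid.
#' @return A one-row tibble.
#' @examples
#' filament_element("ig_domain", "My9", residues = 92)
#' @export
filament_element <- function(kind = c("ig_domain", "helix_linker"),
                             label,
                             residues,
                             folded_extent = if (kind == "ig_domain") 3.88 else residues * 0.15,
                             contour_gain = if (kind == "ig_domain") 29.7 else 6.0,
                             midpoint_force = 30,
                             k0 = 1e-4,
                             delta_x = 0.3,
                             foldable = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(residues) || length(residues) != 1 || residues < 1 || residues != round(residues)) {
    stop("`residues` must be a positive integer")
  }
  if (folded_extent < 0) stop("`folded_extent` must be >= 0")
  if (foldable && contour_gain <= 0) stop("`contour_gain` must be positive for foldable elements")
  if (kind == "helix_linker" && midpoint_force <= 0) stop("`midpoint_force` must be positive")
  if (kind == "ig_domain" && foldable && (k0 <= 0 || delta_x <= 0)) {
    stop("`k0` and `delta_x` must be positive for foldable Ig domains")
  }
  tibble::tibble(
    label = as.character(label),
    kind = kind,
    residues = as.integer(residues),
    folded_extent = folded_extent,
    contour_gain = contour_gain,
    midpoint_force = if (kind == "helix_linker") midpoint_force else NA_real_,
    k0 = if (kind == "ig_domain" && foldable) k0 else NA_real_,
    delta_x = if (kind == "ig_domain" && foldable) delta_x else NA_real_,
    foldable = foldable
  )
}

#' Assemble a filament architecture from mechanical elements
#'
#' @param elements A tibble of elements (rows from [filament_element()]),
#'   ordered N to C along one protomer (or along the whole chain for a
#'   monomer).
#' @param symmetry `"monomer"` keeps the list as is; `"dimer"` appends the
#'   reversed element list to produce a tail-to-tail dimer, so the
#'   C-terminal dimerisation module appears twice (e.g. the (My13)2 pair
#'   counts as two domains even though it acts as one rigid body).
#' @return A tibble of class `filament_architecture` with the full ordered
#'   element list and a `symmetry` attribute.
#' @examples
#' arm <- dplyr::bind_rows(
#'   filament_element("ig_domain", "D1", 92),
#'   filament_element("helix_linker", "h1", 20)
#' )
#' filament_architecture(arm)
#' @export
filament_architecture <- function(elements, symmetry = c("monomer", "dimer")) {
  symmetry <- match.arg(symmetry)
  if (!is.data.frame(elements) || nrow(elements) == 0) {
    stop("`elements` must be a non-empty data frame of filament elements")
  }
  req <- c("label", "kind", "residues", "folded_extent", "contour_gain",
           "midpoint_force", "k0", "delta_x", "foldable")
  miss <- setdiff(req, names(elements))
  if (length(miss)) stop("element table missing columns: ", paste(miss, collapse = ", "))
  if (!all(elements$kind %in% c("ig_domain", "helix_linker"))) {
    stop("unknown element kind: ",
         paste(setdiff(unique(elements$kind), c("ig_domain", "helix_linker")), collapse = ", "))
  }
  elements <- tibble::as_tibble(elements)
  if (symmetry == "dimer") {
    mirrored <- elements[rev(seq_len(nrow(elements))), ]
    mirrored$label <- paste0(mirrored$label, "'")
    elements <- dplyr::bind_rows(elements, mirrored)
  }
  structure(elements, class = c("filament_architecture", class(elements)),
            symmetry = symmetry)
}

#' Canonical My9-My13 filament architecture
#'
#' The C-terminal myomesin filament: per protomer five Ig domains
#' (My9..My13) alternating with four alpha-helical linkers (two roughly
#' four-turn and two roughly six-turn helices), dimerised tail-to-tail
#' about the central (My13)2 module. The dimer comprises nine rigid
#' bodies: eight unfoldable Ig domains plus the central My13 pair, which
#' is treated as a single non-unfoldable element.
#'
#' Defaults: Ig domains of 92 residues with folded extent 3.88 nm and
#' contour gain 29.7 nm (so that 92 x 0.365 - 3.88 = 29.70 nm, consistent
#' with [expected_ig_contour_gain()]); helical linkers of 15/22/22/15
#' residues, each contributing a 6 nm contour gain with a 30 pN two-state
#' midpoint. Exact linker boundaries are known only graphically, so all
#' counts are overridable.
#'
#' @param symmetry `"dimer"` (default) for the full tail-to-tail filament
#'   or `"monomer"` for a single My9..My13 arm (all five Ig domains
#'   foldable).
#' @param ig_residues,ig_folded_extent,ig_contour_gain,ig_k0,ig_delta_x
#'   Ig-domain parameters (recycled over the five domains).
#' @param linker_residues Residue counts of the four helical linkers.
#' @param helix_contour_gain,helix_midpoint Helix contour gain (nm) and
#'   two-state midpoint force (pN), recycled over linkers.
#' @return A [filament_architecture()].
#' @examples
#' canonical_architecture()
#' @export
canonical_architecture <- function(symmetry = c("dimer", "monomer"),
                                   ig_residues = 92,
                                   ig_folded_extent = 3.88,
                                   ig_contour_gain = 29.7,
                                   ig_k0 = 1e-4,
                                   ig_delta_x = 0.3,
                                   linker_residues = c(15, 22, 22, 15),
                                   helix_contour_gain = 6.0,
                                   helix_midpoint = 30) {
  symmetry <- match.arg(symmetry)
  stopifnot(length(linker_residues) == 4)
  ig_residues <- rep_len(ig_residues, 5)
  ig_folded_extent <- rep_len(ig_folded_extent, 5)
  ig_contour_gain <- rep_len(ig_contour_gain, 5)
  helix_contour_gain <- rep_len(helix_contour_gain, 4)
  helix_midpoint <- rep_len(helix_midpoint, 4)
  labels <- paste0("My", 9:13)
  rows <- vector("list", 9)
  for (i in 1:5) {
    # In the dimer the central My13 pair is the dimerisation interface and
    # is kept rigid; in a monomer arm all domains can unfold.
    foldable <- !(symmetry == "dimer" && i == 5)
    rows[[2 * i - 1]] <- filament_element(
      "ig_domain", labels[i],
      residues = ig_residues[i],
      folded_extent = ig_folded_extent[i],
      contour_gain = ig_contour_gain[i],
      k0 = ig_k0, delta_x = ig_delta_x,
      foldable = foldable
    )
    if (i < 5) {
      rows[[2 * i]] <- filament_element(
        "helix_linker", paste0("h", i),
        residues = linker_residues[i],
        contour_gain = helix_contour_gain[i],
        midpoint_force = helix_midpoint[i]
      )
    }
  }
  filament_architecture(dplyr::bind_rows(rows), symmetry = symmetry)
}

#' Straightened-filament reference decomposition
#'
#' The architecture configured so that the fully extended tail-to-tail
#' dimer reproduces the published straightened-length decomposition:
#' ten straightened My-domain modules of 29 Angstrom each (290 Angstrom)
#' plus unfolded helical linkers of 150 residues total at a C-alpha
#' spacing of 3.8 Angstrom (570 Angstrom), i.e. 860 Angstrom overall.
#' Only the class totals are published; the per-linker integer split
#' (15/22/23/15 residues per protomer) is a declared configuration.
#'
#' @return A dimer [filament_architecture()].
#' @seealso [extended_filament_length()]
#' @export
straightened_reference_architecture <- function() {
  canonical_architecture(
    symmetry = "dimer",
    ig_folded_extent = 2.9,            # nm; straightened module length 29 A
    linker_residues = c(15, 22, 23, 15) # 75/protomer -> 150 residues in the dimer
  )
}

#' @export
print.filament_architecture <- function(x, ...) {
  cat("<filament_architecture> ", attr(x, "symmetry"), ", ",
      nrow(x), " elements (",
      sum(x$kind == "ig_domain"), " Ig, ",
      sum(x$kind == "helix_linker"), " helix)\n", sep = "")
  NextMethod()
}
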