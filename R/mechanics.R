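#' Equilibrium unfolded fraction of a two-state helical linker
#'
#' Helix unfolding/refolding is fast compared with pulling, so the state
#' occupancy follows a two-state Boltzmann law in the applied force:
#' `1 / (1 + exp(-(F - F_mid) * dL_eff / kT))`, where `dL_eff` is the
#' extension gained by unfolding at the midpoint force (the contour gain
#' times the worm-like-chain fractional extension at `F_mid`). The
#' fraction is exactly 0.5 at the midpoint and essentially zero at rest.
#'
#' @param force Applied force, pN (vectorised).
#' @param midpoint_force Two-state midpoint force, pN.
#' @param contour_gain Contour-length gain of the unfolded helix, nm.
#' @param persistence_length Persistence length of the unfolded chain, nm.
#' @param temperature Temperature, K.
#' @return Unfolded fraction in `[0, 1]`.
#' @examples
#' helix_unfolded_fraction(30)  # 0.5 at the default 30 pN midpoint
#' @export
helix_unfolded_fraction <- function(force,
                                    midpoint_force = 30,
                                    contour_gain = 6,
                                    persistence_length = 0.5,
                                    temperature = 298) {
  if (any(force < 0)) stop("`force` must be non-negative")
  kT <- thermal_energy(temperature)
  dl_eff <- contour_gain *
    ms_frac_at_force(midpoint_force, persistence_length, temperature)
  stats::plogis((force - midpoint_force) * dl_eff / kT)
}

#' Bell-Evans force-activated unfolding rate
#'
#' `k(F) = k0 * exp(F * delta_x / kT)`: the log-rate is linear in force
#' with slope `delta_x / kT`.
#'
#' @param force Applied force, pN (vectorised).
#' @param k0 Zero-force unfolding rate, 1/s.
#' @param delta_x Distance to the transition state, nm.
#' @param temperature Temperature, K.
#' @return Unfolding rate in 1/s.
#' @examples
#' bell_evans_rate(0, k0 = 1e-4, delta_x = 0.3)   # k0
#' @export
bell_evans_rate <- function(force, k0 = 1e-4, delta_x = 0.3, temperature = 298) {
  if (any(force < 0)) stop("`force` must be non-negative")
  if (k0 <= 0 || delta_x <= 0) stop("`k0` and `delta_x` must be positive")
  k0 * exp(force * delta_x / thermal_energy(temperature))
}

# Decompose an architecture + state vector into the three quantities the
# quasi-static force balance needs:
#   rigid    -- extension independent of force (nm)
#   contour  -- total effective WLC contour length (nm)
# In "wlc" compliance mode every folded element is itself a short WLC of
# contour equal to its folded extent, so the whole filament is a single
# effective WLC whose contour jumps by exactly `contour_gain` on each
# unfolding. In "rigid" mode folded extents are inextensible rods that
# stay in the chain and only the unfolded gains are compliant.
chain_decompose <- function(arch, unfolded, folded_compliance = c("wlc", "rigid")) {
  folded_compliance <- match.arg(folded_compliance)
  base <- sum(arch$folded_extent)
  pool <- sum(arch$contour_gain[unfolded])
  if (folded_compliance == "wlc") {
    list(rigid = 0, contour = base + pool)
  } else {
    list(rigid = base, contour = pool)
  }
}

#' Extension of a serial chain of filament elements at a common force
#'
#' Elements in series all feel the same force and their extensions add.
#' Unfolded contour behaves as a worm-like chain; folded elements
#' contribute either as short worm-like chains of their folded extent
#' (`folded_compliance = "wlc"`, the default, making the filament one
#' effective WLC) or as inextensible rods (`"rigid"`).
#'
#' @param force Applied force, pN (vectorised).
#' @param arch A [filament_architecture()].
#' @param unfolded Logical vector, one per element: is the element
#'   currently unfolded? Default all folded.
#' @param folded_compliance `"wlc"` or `"rigid"`.
#' @param persistence_length Persistence length, nm.
#' @param temperature Temperature, K.
#' @return Extension in nm.
#' @examples
#' arm <- canonical_architecture("monomer")
#' serial_chain_extension(30, arm)
#' @export
serial_chain_extension <- function(force, arch,
                                   unfolded = rep(FALSE, nrow(arch)),
                                   folded_compliance = c("wlc", "rigid"),
                                   persistence_length = 0.5,
                                   temperature = 298) {
  stopifnot(inherits(arch, "filament_architecture"),
            length(unfolded) == nrow(arch))
  parts <- chain_decompose(arch, unfolded, folded_compliance)
  phi <- ms_frac_at_force(force, persistence_length, temperature)
  parts$rigid + parts$contour * phi
}

#' Continuous-time two-state (Gillespie) simulation at fixed force
#'
#' Simulates the folded/unfolded telegraph process of a helical linker at
#' constant force with rates chosen so that detailed balance reproduces
#' the equilibrium occupancy of [helix_unfolded_fraction()]:
#' `k_unfold = nu * sqrt(p/(1-p))`, `k_fold = nu * sqrt((1-p)/p)`.
#' Used as the stochastic oracle for the equilibrium occupancy and as the
#' package's optional kinetic helix mode.
#'
#' @param force Constant force, pN.
#' @param n_events Number of state transitions to simulate.
#' @param midpoint_force,contour_gain,persistence_length,temperature As in
#'   [helix_unfolded_fraction()].
#' @param attempt_rate Symmetric attempt frequency `nu`, 1/s.
#' @return A list with `occupancy` (time-averaged unfolded fraction),
#'   `se` (batch-means standard error, 10 batches), `n_events`, and
#'   `total_time` in s.
#' @examples
#' gillespie_two_state(30, n_events = 1e3, attempt_rate = 1e3)
#' @export
gillespie_two_state <- function(force, n_events = 1e5,
                                midpoint_force = 30, contour_gain = 6,
                                persistence_length = 0.5, temperature = 298,
                                attempt_rate = 1e4) {
  p_eq <- helix_unfolded_fraction(force, midpoint_force, contour_gain,
                                  persistence_length, temperature)
  k_unfold <- attempt_rate * sqrt(p_eq / (1 - p_eq))
  k_fold <- attempt_rate * sqrt((1 - p_eq) / p_eq)
  # alternating exponential dwells; start folded
  n_half <- ceiling(n_events / 2)
  dwell_folded <- stats::rexp(n_half, rate = k_unfold)
  dwell_unfolded <- stats::rexp(n_half, rate = k_fold)
  batches <- rep(seq_len(10), length.out = n_half)
  occ_b <- vapply(split(seq_len(n_half), batches), function(idx) {
    sum(dwell_unfolded[idx]) / (sum(dwell_unfolded[idx]) + sum(dwell_folded[idx]))
  }, numeric(1))
  total_unf <- sum(dwell_unfolded)
  total <- total_unf + sum(dwell_folded)
  list(
    occupancy = total_unf / total,
    se = stats::sd(occ_b) / sqrt(length(occ_b)),
    n_events = 2 * n_half,
    total_time = total
  )
}
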