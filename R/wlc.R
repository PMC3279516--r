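#' Worm-like-chain parameter set
#'
#' @param persistence_length Persistence length p, nm.
#' @param contour_length Contour length L, nm.
#' @param temperature Temperature, K.
#' @return A list of class `wlc_params`.
#' @examples
#' wlc_params(contour_length = 30)
#' @export
wlc_params <- function(persistence_length = 0.5,
                       contour_length,
                       temperature = 298) {
  if (!is.numeric(persistence_length) || persistence_length <= 0) {
    stop("`persistence_length` must be positive")
  }
  if (missing(contour_length) || !is.numeric(contour_length) || contour_length <= 0) {
    stop("`contour_length` must be positive")
  }
  structure(
    list(
      persistence_length = persistence_length,
      contour_length = contour_length,
      temperature = temperature
    ),
    class = "wlc_params"
  )
}

# Marko-Siggia interpolation at fractional extension phi = x/L.
# Returns force in pN. Vectorised over phi.
ms_force_frac <- function(phi, persistence_length = 0.5, temperature = 298) {
  kT <- thermal_energy(temperature)
  (kT / persistence_length) * (phi + 1 / (4 * (1 - phi)^2) - 0.25)
}

# d(force)/d(phi), used by Newton solvers.
ms_dforce_frac <- function(phi, persistence_length = 0.5, temperature = 298) {
  kT <- thermal_energy(temperature)
  (kT / persistence_length) * (1 + 1 / (2 * (1 - phi)^3))
}

# Stretching energy per unit contour length at fractional extension phi
# (integral of the Marko-Siggia force over extension), pN nm per nm.
ms_energy_frac <- function(phi, persistence_length = 0.5, temperature = 298) {
  kT <- thermal_energy(temperature)
  (kT / persistence_length) * (phi^2 / 2 + 1 / (4 * (1 - phi)) - phi / 4 - 0.25)
}

# Invert Marko-Siggia: fractional extension phi in [0, 1) at given force.
# Newton with bisection safeguard; vectorised; rel. tolerance ~1e-12.
ms_frac_at_force <- function(force, persistence_length = 0.5, temperature = 298) {
  if (!length(force)) return(numeric(0))
  if (any(force < 0)) stop("`force` must be non-negative")
  kT <- thermal_energy(temperature)
  f <- force * persistence_length / kT   # dimensionless
  phi <- pmin(pmax(f / (f + 1.5), 0), 0.99)  # rough start, exact limits both ends
  for (i in 1:100) {
    g <- phi + 1 / (4 * (1 - phi)^2) - 0.25 - f
    dg <- 1 + 1 / (2 * (1 - phi)^3)
    step <- g / dg
    phi_new <- phi - step
    phi_new[phi_new < 0] <- phi[phi_new < 0] / 2
    phi_new[phi_new >= 1] <- (phi[phi_new >= 1] + 1) / 2
    phi <- phi_new
    if (max(abs(step)) < 1e-14) break
  }
  phi[force == 0] <- 0
  phi
}

#' Worm-like-chain force at a given extension
#'
#' Marko-Siggia interpolation formula
#' `F = (kT/p) * (x/L + 1/(4 (1 - x/L)^2) - 1/4)`,
#' monotone increasing in extension and divergent as `x -> L`.
#'
#' @param extension End-to-end extension x, nm. Must satisfy
#'   `0 <= x < contour_length`.
#' @param params A [wlc_params()] object.
#' @return Force in pN (vectorised over `extension`).
#' @examples
#' p <- wlc_params(contour_length = 30)
#' wlc_force(15, p)   # half extension
#' @export
wlc_force <- function(extension, params) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(extension < 0)) stop("`extension` must be non-negative")
  if (any(extension >= params$contour_length)) {
    stop("`extension` must be below the contour length (force diverges at x = L)")
  }
  ms_force_frac(extension / params$contour_length,
                params$persistence_length, params$temperature)
}

#' Worm-like-chain extension at a given force
#'
#' Numerical inverse of [wlc_force()]: the unique extension `x` in
#' `[0, L)` with `wlc_force(x) = force`, solved by safeguarded Newton
#' iteration to relative tolerance better than 1e-8.
#'
#' @param force Force in pN, non-negative (vectorised).
#' @param params A [wlc_params()] object.
#' @return Extension in nm.
#' @examples
#' p <- wlc_params(contour_length = 30)
#' wlc_extension(wlc_force(21, p), p)  # 21
#' @export
wlc_extension <- function(force, params) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(force < 0)) stop("`force` must be non-negative")
  params$contour_length *
    ms_frac_at_force(force, params$persistence_length, params$temperature)
}
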