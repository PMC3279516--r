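#' Build a synthetic superhelical bead filament
#'
#' Generates a bead model of `n_modules` identical modules whose
#' centroids lie on a helix of the given rise, per-module rotation
#' (twist) and radius. All modules share one template point cloud
#' (an elongated spiral of beads aligned with the helix axis, plus a
#' small seeded jitter), rotated about the helix axis by the cumulative
#' twist, so tilt/twist recovery with [tilt_twist()] is well posed: the
#' designed consecutive centroid distance is
#' `sqrt(rise^2 + (2 r sin(twist/2))^2)` and the recovered twist equals
#' the input twist.
#'
#' This is a synthetic fixture generator, used to validate the geometry
#' pipeline (centroid spectra, tilt/twist, p(r)) against closed forms; it
#' is not a physical model of any deposited structure.
#'
#' @param n_modules Number of modules (>= 1).
#' @param rise Axial rise per module, Angstrom.
#' @param twist Rotation per module about the helix axis, degrees.
#' @param radius Helix radius of the module centroids, Angstrom (>= 0).
#' @param points_per_module Beads per module (>= 3).
#' @param module_length Axial extent of the module template, Angstrom.
#' @param module_radius Radial extent of the module template, Angstrom.
#' @param jitter Gaussian jitter added to the template, Angstrom.
#' @param seed Seed for the template jitter.
#' @return A [structure_model()] with domains `module_01`, `module_02`, ...
#' @examples
#' sh <- build_synthetic_superhelix(5, rise = 38, twist = 26.5, radius = 10)
#' neighbor_distance_stats(domain_centroids(sh), order = 1)
#' @export
build_synthetic_superhelix <- function(n_modules, rise = 38, twist = 26.5,
                                       radius = 10, points_per_module = 24,
                                       module_length = 20, module_radius = 4,
                                       jitter = 0.15, seed = 1L) {
  if (n_modules < 1) stop("`n_modules` must be >= 1")
  if (radius < 0) stop("`radius` must be >= 0")
  if (points_per_module < 3) stop("`points_per_module` must be >= 3")
  set.seed(seed)
  m <- points_per_module
  # Elongated template centred at the origin: beads on the z axis plus an
  # ellipse in the xy plane. Jitter is applied along z for the axis beads
  # and in-plane for the ring beads, so all cross-covariances with z
  # vanish exactly and the template's long inertia axis is exactly the
  # helix axis -- a rotation about z is then recovered by tilt_twist()
  # as a pure twist.
  m_axis <- ceiling(m / 2)
  m_ring <- m - m_axis
  axis_pts <- cbind(0, 0, seq(-module_length / 2, module_length / 2,
                              length.out = m_axis) +
                      stats::rnorm(m_axis, sd = jitter))
  template <- axis_pts
  if (m_ring > 0) {
    t_ang <- seq(0, 2 * pi, length.out = m_ring + 1)[seq_len(m_ring)]
    ring <- cbind(module_radius * cos(t_ang) + stats::rnorm(m_ring, sd = jitter),
                  (module_radius / 2) * sin(t_ang) + stats::rnorm(m_ring, sd = jitter),
                  0)
    template <- rbind(axis_pts, ring)
  }
  th <- twist * pi / 180
  atoms <- purrr::map_dfr(seq_len(n_modules) - 1L, function(k) {
    a <- k * th
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    ctr <- c(radius * cos(a), radius * sin(a), k * rise)
    pts <- template %*% t(Rz) + matrix(ctr, m, 3, byrow = TRUE)
    pts <- sweep(pts, 2, colMeans(pts) - ctr)   # pin the centroid exactly
    tibble::tibble(
      chain = "A",
      resno = k * m + seq_len(m),
      atom = "CA",
      element = "C",
      x = pts[, 1], y = pts[, 2], z = pts[, 3]
    )
  })
  domains <- tibble::tibble(
    label = sprintf("module_%02d", seq_len(n_modules)),
    chain = "A",
    first = (seq_len(n_modules) - 1L) * m + 1L,
    last = seq_len(n_modules) * m
  )
  structure_model(atoms, domains)
}

#' Designed consecutive centroid distance of a superhelix
#'
#' Closed form `sqrt(rise^2 + (2 r sin(twist/2))^2)` for the distance
#' between consecutive module centroids of a regular helix.
#'
#' @param rise Axial rise per module, Angstrom.
#' @param twist Rotation per module, degrees.
#' @param radius Helix radius, Angstrom.
#' @return Distance in Angstrom.
#' @export
superhelix_consecutive_distance <- function(rise, twist, radius) {
  sqrt(rise^2 + (2 * radius * sin(twist * pi / 360))^2)
}

#' Synthetic stand-in for the composite My9-My13 filament model
#'
#' A ten-module regular superhelix whose geometry is solved so that the
#' order-1, order-3 and order-4 centroid distances are exactly the
#' 50 / 116 / 153 Angstrom distance windows reported for the composite
#' filament model (rise 38.0593 Angstrom, radius 21.0704 Angstrom,
#' per-module rotation 259.3848 degrees, i.e. -100.6 degrees), with a
#' maximum dimension close to 360 Angstrom. This is a synthetic fixture:
#' it reproduces the filament's distance spectrum for pipeline
#' validation, not the deposited coordinates, and its per-module rotation
#' is a geometric solution, not the filament's 26-27 degree twist.
#'
#' @param n_modules Number of modules; 10 for the dimer-sized filament.
#' @param points_per_module,seed Passed to
#'   [build_synthetic_superhelix()].
#' @return A [structure_model()].
#' @export
synthetic_filament_standin <- function(n_modules = 10, points_per_module = 40,
                                       seed = 1L) {
  build_synthetic_superhelix(
    n_modules = n_modules,
    rise = 38.0592721613,
    twist = 259.3848,
    radius = 21.0704162742,
    points_per_module = points_per_module,
    module_length = 18,
    module_radius = 6,
    jitter = 0.1,
    seed = seed
  )
}
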