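# Shared fixtures: small architectures and synthetic traces built in code.

# n Ig domains in series, no helical linkers
ig_only_architecture <- function(n = 4, k0 = 1e-4, delta_x = 0.3,
                                 contour_gain = 29.7) {
  rows <- lapply(seq_len(n), function(i) {
    filament_element("ig_domain", paste0("D", i), residues = 92,
                     contour_gain = contour_gain, k0 = k0, delta_x = delta_x)
  })
  filament_architecture(dplyr::bind_rows(rows))
}

# noise-free trace lying exactly on one worm-like chain pulled against a
# cantilever (quasi-static, no transitions)
pure_wlc_trace <- function(contour = 120, persistence = 0.5, stiffness = 6,
                           x_max = 0.92 * contour, dx = 0.05) {
  p <- wlc_params(persistence_length = persistence, contour_length = contour)
  x <- seq(dx, x_max, by = dx)
  f <- wlc_force(x, p)
  tr <- tibble::tibble(
    time_s = seq_along(x) * 5e-5,
    stage_nm = x + f / stiffness,
    extension_nm = x,
    force_pN = f
  )
  class(tr) <- c("fe_trace", class(tr))
  tr
}
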