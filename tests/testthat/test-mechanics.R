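test_that("serial chain extension adds element extensions at common force", {
  one <- filament_architecture(
    filament_element("ig_domain", "D1", 92, folded_extent = 4, contour_gain = 30)
  )
  # single unfolded element behaves as a WLC of its total contour
  p <- wlc_params(contour_length = 34)
  f <- c(2, 10, 40)
  expect_equal(serial_chain_extension(f, one, unfolded = TRUE),
               wlc_extension(f, p))
  # additivity: A+B = A + B at every force
  two <- filament_architecture(dplyr::bind_rows(
    filament_element("ig_domain", "D1", 92, folded_extent = 4, contour_gain = 30),
    filament_element("helix_linker", "h1", 20, folded_extent = 3, contour_gain = 6)
  ))
  expect_equal(serial_chain_extension(f, two, unfolded = c(TRUE, TRUE)),
               serial_chain_extension(f, one, unfolded = TRUE) +
                 wlc_extension(f, wlc_params(contour_length = 9)))
  # doubling all contour lengths doubles the extension at fixed force
  expect_equal(serial_chain_extension(f, two, unfolded = c(TRUE, TRUE)) * 2,
               serial_chain_extension(
                 f,
                 filament_architecture(dplyr::bind_rows(
                   filament_element("ig_domain", "D1", 92, folded_extent = 8,
                                    contour_gain = 60),
                   filament_element("helix_linker", "h1", 20, folded_extent = 6,
                                    contour_gain = 12)
                 )),
                 unfolded = c(TRUE, TRUE)
               ))
  # rigid mode: folded elements are inextensible rods
  expect_equal(serial_chain_extension(f, two, unfolded = c(FALSE, FALSE),
                                      folded_compliance = "rigid"),
               rep(7, length(f)))
})

test_that("helix occupancy is 0.5 at the midpoint and ~0 at rest", {
  expect_equal(helix_unfolded_fraction(30), 0.5)
  expect_lt(helix_unfolded_fraction(0), 0.01)
  f <- seq(0, 60, by = 5)
  expect_true(all(diff(helix_unfolded_fraction(f)) > 0))
})

test_that("Gillespie two-state occupancy matches the Boltzmann closed form", {
  set.seed(42)
  for (f in c(27, 30, 33)) {
    g <- gillespie_two_state(f, n_events = 1e5, attempt_rate = 1e4)
    expect_lt(abs(g$occupancy - helix_unfolded_fraction(f)), 3 * g$se)
  }
})

test_that("Bell-Evans rate is exponential in force", {
  kT <- thermal_energy(298)
  expect_equal(bell_evans_rate(0, k0 = 1e-4, delta_x = 0.3), 1e-4)
  expect_equal(bell_evans_rate(kT * log(2) / 0.3, k0 = 1e-4, delta_x = 0.3),
               2e-4)
  # log-linear with slope delta_x / kT
  f <- c(10, 50, 90, 130)
  lk <- log(bell_evans_rate(f, k0 = 1e-4, delta_x = 0.3))
  expect_equal(unname(stats::coef(stats::lm(lk ~ f))[2]), 0.3 / kT,
               tolerance = 1e-10)
})

test_that("a pull with transitions disabled is a smooth WLC-vs-cantilever curve", {
  arch <- ig_only_architecture(2)
  pr <- constant_velocity_protocol(to = 8, speed = 1000, force_noise_sd = 0,
                                   seed = 3)
  tr <- simulate_pull(arch, pr, transitions = FALSE)
  expect_equal(nrow(trace_events(tr)), 0)
  expect_true(all(diff(tr$force_pN) >= 0))
  # quasi-static balance residual at every sample, in force units
  resid <- (tr$stage_nm - tr$extension_nm) * 6 - tr$force_pN
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("stretch and relax are identical when noise and transitions are off", {
  arch <- canonical_architecture("monomer")
  pr <- stretch_relax_protocol(from = 0.5, to = 12, speed = 1000,
                               force_noise_sd = 0, seed = 5)
  tr <- simulate_pull(arch, pr, transitions = FALSE)
  ph <- trace_phases(tr)
  expect_length(ph, 2)
  st <- ph[[1]]; rx <- ph[[2]]
  # the reversed relax grid revisits the stretch grid shifted by one sample
  n <- nrow(st)
  expect_equal(utils::head(st$stage_nm, n - 1), rev(rx$stage_nm)[-1])
  expect_equal(utils::head(st$force_pN, n - 1), rev(rx$force_pN)[-1],
               tolerance = 1e-9)
  expect_equal(abs(hysteresis(st, rx)), 0, tolerance = 1e-3)
})

test_that("identical seeds give bit-identical traces and different seeds differ", {
  arch <- canonical_architecture()
  pr <- constant_velocity_protocol(to = 120, speed = 2000, seed = 77)
  t1 <- simulate_pull(arch, pr)
  t2 <- simulate_pull(arch, pr)
  expect_identical(t1$force_pN, t2$force_pN)
  expect_identical(trace_events(t1), trace_events(t2))
  pr2 <- constant_velocity_protocol(to = 120, speed = 2000, seed = 78)
  expect_false(identical(simulate_pull(arch, pr2)$force_pN, t1$force_pN))
})

test_that("Ig domains unfold at most once; helices can toggle repeatedly", {
  arch <- canonical_architecture("monomer")
  pr <- constant_velocity_protocol(to = 60, speed = 100, seed = 12)
  tr <- simulate_pull(arch, pr, log_helix = TRUE)
  ev <- trace_events(tr)
  ig <- ev[ev$kind == "ig_domain", ]
  expect_true(all(table(ig$label) <= 1))
  expect_true(all(ig$transition == "unfold"))
  # helix toggle counts recorded; repeated toggling is expected in the plateau
  expect_gt(sum(attr(tr, "helix_toggles")), 4)
  # event count never exceeds the number of foldable elements per kind
  expect_lte(nrow(ig), sum(arch$kind == "ig_domain" & arch$foldable))
})

test_that("mean Ig unfolding force increases with pulling speed", {
  arch <- ig_only_architecture(1)
  mean_force <- vapply(c(200, 1000, 5000), function(v) {
    fs <- vapply(1:20, function(k) {
      pr <- constant_velocity_protocol(to = 60, speed = v, seed = 9000 + 13 * k)
      ev <- trace_events(simulate_pull(arch, pr))
      if (nrow(ev)) ev$force_pN[1] else NA_real_
    }, numeric(1))
    mean(fs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_force) > 0))
})
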