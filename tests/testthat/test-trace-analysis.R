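test_that("a smooth monotone trace yields no events", {
  tr <- pure_wlc_trace(contour = 120)
  expect_equal(nrow(detect_events(tr)), 0)
})

test_that("event detection recovers the generator event log", {
  arch <- ig_only_architecture(4)
  n_true <- 0; n_det <- 0; n_matched <- 0
  for (k in 1:10) {
    pr <- constant_velocity_protocol(to = 180, speed = 1000, seed = 500 + 11 * k)
    tr <- simulate_pull(arch, pr)
    truth <- trace_events(tr)
    truth <- truth[truth$kind == "ig_domain", ]
    # keep pulls without coincident double events: those are one observable drop
    if (anyDuplicated(truth$time_s)) next
    ev <- detect_events(tr)
    n_true <- n_true + nrow(truth)
    n_det <- n_det + nrow(ev)
    for (t0 in truth$time_s) {
      if (any(abs(ev$time_s - t0) <= 5e-3)) n_matched <- n_matched + 1
    }
  }
  expect_gt(n_true, 20)
  recall <- n_matched / n_true
  precision <- n_matched / n_det
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("a four-event trace is detected event-for-event within 5 ms", {
  arch <- ig_only_architecture(4)
  pr <- constant_velocity_protocol(to = 180, speed = 1000, seed = 533)
  tr <- simulate_pull(arch, pr)
  truth <- trace_events(tr)
  expect_equal(nrow(truth), 4)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 4)
  expect_true(all(abs(sort(ev$time_s) - sort(truth$time_s)) <= 5e-3))
  # events strictly ordered, drops larger than the ~30 pN plateau scale
  expect_true(all(diff(ev$time_s) > 0))
  expect_true(all(ev$drop_pN > 30))
})

test_that("noise-free single-segment fit recovers the contour length to 0.1 nm", {
  tr <- pure_wlc_trace(contour = 120)
  fits <- fit_wlc_segments(tr, events = myoelastica:::empty_events(),
                           min_force = 5)
  expect_equal(nrow(fits), 1)
  expect_lt(abs(fits$contour_nm - 120), 0.1)
})

test_that("Delta-L of a dimer pull matches the generator contour gains", {
  arch <- canonical_architecture()
  pr <- constant_velocity_protocol(to = 450, speed = 1000, seed = 101)
  tr <- simulate_pull(arch, pr)
  ev <- detect_events(tr)
  fits <- suppressWarnings(fit_wlc_segments(tr, ev))
  dl <- fits$delta_L_nm[!is.na(fits$delta_L_nm)]
  expect_gt(length(dl), 5)
  expect_true(all(abs(dl - 29.7) < 0.5))
})

test_that("contour transform is the exact inverse of single-WLC generation", {
  tr <- pure_wlc_trace(contour = 80)
  cls <- contour_length_transform(tr, force_floor = 5)
  expect_gt(nrow(cls), 100)
  expect_lt(max(abs(cls$contour_nm - 80)), 1e-6)
})

test_that("interleaved samples from two WLCs give modes 6 nm apart", {
  p1 <- wlc_params(contour_length = 40)
  p2 <- wlc_params(contour_length = 46)
  fg <- seq(10, 40, by = 0.02)
  idx <- rep(seq_along(fg), each = 2)
  on_first <- rep(c(TRUE, FALSE), times = length(fg))
  f <- fg[idx]
  x <- ifelse(on_first, wlc_extension(f, p1), wlc_extension(f, p2))
  set.seed(5)
  f_rec <- f + stats::rnorm(length(f), sd = 1.5)  # recorded force is noisy
  tr <- tibble::tibble(time_s = seq_along(f) * 5e-5, stage_nm = x + f / 6,
                       extension_nm = x, force_pN = f_rec)
  cls <- contour_length_transform(tr, force_floor = 5)
  ps <- fit_peak_spacing(cls, n_peaks = 2, bin_width = 0.5)
  expect_equal(ps$n_peaks, 2)
  expect_equal(ps$spacing_nm, 6, tolerance = 0.05)
  expect_equal(ps$peaks$mean_nm, c(40, 46), tolerance = 0.01)
})

test_that("peak spacing is recovered without bias from a constructed mixture", {
  set.seed(7)
  x <- c(stats::rnorm(2500, 40, 1), stats::rnorm(2500, 46, 1),
         stats::rnorm(2500, 52, 1), stats::rnorm(2500, 58, 1))
  ps <- fit_peak_spacing(x)
  expect_equal(ps$n_peaks, 4)
  expect_lt(abs(ps$spacing_nm - 6), 0.1)
  expect_equal(ps$spacing_nm, 6, tolerance = 0.2 / 6)
})

test_that("a single narrow cluster has undefined spacing", {
  set.seed(8)
  ps <- fit_peak_spacing(stats::rnorm(2000, 35, 0.8), n_peaks = 1)
  expect_equal(ps$n_peaks, 1)
  expect_true(is.na(ps$spacing_nm))
})

test_that("a pure WLC trace has no plateau", {
  expect_equal(nrow(detect_plateau(pure_wlc_trace(contour = 120))), 0)
})

test_that("the plateau detector recovers the helix midpoint force", {
  arm <- canonical_architecture("monomer")
  pr <- constant_velocity_protocol(to = 55, speed = 10, seed = 204)
  tr <- simulate_pull(arm, pr)
  pl <- detect_plateau(tr)
  expect_equal(nrow(pl), 1)
  expect_lt(abs(pl$plateau_force_pN - 30), 2)
  expect_gte(pl$span_nm, 10)
})

test_that("hysteresis is zero for identical curves and h*w for a rectangle", {
  tr <- pure_wlc_trace(contour = 60)
  expect_equal(hysteresis(tr, tr), 0)
  # rectangular loop 10 pN tall, 5 nm wide
  up <- tibble::tibble(time_s = 1:100 * 1e-3, stage_nm = seq(10, 15, length.out = 100),
                       extension_nm = seq(10, 15, length.out = 100),
                       force_pN = rep(20, 100))
  dn <- up; dn$force_pN <- rep(10, 100)
  expect_equal(hysteresis(up, dn), 50, tolerance = 1e-6)
  far <- up; far$extension_nm <- far$extension_nm + 100; far$stage_nm <- far$stage_nm + 100
  expect_error(hysteresis(up, far), "overlap")
})
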