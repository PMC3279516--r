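rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

test_that("read_pdb handles the identity case and round trips written files", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"
  ), tf)
  m <- read_pdb(tf)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(unlist(m$atoms[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
  # write/read round trip of a synthetic model, 3 decimals
  sh <- build_synthetic_superhelix(3, seed = 2)
  pf <- tempfile(fileext = ".pdb")
  write_pdb(sh, pf)
  back <- read_pdb(pf, domains = sh$domains)
  expect_equal(nrow(back$atoms), nrow(sh$atoms))
  expect_lt(max(abs(back$atoms$x - sh$atoms$x)), 5e-4 + 1e-9)
  expect_lt(max(abs(back$atoms$z - sh$atoms$z)), 5e-4 + 1e-9)
})

test_that("read_pdb rejects degenerate or malformed files", {
  f1 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  C   LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"
  ), f1)
  expect_error(read_pdb(f1), "no ATOM records")
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   bad     0.000  1.00  0.00           C"
  ), f2)
  expect_error(read_pdb(f2), "line 1")
  f3 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1A      0.000   1.000   0.000  1.00  0.00           C"
  ), f3)
  expect_error(read_pdb(f3), "insertion")
  expect_error(read_pdb(tempfile()), "not found")
})

test_that("superposition recovers a known rigid motion and flags degeneracy", {
  sh <- build_synthetic_superhelix(4, seed = 9)
  # identity: model onto itself
  self <- superpose_shared_domain(sh, sh, "module_02")
  expect_lt(self$rmsd, 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  # rotate 37 degrees about z, translate, recover
  moved <- apply_transform(sh, rot_z(37), c(5, -2, 1))
  sp <- superpose_shared_domain(moved, sh, "module_03")
  expect_lt(sp$rmsd, 1e-6)
  expect_equal(sp$rotation %*% rot_z(37), diag(3), tolerance = 1e-8)
  # all atoms are brought back, not only the matched domain
  expect_equal(sp$transformed$atoms$x, sh$atoms$x, tolerance = 1e-8)
  # idempotence: superposing the superposed model changes rmsd by < 1e-9
  again <- superpose_shared_domain(sp$transformed, sh, "module_03")
  expect_lt(abs(again$rmsd - sp$rmsd), 1e-9)
  # fewer than 3 shared C-alpha positions
  small <- structure_model(sh$atoms[1:2, ],
                           tibble::tibble(label = "m", chain = "A",
                                          first = 1, last = 2))
  expect_error(superpose_shared_domain(small, small, "m"), "at least 3")
  # collinear point sets are flagged
  lin <- structure_model(
    tibble::tibble(chain = "A", resno = 1:5, atom = "CA", element = "C",
                   x = 1:5, y = 0, z = 0),
    tibble::tibble(label = "m", chain = "A", first = 1, last = 5)
  )
  expect_error(superpose_shared_domain(lin, lin, "m"), "collinear")
})

test_that("superposition agrees with the bio3d reference implementation", {
  sh <- build_synthetic_superhelix(3, seed = 4)
  moved <- apply_transform(sh, rot_z(25), c(-3, 7, 2))
  a <- myoelastica:::domain_atoms(moved, "module_01")
  b <- myoelastica:::domain_atoms(sh, "module_01")
  nxyz <- 3 * nrow(a)
  fit <- bio3d::fit.xyz(
    fixed = as.numeric(t(cbind(b$x, b$y, b$z))),
    mobile = as.numeric(t(cbind(a$x, a$y, a$z))),
    fixed.inds = seq_len(nxyz), mobile.inds = seq_len(nxyz)
  )
  ours <- superpose_shared_domain(moved, sh, "module_01")
  moved_ours <- myoelastica:::domain_atoms(ours$transformed, "module_01")
  expect_equal(cbind(moved_ours$x, moved_ours$y, moved_ours$z),
               matrix(fit, ncol = 3, byrow = TRUE), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("merged fragments reproduce the intact filament", {
  whole <- build_synthetic_superhelix(5, seed = 6)
  d <- whole$domains
  frag1 <- structure_model(whole$atoms[whole$atoms$resno <= d$last[3], ], d[1:3, ])
  frag2 <- structure_model(whole$atoms[whole$atoms$resno >= d$first[3], ], d[3:5, ])
  frag2_moved <- apply_transform(frag2, rot_z(61), c(10, 4, -8))
  placed <- superpose_shared_domain(frag2_moved, frag1, "module_03")
  composite <- merge_models(frag1, placed$transformed)
  expect_equal(nrow(composite$domains), 5)
  expect_equal(domain_centroids(composite), domain_centroids(whole),
               tolerance = 1e-6)
})

test_that("domain centroids behave like centroids", {
  m <- structure_model(
    tibble::tibble(chain = "A", resno = 1:2, atom = "CA", element = "C",
                   x = c(0, 2), y = 0, z = 0),
    tibble::tibble(label = "d", chain = "A", first = 1, last = 2)
  )
  expect_equal(unlist(domain_centroids(m)[1, c("x", "y", "z")]),
               c(x = 1, y = 0, z = 0))
  # rigid equivariance: translating the model translates every centroid
  sh <- build_synthetic_superhelix(4, seed = 5)
  shifted <- apply_transform(sh, diag(3), c(3, -1, 7))
  c0 <- domain_centroids(sh)
  c1 <- domain_centroids(shifted)
  expect_equal(c1$x, c0$x + 3, tolerance = 1e-9)
  expect_equal(c1$y, c0$y - 1, tolerance = 1e-9)
  expect_equal(c1$z, c0$z + 7, tolerance = 1e-9)
  # ten modules give ten labels; merging the central pair gives nine bodies
  st <- synthetic_filament_standin()
  cent10 <- domain_centroids(st)
  expect_equal(nrow(cent10), 10)
  cent9 <- domain_centroids(st, merge = c("module_05", "module_06"))
  expect_equal(nrow(cent9), 9)
})

test_that("neighbor distance stats are exact on collinear equally spaced centroids", {
  cent <- tibble::tibble(label = letters[1:6], x = (0:5) * 7, y = 0, z = 0)
  for (k in 1:3) {
    st <- neighbor_distance_stats(cent, k)
    expect_equal(st$mean, k * 7)
    expect_equal(st$sd, 0)
    expect_equal(st$n_pairs, 6 - k)
  }
  expect_error(neighbor_distance_stats(cent, 6), "at least")
})

test_that("tilt/twist has the documented convention and recovers constructions", {
  sh <- build_synthetic_superhelix(4, rise = 38, twist = 26.5, radius = 10,
                                   seed = 3)
  # identical domain, no motion
  self <- tilt_twist(sh, "module_02", "module_02")
  expect_equal(self$tilt_deg, 0)
  expect_equal(self$twist_deg, 0)
  # copy rotated exactly 30 degrees about its own long axis (z) and
  # translated along it
  d1 <- sh$domains[1, ]
  m1 <- structure_model(sh$atoms[sh$atoms$resno <= d1$last, ], d1)
  copy <- apply_transform(m1, rot_z(30), c(0, 0, 40))
  copy$atoms$resno <- copy$atoms$resno + 100
  both <- structure_model(
    dplyr::bind_rows(m1$atoms, copy$atoms),
    dplyr::bind_rows(d1, tibble::tibble(label = "copy", chain = "A",
                                        first = 101, last = 100 + d1$last))
  )
  tt <- tilt_twist(both, "module_01", "copy")
  expect_equal(tt$twist_deg, 30, tolerance = 1e-4)
  expect_lt(tt$tilt_deg, 0.01)
  # spherical cloud -> degenerate inertia tensor
  set.seed(11)
  sph <- structure_model(
    tibble::tibble(chain = "A", resno = 1:8, atom = "CA", element = "C",
                   x = c(1, -1, 0, 0, 0, 0, 0.5, -0.5),
                   y = c(0, 0, 1, -1, 0, 0, 0.5, -0.5),
                   z = c(0, 0, 0, 0, 1, -1, 0.5, -0.5)),
    tibble::tibble(label = "s", chain = "A", first = 1, last = 8)
  )
  expect_error(tilt_twist(sph, "s", "s"), "degenerate")
})

test_that("the synthetic superhelix matches its closed forms", {
  # n = 1: single module at the helix start
  one <- build_synthetic_superhelix(1, rise = 38, twist = 26.5, radius = 10,
                                    seed = 2)
  expect_equal(nrow(one$domains), 1)
  expect_equal(unlist(domain_centroids(one)[1, c("x", "y", "z")]),
               c(x = 10, y = 0, z = 0), tolerance = 1e-9)
  # consecutive centroid distance equals sqrt(rise^2 + (2 r sin(twist/2))^2)
  sh <- build_synthetic_superhelix(6, rise = 38, twist = 26.5, radius = 10,
                                   seed = 3)
  nd <- neighbor_distance_stats(domain_centroids(sh), 1)
  expect_equal(nd$mean, superhelix_consecutive_distance(38, 26.5, 10),
               tolerance = 1e-9)
  expect_lt(nd$sd, 1e-9)
  # tilt_twist on consecutive modules recovers the input twist within 0.1 deg
  tt <- tilt_twist(sh, "module_02", "module_03")
  expect_lt(abs(tt$twist_deg - 26.5), 0.1)
  expect_lt(tt$tilt_deg, 0.1)
  expect_error(build_synthetic_superhelix(3, radius = -1), "radius")
  expect_error(build_synthetic_superhelix(0), "n_modules")
})

test_that("p(r) matches brute-force enumeration and its scalars are consistent", {
  # two points 10 A apart
  two <- matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)
  dd2 <- pair_distance_distribution(two, bin_width = 2)
  expect_equal(sum(dd2$count), 1)
  expect_equal(dd2$count[dd2$r_lo <= 10 & dd2$r_hi > 10], 1)
  g <- glance(dd2)
  expect_equal(g$dmax, 10)
  expect_equal(g$rg, 5)
  expect_error(pair_distance_distribution(two[1, , drop = FALSE]), "2 points")
  # brute-force double loop oracle on a random 200-point cloud
  set.seed(13)
  pts <- matrix(stats::rnorm(600, sd = 20), 200, 3)
  dd <- pair_distance_distribution(pts, bin_width = 2)
  n <- nrow(pts)
  brute <- numeric(nrow(dd))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      bin <- min(floor(d / 2) + 1, nrow(dd))
      brute[bin] <- brute[bin] + 1
    }
  }
  expect_equal(dd$count, brute)
  expect_equal(sum(dd$count), n * (n - 1) / 2)
  # dmax is at least the last non-empty bin edge; rg <= dmax
  expect_gte(attr(dd, "dmax"), max(dd$r_lo[dd$count > 0]))
  expect_lte(attr(dd, "rg"), attr(dd, "dmax"))
})

test_that("geometry outputs are invariant under global rigid motions", {
  st <- build_synthetic_superhelix(6, rise = 30, twist = 40, radius = 15,
                                   seed = 21)
  for (seed in 1:3) {
    set.seed(seed)
    # random rotation via QR of a Gaussian matrix
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    tvec <- stats::rnorm(3, sd = 30)
    moved <- apply_transform(st, R, tvec)
    nd0 <- neighbor_distance_stats(domain_centroids(st), c(1, 2))
    nd1 <- neighbor_distance_stats(domain_centroids(moved), c(1, 2))
    expect_equal(nd1$mean, nd0$mean, tolerance = 1e-6)
    dd0 <- pair_distance_distribution(st, 2)
    dd1 <- pair_distance_distribution(moved, 2)
    expect_equal(dd1$count, dd0$count)
    expect_equal(attr(dd1, "rg"), attr(dd0, "rg"), tolerance = 1e-6)
    expect_equal(attr(dd1, "dmax"), attr(dd0, "dmax"), tolerance = 1e-6)
    t0 <- tilt_twist(st, "module_02", "module_03")
    t1 <- tilt_twist(moved, "module_02", "module_03")
    expect_lt(abs(t1$tilt_deg - t0$tilt_deg), 1e-6)
    expect_lt(abs(t1$twist_deg - t0$twist_deg), 1e-6)
    expect_lt(abs(t1$centroid_distance - t0$centroid_distance), 1e-6)
  }
})
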