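test_that("ray sampling is Gaussian in the transverse plane and reproducible", {
  a <- angles_to_direction(-21, 21)
  beam <- beam_profile(waist_um = 200, centre_x_um = 189, centre_y_um = 189)
  r1 <- sample_rays(beam, a, 5000, seed = 4)
  r2 <- sample_rays(beam, a, 5000, seed = 4)
  expect_identical(r1$support, r2$support)
  r3 <- sample_rays(beam, a, 5000, seed = 5)
  expect_false(identical(r1$support, r3$support))
  # supports are perpendicular to the shared direction
  expect_lt(max(abs(r1$support %*% a)), 1e-9)
  # the beam axis crosses z = 0 at the requested centre: the projected
  # cloud is centred there, sd waist/2 per transverse axis
  u0 <- -r1$support[, 3] / a[3]
  x0 <- r1$support[, 1] + u0 * a[1]
  y0 <- r1$support[, 2] + u0 * a[2]
  expect_equal(mean(x0), 189, tolerance = 5)
  expect_equal(mean(y0), 189, tolerance = 5)
  # transverse (not projected) spread straight from the support cloud
  sds <- sqrt(eigen(stats::cov(r1$support))$values[1:2])
  expect_equal(sds, c(100, 100), tolerance = 5)
  # sampling does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(sample_rays(beam, a, 10, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("ray-mirror intersections are exact on flat and tilted devices", {
  geom <- dmd_geometry(nx = 4, ny = 4)
  pat0 <- make_pattern(geom, "all_minus")
  a <- c(0, 0, 1)
  # flat device: aim at the centre of mirror (1,1)
  flat <- dmd_geometry(pitch_um = 7.56, mirror_um = 7.56, tilt_deg = 1e-9,
                       nx = 4, ny = 4)
  centre <- c(1.5 * 7.56, 1.5 * 7.56, 0)
  rays <- list(support = matrix(centre - sum(centre * a) * a, 1, 3),
               direction = a)
  hit <- intersect_rays(rays, flat, pat0)
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$mx, hit$my), c(1, 1))
  expect_equal(c(hit$s, hit$t), c(7.56 / 2, 7.56 / 2), tolerance = 1e-6)
  # a ray aimed outside the array footprint misses
  far <- c(100, 100, 0)
  miss <- intersect_rays(list(support = matrix(far - sum(far * a) * a, 1, 3),
                              direction = a), geom, pat0)
  expect_equal(nrow(miss), 0)
})

test_that("hit points satisfy the tilted mirror-plane equation", {
  geom <- dmd_geometry()
  pat <- make_pattern(geom, "checkerboard", period = 5)
  a <- angles_to_direction(-21, 21)
  beam <- beam_profile(300, 189, 189)
  bundle <- sample_rays(beam, a, 10000, seed = 8)
  hits <- intersect_rays(bundle, geom, pat)
  expect_gt(nrow(hits), 3000)
  gam <- ifelse(unclass(pat)[cbind(hits$mx + 1, hits$my + 1)] == 1L,
                geom$tilt_deg, -geom$tilt_deg)
  resid <- numeric(nrow(hits))
  onmirror <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    p_model <- mirror_surface_point(geom, hits$mx[i], hits$my[i], gam[i],
                                    hits$s[i], hits$t[i])
    resid[i] <- max(abs(p_model - c(hits$x[i], hits$y[i], hits$z[i])))
    onmirror[i] <- all(c(hits$s[i], hits$t[i]) >= 0) &&
      all(c(hits$s[i], hits$t[i]) <= geom$mirror_um)
  }
  expect_lt(max(resid), 1e-9)
  expect_true(all(onmirror))
  # every hit lands on a distinct lattice cell consistent with its indices
  expect_true(all(hits$mx >= 0 & hits$mx < 50 & hits$my >= 0 & hits$my < 50))
})

test_that("ray-traced fields obey the coherent-sum bounds", {
  geom <- dmd_geometry(nx = 10, ny = 10, tilt_deg = 1e-9)
  pat <- make_pattern(geom, "all_minus")
  grid <- angular_grid(c(-10, 22), c(-22, 10), step = 2)
  # single ray: unit modulus everywhere
  f1 <- raytrace_field(geom, pat, c(-10, 10), grid, 0.532,
                       beam = beam_profile(1e-6, 37.8, 37.8), rays = 1,
                       seed = 1)
  expect_equal(Mod(f1$values), matrix(1, nrow(f1$values), ncol(f1$values)),
               tolerance = 1e-12)
  # K rays on an effectively flat device: all phasors align exactly at the
  # specular direction (the zero order), and nowhere exceed the ray count
  fK <- raytrace_field(geom, pat, c(-10, 10), grid, 0.532,
                       beam = beam_profile(40, 37.8, 37.8), rays = 500,
                       seed = 2)
  K_hit <- fK$meta$hits
  expect_gt(K_hit, 0)
  amp <- Mod(fK$values)
  expect_lte(max(amp), K_hit * (1 + 1e-12))
  spec <- amp[grid$phi_deg == 10, grid$theta_deg == -10]
  expect_equal(spec, K_hit, tolerance = 1e-9)
  # seed determinism of the full field
  fK2 <- raytrace_field(geom, pat, c(-10, 10), grid, 0.532,
                        beam = beam_profile(40, 37.8, 37.8), rays = 500,
                        seed = 2)
  expect_identical(fK$values, fK2$values)
})

test_that("Monte-Carlo maps agree with the analytic approach where it counts", {
  setup <- default_fig_setup()
  geom <- setup$geom
  pat <- make_pattern(geom, "all_minus")
  grid <- angular_grid(c(-15, 15), c(-15, 15), step = 0.25)
  Ia <- intensity(analytic_dmd_field(geom, pat, setup$incidence, grid,
                                     setup$wavelength_um))
  rt <- raytrace_field(geom, pat, setup$incidence, grid, setup$wavelength_um,
                       rays = 40000, seed = 6)
  Ir <- intensity(rt)
  # peak positions coincide within one grid step
  pk_a <- dmdsim:::find_peaks(Ia, 0.5)
  pk_r <- dmdsim:::find_peaks(Ir, 0.5)
  expect_equal(nrow(pk_a), nrow(pk_r))
  for (i in seq_len(nrow(pk_a))) {
    dd <- abs(pk_r - matrix(pk_a[i, ], nrow(pk_r), 2, byrow = TRUE))
    expect_lte(min(pmax(dd[, 1], dd[, 2])), 1)
  }
  # doubling K keeps the peak put and lowers the relative noise floor
  rt2 <- raytrace_field(geom, pat, setup$incidence, grid, setup$wavelength_um,
                        rays = 80000, seed = 6)
  Ir2 <- intensity(rt2)
  expect_equal(which.max(Ir2), which.max(Ir))
  noise1 <- stats::median(Ir) / max(Ir)
  noise2 <- stats::median(Ir2) / max(Ir2)
  expect_lt(noise2, noise1)
})
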