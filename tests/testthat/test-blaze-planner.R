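test_that("diagonal-plane angle mapping matches the 3-D projection", {
  expect_equal(diagonal_angle(0), 0)
  expect_equal(diagonal_angle(-21), -28.49602, tolerance = 1e-5)
  set.seed(13)
  phis <- runif(50, -80, 80)
  expect_equal(diagonal_angle_inverse(diagonal_angle(phis)), phis,
               tolerance = 1e-12)
  # the 2-D definition agrees with projecting the anti-diagonal direction
  # a(phi, -phi) onto the diagonal axis k = (1,-1,0)/sqrt(2)
  k <- c(1, -1, 0) / sqrt(2)
  for (phi in phis) {
    a <- angles_to_direction(phi, -phi)
    alpha3d <- atan2(sum(a * k), a[3]) * 180 / pi
    expect_equal(diagonal_angle(phi), alpha3d, tolerance = 1e-12)
  }
})

test_that("the half-angle identity underpinning the solver holds", {
  set.seed(17)
  al <- runif(1000, -pi, pi); g <- runif(1000, -pi / 2, pi / 2)
  expect_equal(sin(al) + sin(2 * g - al), 2 * sin(g) * cos(al - g),
               tolerance = 1e-12)
})

test_that("the diagonal lattice constant is pitch/sqrt(2), not pitch/2", {
  # the printed -40.6/16.6 deg solution for n = -4, 488 nm, gamma = -12 only
  # reproduces with m' = m/sqrt(2); the halved constant is off by > 10 deg
  cfg_sqrt2 <- diagonal_config(7.56)
  expect_equal(cfg_sqrt2$m_prime_um, 7.56 / sqrt(2), tolerance = 1e-12)
  sol <- solve_blaze_incidence(-4, -12, 488, cfg_sqrt2)
  alpha <- min(sol$alpha_deg)
  expect_equal(alpha, -40.6, tolerance = 0.05)
  expect_equal(-alpha + 2 * (-12), 16.6, tolerance = 0.05)

  cfg_half <- diagonal_config(7.56 * sqrt(2) / 2) # yields m' = 7.56/2
  sol_half <- solve_blaze_incidence(-4, -12, 488, cfg_half)
  expect_true(nrow(sol_half) == 0 || min(abs(sol_half$alpha_deg - (-40.6))) > 10)
})

test_that("envelope-centre orders scale and anchor as expected", {
  cfg <- diagonal_config()
  # alpha = -40.58 deg hits order -4 at 488 nm to a few thousandths
  expect_equal(blaze_order_real(-40.58, -12, 488, cfg), -4, tolerance = 5e-3)
  # retro-blaze: alpha = gamma gives n = (m'/lambda) 2 sin gamma
  g <- -12
  expect_equal(blaze_order_real(g, g, 532, cfg),
               cfg$m_prime_um * 1000 / 532 * 2 * sin(g * pi / 180),
               tolerance = 1e-12)
  # doubling the wavelength halves the order exactly
  n1 <- blaze_order_real(-25, -12, 400, cfg)
  n2 <- blaze_order_real(-25, -12, 800, cfg)
  expect_equal(n1, 2 * n2, tolerance = 1e-12)
})

test_that("the blaze metric vanishes on integers and is symmetric", {
  cfg <- diagonal_config()
  sol <- solve_blaze_incidence(-4, -12, 488, cfg)
  expect_equal(sol$v, rep(0, nrow(sol)), tolerance = 1e-9)
  # half-integer deviation maximizes v; deviations are sign-symmetric
  al <- min(solve_blaze_incidence(-4, -12, 488, cfg)$alpha_deg)
  n0 <- blaze_order_real(al, -12, 488, cfg) # exactly -4 by construction
  lam_half <- 488 * n0 / (n0 + 0.5) # order n is proportional to 1/lambda
  expect_equal(blaze_metric(al, -12, lam_half, cfg), 1, tolerance = 1e-9)
  eps <- 0.1
  lam_p <- 488 * n0 / (n0 + eps); lam_m <- 488 * n0 / (n0 - eps)
  expect_equal(blaze_metric(al, -12, lam_p, cfg),
               blaze_metric(al, -12, lam_m, cfg), tolerance = 1e-9)
})

test_that("blaze solutions are self-consistent and branch-symmetric", {
  cfg <- diagonal_config()
  set.seed(23)
  checked <- 0
  for (i in 1:50) {
    n <- sample(c(-6:-1, 1:6), 1)
    g <- runif(1, -20, 20)
    lam <- runif(1, 380, 700)
    sol <- solve_blaze_incidence(n, g, lam, cfg)
    if (nrow(sol) == 0) next
    for (j in seq_len(nrow(sol))) {
      expect_equal(blaze_order_real(sol$alpha_deg[j], g, lam, cfg), n,
                   tolerance = 1e-9)
      expect_equal(sol$beta_deg[j], -sol$alpha_deg[j] + 2 * g,
                   tolerance = 1e-12)
      # grating equation in length units
      expect_equal(n * lam,
                   cfg$m_prime_um * 1000 *
                     (sin(sol$alpha_deg[j] * pi / 180) +
                      sin(sol$beta_deg[j] * pi / 180)),
                   tolerance = 1e-9)
    }
    # the two branches exchange alpha and beta
    if (nrow(sol) == 2) {
      expect_equal(sol$alpha_deg[1], sol$beta_deg[2], tolerance = 1e-9)
      expect_equal(sol$alpha_deg[2], sol$beta_deg[1], tolerance = 1e-9)
    }
    checked <- checked + 1
  }
  expect_gte(checked, 20)
  # unsatisfiable condition returns an empty frame with a message
  expect_message(out <- solve_blaze_incidence(-40, -12, 488, cfg),
                 "unsatisfiable")
  expect_equal(nrow(out), 0)
})

test_that("the three-colour design reproduces the published wavelengths", {
  plan <- plan_three_colours(488, -4, -3, 4)
  expect_equal(plan$lambda2_nm, 650.67, tolerance = 0.01)
  expect_equal(plan$alpha12_deg, -40.6, tolerance = 0.05)
  expect_equal(plan$beta_deg, 16.6, tolerance = 0.05)
  expect_equal(plan$alpha3_deg, -plan$beta_deg + 24, tolerance = 1e-12)
  expect_equal(plan$lambda3_nm, 553.93, tolerance = 0.2)
  # wavelength pairing identities
  expect_equal(second_wavelength(650.67, -3, -4), 488, tolerance = 0.01)
  expect_equal(second_wavelength(532, 5, 5), 532)
  expect_error(second_wavelength(488, -4, 0), "non-zero")
  # third colour round trip: its blazed order is exactly n3
  third <- third_wavelength(plan$beta_deg, 12, 4)
  expect_equal(blaze_order_real(third$alpha3_deg, 12, third$lambda3_nm), 4,
               tolerance = 1e-9)
})

test_that("diagonal scans locate shared-incidence wavelength pairs", {
  cfg <- diagonal_config()
  sc <- diagonal_scan(cfg, -12, lambda_nm = c(400, 700), alpha_deg = c(-60, 0),
                      lambda_step = 2, alpha_step = 0.5)
  # the blaze locus through (488 nm, -40.6 deg) also passes 650.67 nm at the
  # same incidence: v is tiny at both grid points nearest those coordinates
  ia <- which.min(abs(sc$alpha_deg - (-40.58)))
  i488 <- which.min(abs(sc$lambda_nm - 488))
  i651 <- which.min(abs(sc$lambda_nm - 650.67))
  expect_lt(sc$v[i488, ia], 0.1)
  expect_lt(sc$v[i651, ia], 0.1)
  # at fixed alpha the locus wavelengths are lambda = m'(sin a + sin b)/n:
  # consecutive loci correspond to consecutive integers n
  # n * lambda is the fixed path difference at this alpha
  ns <- sc$n_real[, ia]
  expect_equal(ns * sc$lambda_nm, rep(ns[1] * sc$lambda_nm[1], length(ns)),
               tolerance = 1e-9)
  # cross-check with the grating-approach displacement along the diagonal
  geom <- dmd_geometry()
  coarse_l <- seq(420, 680, by = 20)
  for (lam in coarse_l[c(2, 7, 12)]) {
    va <- abs(sin(pi * sc$n_real[which.min(abs(sc$lambda_nm - lam)), ]))
    amin <- sc$alpha_deg[which.min(va)]
    phi <- diagonal_angle_inverse(amin)
    d <- displacement(c(phi, -phi), geom, lam / 1000, "minus")
    expect_lt(d$displacement_deg, 0.25) # a v-zero is a displacement zero
  }
})
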