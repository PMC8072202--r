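# Independent oracles used across the suite. These deliberately avoid the
# package's closed forms: the quadrature oracle integrates the raw phase
# factor over the mirror, the lattice oracle sums phasors mirror by mirror.

# 2-D Gauss-Legendre quadrature of the single-mirror diffraction integral
quadrature_single_mirror <- function(a, b, gamma_deg, w_um, wavelength_um,
                                     n = 64) {
  k0 <- 2 * pi / wavelength_um
  R <- dmdsim::rotation_matrix(gamma_deg)
  u <- a + b
  f_re <- function(s, t) {
    d1 <- R[1, 1] * s + R[1, 2] * t
    d2 <- R[2, 1] * s + R[2, 2] * t
    d3 <- R[3, 1] * s + R[3, 2] * t
    cos(k0 * (d1 * u[1] + d2 * u[2] + d3 * u[3]))
  }
  f_im <- function(s, t) {
    d1 <- R[1, 1] * s + R[1, 2] * t
    d2 <- R[2, 1] * s + R[2, 2] * t
    d3 <- R[3, 1] * s + R[3, 2] * t
    sin(k0 * (d1 * u[1] + d2 * u[2] + d3 * u[3]))
  }
  pracma::quad2d(f_re, 0, w_um, 0, w_um, n = n) +
    1i * pracma::quad2d(f_im, 0, w_um, 0, w_um, n = n)
}

# explicit phasor sum over the full mirror lattice
bruteforce_lattice_sum <- function(geom, a, b, wavelength_um) {
  k0 <- 2 * pi / wavelength_um
  u <- a + b
  s <- 0
  for (mx in 0:(geom$nx - 1)) for (my in 0:(geom$ny - 1)) {
    s <- s + exp(1i * k0 * geom$pitch_um * (mx * u[1] + my * u[2]))
  }
  s
}

# dense-grid argmax of the grating intensity inside a window, as an
# independent check on the analytic brightest-order search
densegrid_brightest <- function(geom, incidence, wavelength_um, tilt_sign,
                                window_deg, step = 0.02) {
  grid <- dmdsim::angular_grid(window_deg$phi, window_deg$theta, step)
  gi <- dmdsim::grating_intensity(geom, incidence, grid, wavelength_um, tilt_sign)
  z <- dmdsim::intensity(gi)
  ij <- which(z == max(z), arr.ind = TRUE)[1, ]
  c(phi_deg = grid$phi_deg[ij[1]], theta_deg = grid$theta_deg[ij[2]])
}

default_fig_setup <- function() {
  list(geom = dmdsim::dmd_geometry(),
       incidence = c(-21, 21),
       wavelength_um = 0.532)
}
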