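#' Native-grating lattice factor (Dirichlet closed form)
#'
#' Coherent sum of the lattice phase factors over the full nx x ny mirror
#' grid, evaluated in closed form as the product of two Dirichlet
#' kernels:
#' `D_N(xi) = exp(i (N-1) xi / 2) * sin(N xi / 2) / sin(xi / 2)`,
#' with `xi = k * pitch * (a + b) . e` for e in {x, y}. At the removable
#' singularities (xi a multiple of 2*pi, i.e. exactly on a native
#' diffraction order) the kernel equals N, so the modulus peaks at
#' nx * ny.
#'
#' @param geom A [dmd_geometry()].
#' @param a Incidence direction (length-3 unit vector).
#' @param b Diffraction direction(s): length-3 vector or n x 3 matrix.
#' @param wavelength_um Wavelength in micrometres.
#' @return Complex scalar or length-n vector (dimensionless).
#' @export
grating_factor <- function(geom, a, b, wavelength_um) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  k0 <- 2 * pi / wavelength_um
  xix <- k0 * geom$pitch_um * (a[1] + b[, 1])
  xiy <- k0 * geom$pitch_um * (a[2] + b[, 2])
  drop(dirichlet_kernel(xix, geom$nx) * dirichlet_kernel(xiy, geom$ny))
}

dirichlet_kernel <- function(xi, N) {
  s <- sin(xi / 2)
  # L'Hopital limit at the grating orders, where s -> 0
  ratio <- ifelse(abs(s) < 1e-9, N * cos(N * xi / 2) / cos(xi / 2),
                  sin(N * xi / 2) / s)
  complex(modulus = 1, argument = (N - 1) * xi / 2) * ratio
}

#' Intensity map by the envelope-times-grating factorization
#'
#' For a uniformly tilted device under uniform illumination the far-field
#' intensity factorizes into the single-mirror envelope times the native
#' grating comb: `I = |E_single|^2 * |E_grating|^2`. This is the fastest
#' of the field approaches but cannot represent displayed patterns.
#'
#' @param geom A [dmd_geometry()].
#' @param incidence Length-2 numeric `c(phi_a, theta_a)` in degrees.
#' @param grid An [angular_grid()].
#' @param wavelength_um Wavelength in micrometres.
#' @param tilt_sign `"minus"` (gamma = -tilt_deg) or `"plus"`.
#' @return A [field_map()] holding the real intensity.
#' @export
grating_intensity <- function(geom, incidence, grid, wavelength_um,
                              tilt_sign = c("minus", "plus")) {
  tilt_sign <- match.arg(tilt_sign)
  gamma <- if (tilt_sign == "minus") -geom$tilt_deg else geom$tilt_deg
  a <- angles_to_direction(incidence[1], incidence[2])
  B <- grid_directions(grid)
  env <- Mod(single_mirror_field(a, B, gamma, geom$mirror_um, wavelength_um))^2
  grat <- Mod(grating_factor(geom, a, B, wavelength_um))^2
  field_map(matrix(env * grat, length(grid$phi_deg), length(grid$theta_deg)),
            grid, wavelength_um,
            meta = list(approach = "grating", incidence = incidence,
                        tilt_sign = tilt_sign))
}

#' Centre of the single-mirror envelope (specular reflection)
#'
#' The envelope of the diffraction pattern is centred on the specular
#' reflection of the incident light off a single tilted mirror surface:
#' `b = 2 (a . nu) nu - a` with mirror normal `nu = R(gamma) z`. For
#' incidence and tilt in the device diagonal this reduces to the
#' one-dimensional reflection law `beta = -alpha + 2*gamma`.
#'
#' @param a Incidence direction (length-3 unit vector).
#' @param gamma_deg Mirror tilt in degrees.
#' @return Length-3 unit direction. A result with z <= 0 means the
#'   reflection leaves the observable hemisphere; callers should treat it
#'   as out of range.
#' @export
envelope_centre <- function(a, gamma_deg) {
  nu <- drop(rotation_matrix(gamma_deg) %*% c(0, 0, 1))
  drop(2 * sum(a * nu) * nu - a)
}

#' Native diffraction orders of the mirror lattice
#'
#' Enumerates all integer orders (px, py) of the 2-D grating equation
#' `(a + b) . x = px * lambda / pitch`, `(a + b) . y = py * lambda / pitch`
#' whose diffraction direction exists (transverse components inside the
#' unit disc, z > 0), optionally restricted to an angular window. The
#' (0, 0) order is the specular partner `(-ax, -ay, az)` of the
#' incidence direction.
#'
#' @param a Incidence direction (length-3 unit vector).
#' @param geom A [dmd_geometry()].
#' @param wavelength_um Wavelength in micrometres.
#' @param window Optional list with `phi` and `theta` length-2 degree
#'   ranges; `NULL` keeps the whole hemisphere.
#' @return A data.frame with columns px, py, bx, by, bz, phi_deg,
#'   theta_deg.
#' @export
native_orders_near <- function(a, geom, wavelength_um, window = NULL) {
  q <- wavelength_um / geom$pitch_um      # order spacing in direction cosines
  px <- seq(ceiling((a[1] - 1) / q), floor((a[1] + 1) / q))
  py <- seq(ceiling((a[2] - 1) / q), floor((a[2] + 1) / q))
  ords <- expand.grid(px = px, py = py)
  bx <- ords$px * q - a[1]
  by <- ords$py * q - a[2]
  r2 <- bx^2 + by^2
  keep <- r2 < 1
  ords <- ords[keep, , drop = FALSE]
  bx <- bx[keep]; by <- by[keep]
  bz <- sqrt(1 - bx^2 - by^2)
  out <- data.frame(px = ords$px, py = ords$py, bx = bx, by = by, bz = bz,
                    phi_deg = rad2deg(atan(bx / bz)),
                    theta_deg = rad2deg(atan(by / bz)))
  if (!is.null(window)) {
    out <- out[out$phi_deg >= window$phi[1] & out$phi_deg <= window$phi[2] &
               out$theta_deg >= window$theta[1] & out$theta_deg <= window$theta[2], ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Envelope-to-brightest-order displacement
#'
#' Angular distance (great circle, degrees) between the envelope centre
#' (specular reflection off a tilted mirror) and the native grating order
#' carrying the highest envelope intensity. The grating factor peaks with
#' equal modulus nx * ny at every order, so the envelope alone decides
#' which order is brightest. A displacement of 0 means the blaze
#' (Littrow-type) condition is fulfilled: one order sits exactly at the
#' envelope centre and dominates the diffracted light.
#'
#' @param incidence Length-2 numeric `c(phi_a, theta_a)` in degrees.
#' @param geom A [dmd_geometry()].
#' @param wavelength_um Wavelength in micrometres.
#' @param tilt_sign `"minus"` or `"plus"`.
#' @return List with `displacement_deg`, `envelope_centre` (direction),
#'   `order` (one-row data.frame as in [native_orders_near()]).
#' @export
displacement <- function(incidence, geom, wavelength_um,
                         tilt_sign = c("minus", "plus")) {
  tilt_sign <- match.arg(tilt_sign)
  gamma <- if (tilt_sign == "minus") -geom$tilt_deg else geom$tilt_deg
  a <- angles_to_direction(incidence[1], incidence[2])
  bE <- envelope_centre(a, gamma)
  if (bE[3] <= 0)
    stop("envelope centre lies outside the observable hemisphere")
  ords <- native_orders_near(a, geom, wavelength_um)
  if (nrow(ords) == 0L) stop("no native order within the hemisphere")
  Bo <- as.matrix(ords[, c("bx", "by", "bz")])
  env <- Mod(single_mirror_field(a, Bo, gamma, geom$mirror_um, wavelength_um))^2
  best <- which.max(env)
  dotp <- min(1, max(-1, sum(bE * Bo[best, ])))
  list(displacement_deg = rad2deg(acos(dotp)),
       envelope_centre = bE,
       order = ords[best, , drop = FALSE])
}

#' Displacement over a grid of incidence angles
#'
#' Evaluates [displacement()] on a regular grid of incidence angles.
#' Near-zero bands of the resulting map locate blaze-compatible
#' incidence-angle sets. Entries where the envelope centre leaves the
#' hemisphere are NA.
#'
#' @param geom A [dmd_geometry()].
#' @param wavelength_um Wavelength in micrometres.
#' @param incidence_range Length-2 range in degrees applied to both
#'   phi_a and theta_a.
#' @param step Incidence sampling step in degrees.
#' @param tilt_sign `"minus"` or `"plus"`.
#' @return A list with `phi_deg`, `theta_deg` axis vectors and a
#'   `displacement_deg` matrix (rows phi_a, columns theta_a).
#' @export
displacement_map <- function(geom, wavelength_um,
                             incidence_range = c(-60, 60), step = 0.2,
                             tilt_sign = c("minus", "plus")) {
  tilt_sign <- match.arg(tilt_sign)
  if (step <= 0) stop("step must be > 0")
  phis <- seq(incidence_range[1], incidence_range[2], by = step)
  thetas <- phis
  M <- matrix(NA_real_, length(phis), length(thetas))
  for (j in seq_along(thetas)) for (i in seq_along(phis)) {
    d <- tryCatch(
      displacement(c(phis[i], thetas[j]), geom, wavelength_um, tilt_sign),
      error = function(e) NULL)
    if (!is.null(d)) M[i, j] <- d$displacement_deg
  }
  list(phi_deg = phis, theta_deg = thetas, displacement_deg = M)
}
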