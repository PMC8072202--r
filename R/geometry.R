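#' DMD device geometry
#'
#' Describes the micromirror array: lattice pitch, mirror edge length, tilt
#' magnitude and array size. Mirrors rotate about their diagonal axis
#' (1,1,0)/sqrt(2) between the two steady tilt states -tilt_deg and
#' +tilt_deg. The gap between adjacent mirrors is `pitch_um - mirror_um`.
#'
#' Defaults correspond to the DLP LightCrafter 6500 class of devices
#' (7.56 um pitch, +/-12 deg tilt) with a 50 x 50 sub-array, the
#' configuration used throughout the package examples.
#'
#' @param pitch_um Micromirror pitch m in micrometres.
#' @param mirror_um Mirror edge length w in micrometres (w <= m).
#' @param tilt_deg Magnitude of the tilt angle gamma in degrees
#'   (0 < tilt_deg < 90).
#' @param nx,ny Number of mirrors along x and y.
#' @return An object of class `dmd_geometry` with fields `pitch_um`,
#'   `mirror_um`, `tilt_deg`, `nx`, `ny` and derived `gap_um`.
#' @examples
#' geom <- dmd_geometry()
#' geom$gap_um # 0 for the default device
#' @export
dmd_geometry <- function(pitch_um = 7.56, mirror_um = 7.56, tilt_deg = 12,
                         nx = 50, ny = 50) {
  stopifnot(is.numeric(pitch_um), length(pitch_um) == 1L, pitch_um > 0)
  if (!(mirror_um > 0 && mirror_um <= pitch_um))
    stop("mirror_um must satisfy 0 < mirror_um <= pitch_um")
  if (!(tilt_deg > 0 && tilt_deg < 90))
    stop("tilt_deg must lie strictly between 0 and 90 degrees")
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("nx and ny must be >= 1")
  structure(
    list(pitch_um = pitch_um, mirror_um = mirror_um, tilt_deg = tilt_deg,
         nx = nx, ny = ny, gap_um = pitch_um - mirror_um),
    class = "dmd_geometry"
  )
}

#' @export
print.dmd_geometry <- function(x, ...) {
  cat(sprintf(
    "DMD geometry: %d x %d mirrors, pitch %.3f um, mirror %.3f um (gap %.3f um), tilt +/-%g deg\n",
    x$nx, x$ny, x$pitch_um, x$mirror_um, x$gap_um, x$tilt_deg))
  invisible(x)
}

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

#' Convert angle coordinates to a unit direction vector
#'
#' Directions toward the source or the observer are parameterized by the
#' angle pair (phi, theta): the direction vector is
#' `(z * tan(phi), z * tan(theta), z)` with
#' `z = 1 / sqrt(tan(phi)^2 + tan(theta)^2 + 1)`, so phi tilts the
#' direction in the x-z plane and theta in the y-z plane. Both incidence
#' and diffraction directions live in the z > 0 hemisphere.
#'
#' Vectorized over `phi_deg`/`theta_deg` (recycled to a common length).
#'
#' @param phi_deg,theta_deg Angles in degrees, strictly inside (-90, 90).
#' @return A numeric vector of length 3 (single input) or an n x 3 matrix
#'   with columns x, y, z; each row has unit norm and z > 0.
#' @examples
#' angles_to_direction(0, 0)      # (0, 0, 1)
#' angles_to_direction(45, 45)    # (1, 1, 1)/sqrt(3)
#' @export
angles_to_direction <- function(phi_deg, theta_deg) {
  n <- max(length(phi_deg), length(theta_deg))
  phi_deg <- rep_len(phi_deg, n); theta_deg <- rep_len(theta_deg, n)
  if (any(abs(phi_deg) >= 90) || any(abs(theta_deg) >= 90))
    stop("angles must lie strictly inside (-90, 90) degrees")
  tp <- tan(deg2rad(phi_deg)); tt <- tan(deg2rad(theta_deg))
  z <- 1 / sqrt(tp^2 + tt^2 + 1)
  out <- cbind(x = z * tp, y = z * tt, z = z)
  if (n == 1L) drop(out) else out
}

#' Convert a unit direction vector back to angle coordinates
#'
#' Inverse of [angles_to_direction()]: `phi = atan(x / z)`,
#' `theta = atan(y / z)`. Requires z > 0.
#'
#' @param v Numeric length-3 vector or n x 3 matrix of directions.
#' @return Named vector `c(phi_deg, theta_deg)` or an n x 2 matrix.
#' @export
direction_to_angles <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  if (ncol(v) != 3L) stop("directions must have 3 components")
  if (any(v[, 3] <= 0)) stop("direction must have z > 0")
  out <- cbind(phi_deg = rad2deg(atan(v[, 1] / v[, 3])),
               theta_deg = rad2deg(atan(v[, 2] / v[, 3])))
  if (nrow(out) == 1L) drop(out) else out
}

#' Rotation matrix about the mirror diagonal axis
#'
#' Proper rotation by `gamma_deg` about the normalized diagonal axis
#' (1, 1, 0)/sqrt(2), the hinge axis shared by all micromirrors.
#'
#' @param gamma_deg Rotation angle in degrees.
#' @return A 3 x 3 orthogonal matrix with determinant +1.
#' @export
rotation_matrix <- function(gamma_deg) {
  g <- deg2rad(gamma_deg)
  n <- c(1, 1, 0) / sqrt(2)
  cg <- cos(g); sg <- sin(g)
  # axis-angle (Rodrigues) form written out for the fixed axis
  matrix(c(
    n[1]^2 * (1 - cg) + cg,        n[1] * n[2] * (1 - cg) - n[3] * sg, n[1] * n[3] * (1 - cg) + n[2] * sg,
    n[2] * n[1] * (1 - cg) + n[3] * sg, n[2]^2 * (1 - cg) + cg,        n[2] * n[3] * (1 - cg) - n[1] * sg,
    n[3] * n[1] * (1 - cg) - n[2] * sg, n[3] * n[2] * (1 - cg) + n[1] * sg, n[3]^2 * (1 - cg) + cg
  ), nrow = 3L, byrow = TRUE)
}

#' Point on a tilted mirror surface
#'
#' Returns the lab-frame position of the point with local on-mirror
#' coordinates (s, t) on mirror (mx, my):
#' `R(gamma) %*% c(s, t, 0) + pitch * c(mx, my, 0)`. Mirror indices are
#' 0-based; the rotation axis passes through the mirror's own (s=0, t=0)
#' corner. For gamma = 0 all points lie in the z = 0 plane.
#'
#' @param geom A [dmd_geometry()].
#' @param mx,my 0-based mirror indices.
#' @param gamma_deg Tilt angle of this mirror in degrees.
#' @param s,t On-mirror coordinates in micrometres, in `[0, mirror_um]`.
#' @return Numeric length-3 position in micrometres.
#' @export
mirror_surface_point <- function(geom, mx, my, gamma_deg, s, t) {
  stopifnot(inherits(geom, "dmd_geometry"))
  if (mx < 0 || mx >= geom$nx || my < 0 || my >= geom$ny)
    stop("mirror index out of range")
  if (s < 0 || s > geom$mirror_um || t < 0 || t > geom$mirror_um)
    stop("on-mirror coordinates must lie in [0, mirror_um]")
  drop(rotation_matrix(gamma_deg) %*% c(s, t, 0)) +
    geom$pitch_um * c(mx, my, 0)
}

#' Gaussian beam profile on the device
#'
#' A collimated Gaussian beam described by its 1/e^2 intensity radius
#' (waist) and the point on the z = 0 device plane through which the beam
#' axis passes.
#'
#' @param waist_um 1/e^2 intensity radius in micrometres (> 0).
#' @param centre_x_um,centre_y_um Beam-axis crossing point on the device
#'   plane, micrometres.
#' @return An object of class `beam_profile`.
#' @export
beam_profile <- function(waist_um, centre_x_um = 0, centre_y_um = 0) {
  stopifnot(is.numeric(waist_um), waist_um > 0)
  structure(list(waist_um = waist_um, centre_x_um = centre_x_um,
                 centre_y_um = centre_y_um),
            class = "beam_profile")
}

# default wide beam: ~uniform amplitude across the array (within 2% at
# the corners for a square array), centred on it
default_beam <- function(geom, factor = 5) {
  wx <- geom$nx * geom$pitch_um
  wy <- geom$ny * geom$pitch_um
  beam_profile(waist_um = factor * max(wx, wy),
               centre_x_um = wx / 2, centre_y_um = wy / 2)
}
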