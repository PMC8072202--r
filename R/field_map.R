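#' Angular output grid
#'
#' Regular grid of diffraction directions (phi_b, theta_b) in degrees on
#' which far-field maps are sampled. The default mirrors the package's
#' standard visualization window: -15 to 15 degrees on both axes.
#'
#' @param phi_range,theta_range Length-2 numeric ranges in degrees.
#' @param step Grid step in degrees (> 0), shared by both axes unless
#'   `theta_step` is given.
#' @param theta_step Optional separate step for the theta axis.
#' @return An object of class `angular_grid` with fields `phi_deg`,
#'   `theta_deg` (axis vectors).
#' @export
angular_grid <- function(phi_range = c(-15, 15), theta_range = c(-15, 15),
                         step = 0.1, theta_step = step) {
  if (step <= 0 || theta_step <= 0) stop("grid step must be > 0")
  if (diff(phi_range) < 0 || diff(theta_range) < 0)
    stop("ranges must be non-decreasing")
  structure(list(phi_deg = seq(phi_range[1], phi_range[2], by = step),
                 theta_deg = seq(theta_range[1], theta_range[2], by = theta_step)),
            class = "angular_grid")
}

# all grid directions as an n x 3 matrix, phi fastest (row index of maps)
grid_directions <- function(grid) {
  np <- length(grid$phi_deg); nt <- length(grid$theta_deg)
  phi <- rep(grid$phi_deg, times = nt)
  theta <- rep(grid$theta_deg, each = np)
  angles_to_direction(phi, theta)
}

#' Complex far-field map container
#'
#' Holds a complex far-field amplitude (or a real intensity) sampled on
#' an [angular_grid()]. Matrix rows index phi_b, columns theta_b.
#'
#' @param values Complex or numeric matrix, `length(grid$phi_deg)` x
#'   `length(grid$theta_deg)`.
#' @param grid The [angular_grid()] the values are sampled on.
#' @param wavelength_um Wavelength in micrometres.
#' @param meta Optional named list of provenance (approach, seed, ...).
#' @return An object of class `field_map`.
#' @export
field_map <- function(values, grid, wavelength_um, meta = list()) {
  stopifnot(inherits(grid, "angular_grid"))
  if (!all(dim(values) == c(length(grid$phi_deg), length(grid$theta_deg))))
    stop("values dimensions do not match the angular grid")
  structure(list(values = values, grid = grid,
                 wavelength_um = wavelength_um, meta = meta),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  kind <- if (is.complex(x$values)) "complex amplitude" else "intensity"
  cat(sprintf(
    "far-field %s map: %d x %d (phi %g..%g, theta %g..%g deg), lambda %g um\n",
    kind, nrow(x$values), ncol(x$values),
    min(x$grid$phi_deg), max(x$grid$phi_deg),
    min(x$grid$theta_deg), max(x$grid$theta_deg), x$wavelength_um))
  invisible(x)
}

#' Intensity of a far-field map
#'
#' Squared modulus of a complex amplitude map (or the values themselves
#' if the map already holds an intensity).
#'
#' @param map A [field_map()].
#' @return A numeric matrix of the same dimensions.
#' @export
intensity <- function(map) {
  stopifnot(inherits(map, "field_map"))
  if (is.complex(map$values)) Mod(map$values)^2 else map$values
}

# local maxima of a matrix above a threshold (8-neighbourhood, strict on
# at least one side to tolerate plateaus at borders)
find_peaks <- function(z, frac_of_max = 0.5) {
  nr <- nrow(z); nc <- ncol(z)
  thr <- frac_of_max * max(z)
  inner <- z[2:(nr - 1), 2:(nc - 1)]
  ok <- inner >= thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & inner >= z[2:(nr - 1) + di, 2:(nc - 1) + dj]
  }
  idx <- which(ok, arr.ind = TRUE)
  cbind(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
}
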