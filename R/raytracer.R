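#' Sample Gaussian-distributed incident rays
#'
#' Draws `count` parallel rays along the incidence direction `a`. Each
#' ray is the line `h + u * a` with a support vector h perpendicular to
#' a. Supports are 2-D Gaussian in an orthonormal basis of the plane
#' perpendicular to a, standard deviation `waist_um / 2` per axis (so the
#' ray density reproduces the 1/e^2 intensity profile of the beam),
#' offset so the beam axis crosses the device plane at the beam centre.
#' Fully reproducible for a given seed; the caller's RNG state is left
#' untouched.
#'
#' @param beam A [beam_profile()].
#' @param a Incidence direction (length-3 unit vector, z > 0).
#' @param count Number of rays (>= 1).
#' @param seed Integer seed.
#' @return List of class `ray_bundle` with `support` (count x 3 matrix),
#'   `direction` (the shared a), `seed`.
#' @export
sample_rays <- function(beam, a, count, seed = 1L) {
  stopifnot(inherits(beam, "beam_profile"), count >= 1)
  basis <- perp_basis(a)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sd <- beam$waist_um / 2
  x1 <- stats::rnorm(count, sd = sd)
  x2 <- stats::rnorm(count, sd = sd)
  centre <- c(beam$centre_x_um, beam$centre_y_um, 0)
  c0 <- centre - sum(centre * a) * a              # support of the beam axis
  support <- matrix(c0, count, 3, byrow = TRUE) +
    outer(x1, basis$e1) + outer(x2, basis$e2)
  structure(list(support = support, direction = a, seed = seed),
            class = "ray_bundle")
}

# orthonormal basis of the plane perpendicular to unit vector a
perp_basis <- function(a) {
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2],
          a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Intersect rays with the tilted mirror array
#'
#' For every ray the candidate mirror is found by projecting the ray to
#' the z = 0 plane; the candidate lattice cell and its 8 neighbours are
#' then tested by exact line-plane intersection with each candidate's
#' tilted mirror plane, accepting intersections whose local (s, t)
#' coordinates lie on the mirror. At the tilt angles of real devices the
#' in-plane shift of a mirror footprint is below one pitch, so the
#' one-cell neighbour ring is exhaustive (checked in the test suite).
#' When several candidates accept (possible only at mirror edges), the
#' intersection closest to the source (largest z along the ray) wins.
#' Rays falling in gaps or outside the array are misses.
#'
#' @param rays A `ray_bundle` from [sample_rays()].
#' @param geom A [dmd_geometry()].
#' @param pattern A [tilt_pattern()] matching `geom`.
#' @return A data.frame with one row per hitting ray: `ray` (index into
#'   the bundle), `mx`, `my`, `s`, `t`, `x`, `y`, `z` (the intersection
#'   point in micrometres).
#' @export
intersect_rays <- function(rays, geom, pattern) {
  check_pattern(pattern, geom)
  a <- rays$direction
  if (a[3] <= 0) stop("ray direction must have z > 0")
  H <- rays$support
  K <- nrow(H)
  m <- geom$pitch_um; w <- geom$mirror_um
  gam <- pattern_gamma(pattern, geom)

  # projection to z = 0
  u0 <- -H[, 3] / a[3]
  x0 <- H[, 1] + u0 * a[1]
  y0 <- H[, 2] + u0 * a[2]
  cx <- floor(x0 / m); cy <- floor(y0 / m)

  Rm <- rotation_matrix(-geom$tilt_deg)
  Rp <- rotation_matrix(geom$tilt_deg)
  num <- rep(-Inf, K)                      # best u so far (largest)
  best <- data.frame(mx = rep(NA_integer_, K), my = NA_integer_,
                     s = NA_real_, t = NA_real_,
                     x = NA_real_, y = NA_real_, z = NA_real_)
  for (dx in -1:1) for (dy in -1:1) {
    mx <- cx + dx; my <- cy + dy
    ok <- mx >= 0 & mx < geom$nx & my >= 0 & my < geom$ny
    if (!any(ok)) next
    idx <- which(ok)
    g <- gam[cbind(mx[idx] + 1L, my[idx] + 1L)]
    plus <- g > 0
    for (sign_grp in list(list(sel = !plus, R = Rm), list(sel = plus, R = Rp))) {
      sel <- idx[sign_grp$sel]
      if (length(sel) == 0L) next
      R <- sign_grp$R
      nu <- R[, 3]                          # mirror normal R(gamma) z
      o <- cbind(m * mx[sel], m * my[sel], 0)
      denom <- sum(a * nu)
      uu <- ((o - H[sel, , drop = FALSE]) %*% nu) / denom
      P <- H[sel, , drop = FALSE] + outer(drop(uu), a)
      local <- (P - o) %*% R                # R^T (p - o) = (s, t, ~0)
      acc <- local[, 1] >= 0 & local[, 1] <= w &
             local[, 2] >= 0 & local[, 2] <= w
      if (!any(acc)) next
      sel2 <- sel[acc]
      better <- drop(uu)[acc] > num[sel2]
      sel3 <- sel2[better]
      if (length(sel3) == 0L) next
      num[sel3] <- drop(uu)[acc][better]
      best$mx[sel3] <- mx[sel3]; best$my[sel3] <- my[sel3]
      best$s[sel3] <- local[acc, 1][better]
      best$t[sel3] <- local[acc, 2][better]
      best$x[sel3] <- P[acc, 1][better]
      best$y[sel3] <- P[acc, 2][better]
      best$z[sel3] <- P[acc, 3][better]
    }
  }
  hit <- !is.na(best$mx)
  cbind(ray = which(hit), best[hit, , drop = FALSE])
}

#' Monte-Carlo ray-traced far field
#'
#' Approximates the Fraunhofer diffraction integral by a Monte-Carlo sum
#' over Gaussian-distributed rays: each hitting ray contributes the unit
#' phasor `exp(i k d . (a + b))`, where d is its intersection point with
#' the mirror array (same direction convention as
#' [single_mirror_field()]); misses contribute nothing. The beam profile
#' enters only through the sampling density; every ray carries unit
#' amplitude.
#'
#' @param geom A [dmd_geometry()].
#' @param pattern A [tilt_pattern()] matching `geom`.
#' @param beam A [beam_profile()]; `NULL` uses a wide default beam (waist
#'   5x the array width, centred on the array) giving illumination
#'   uniform to about 2% across the array.
#' @param incidence Length-2 numeric `c(phi_a, theta_a)` in degrees.
#' @param grid An [angular_grid()].
#' @param wavelength_um Wavelength in micrometres.
#' @param rays Number of Monte-Carlo rays K.
#' @param seed Integer seed (recorded in the output metadata).
#' @param block Grid directions per processing chunk (memory control).
#' @return A [field_map()] holding the complex amplitude; `meta$hits`
#'   records how many rays struck the array.
#' @export
raytrace_field <- function(geom, pattern, incidence, grid, wavelength_um,
                           beam = NULL, rays = 100000L, seed = 1L,
                           block = 5000L) {
  stopifnot(inherits(grid, "angular_grid"), wavelength_um > 0)
  if (is.null(beam)) beam <- default_beam(geom)
  a <- angles_to_direction(incidence[1], incidence[2])
  bundle <- sample_rays(beam, a, rays, seed)
  hits <- intersect_rays(bundle, geom, pattern)
  if (nrow(hits) == 0L)
    stop("no ray hit the device; check beam centre/waist and geometry")
  D <- as.matrix(hits[, c("x", "y", "z")])
  k0 <- 2 * pi / wavelength_um
  pa <- k0 * drop(D %*% a)                     # incoming phase per hit
  B <- grid_directions(grid)
  nb <- nrow(B)
  out <- complex(nb)
  for (start in seq(1L, nb, by = block)) {
    idx <- start:min(start + block - 1L, nb)
    ph <- pa + k0 * (D %*% t(B[idx, , drop = FALSE]))   # hits x |idx|
    out[idx] <- colSums(cos(ph)) + 1i * colSums(sin(ph))
  }
  field_map(matrix(out, length(grid$phi_deg), length(grid$theta_deg)),
            grid, wavelength_um,
            meta = list(approach = "raytrace", incidence = incidence,
                        rays = rays, seed = seed, hits = nrow(hits)))
}
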