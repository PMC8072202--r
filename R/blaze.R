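#' Diagonal (45-degree rotated) device configuration
#'
#' When the device is mounted rotated by 45 degrees about z, incidence
#' and diffraction can be restricted to the diagonal perpendicular to the
#' mirror hinge axes. Along that diagonal the mirror lattice acts as a
#' 1-D blazed grating with effective lattice constant
#' `m' = pitch / sqrt(2)`.
#'
#' @param pitch_um Micromirror pitch in micrometres.
#' @param gamma_minus_deg,gamma_plus_deg The two steady tilt states in
#'   degrees.
#' @return An object of class `diagonal_config` with `m_prime_um` and
#'   the two tilt angles.
#' @export
diagonal_config <- function(pitch_um = 7.56, gamma_minus_deg = -12,
                            gamma_plus_deg = 12) {
  stopifnot(pitch_um > 0, abs(gamma_minus_deg) < 90, abs(gamma_plus_deg) < 90)
  structure(list(pitch_um = pitch_um, m_prime_um = pitch_um / sqrt(2),
                 gamma_minus_deg = gamma_minus_deg,
                 gamma_plus_deg = gamma_plus_deg),
            class = "diagonal_config")
}

#' Map a device-frame angle to the diagonal-plane angle
#'
#' For anti-diagonal incidence `(phi, -phi)` the in-plane angle measured
#' in the plane spanned by the diagonal axis k = (1,-1,0)/sqrt(2) and z
#' is `alpha = atan(sqrt(2) * tan(phi))`. Strictly monotone on
#' (-90, 90); [diagonal_angle_inverse()] undoes it.
#'
#' @param phi_deg Device-frame angle in degrees, |phi_deg| < 90.
#' @return Diagonal-plane angle alpha in degrees.
#' @export
diagonal_angle <- function(phi_deg) {
  if (any(abs(phi_deg) >= 90)) stop("|phi_deg| must be < 90")
  rad2deg(atan(sqrt(2) * tan(deg2rad(phi_deg))))
}

#' @rdname diagonal_angle
#' @param alpha_deg Diagonal-plane angle in degrees.
#' @export
diagonal_angle_inverse <- function(alpha_deg) {
  if (any(abs(alpha_deg) >= 90)) stop("|alpha_deg| must be < 90")
  rad2deg(atan(tan(deg2rad(alpha_deg)) / sqrt(2)))
}

#' Real-valued diffraction order of the envelope centre
#'
#' Along the diagonal the grating equation reads
#' `n * lambda = m' * (sin(alpha) + sin(beta))`. With the diffraction
#' direction pinned to the envelope centre `beta = -alpha + 2*gamma`
#' (specular reflection off a tilted mirror), the corresponding order
#' `n = (m' / lambda) * (sin(alpha) + sin(-alpha + 2*gamma))`
#' is generally not an integer; the blaze condition is fulfilled exactly
#' when it is.
#'
#' @param alpha_deg Diagonal incidence angle in degrees.
#' @param gamma_deg Mirror tilt in degrees.
#' @param wavelength_nm Wavelength in nanometres.
#' @param cfg A [diagonal_config()].
#' @return Real-valued order n (vectorized over inputs).
#' @export
blaze_order_real <- function(alpha_deg, gamma_deg, wavelength_nm,
                             cfg = diagonal_config()) {
  if (any(wavelength_nm <= 0)) stop("wavelength must be > 0")
  al <- deg2rad(alpha_deg); g <- deg2rad(gamma_deg)
  (cfg$m_prime_um * 1000 / wavelength_nm) * (sin(al) + sin(-al + 2 * g))
}

#' Blaze metric v = |sin(n pi)|
#'
#' Zero exactly when the blaze condition holds (integer envelope-centre
#' order), one at half-integer orders; symmetric in the sign of the
#' deviation and slightly nonlinear, so small deviations are emphasized.
#'
#' @inheritParams blaze_order_real
#' @return v in [0, 1] (vectorized).
#' @export
blaze_metric <- function(alpha_deg, gamma_deg, wavelength_nm,
                         cfg = diagonal_config()) {
  abs(sin(pi * blaze_order_real(alpha_deg, gamma_deg, wavelength_nm, cfg)))
}

#' Solve the blaze condition for the incidence angle
#'
#' Finds the diagonal incidence angles alpha at which order `order_n` is
#' blazed for the given tilt and wavelength. Using
#' `sin(alpha) + sin(2*gamma - alpha) = 2 sin(gamma) cos(alpha - gamma)`,
#' the closed-form solutions are
#' `alpha = gamma +/- acos(n * lambda / (2 m' sin(gamma)))`; the two
#' branches are exchanged under alpha <-> beta. No solution exists when
#' `|n * lambda| > 2 m' |sin(gamma)|`.
#'
#' @param order_n Integer diffraction order.
#' @param gamma_deg Mirror tilt in degrees.
#' @param wavelength_nm Wavelength in nanometres.
#' @param cfg A [diagonal_config()].
#' @return A data.frame of blaze solutions with columns `order_n`,
#'   `alpha_deg`, `beta_deg`, `wavelength_nm`, `gamma_deg`, `v`,
#'   `beta_feasible` (FALSE when |beta| >= 90 deg, impractical on an
#'   optical table). Zero rows when the condition is unsatisfiable.
#' @examples
#' solve_blaze_incidence(-4, -12, 488) # alpha -40.6 / +16.6 deg branches
#' @export
solve_blaze_incidence <- function(order_n, gamma_deg, wavelength_nm,
                                  cfg = diagonal_config()) {
  stopifnot(order_n == round(order_n), wavelength_nm > 0)
  g <- deg2rad(gamma_deg)
  x <- order_n * (wavelength_nm / 1000) / (2 * cfg$m_prime_um * sin(g))
  if (abs(x) > 1) {
    message(sprintf(
      "blaze condition unsatisfiable: |n lambda| = %.3f um exceeds 2 m' |sin gamma| = %.3f um",
      abs(order_n) * wavelength_nm / 1000,
      abs(2 * cfg$m_prime_um * sin(g))))
    return(data.frame(order_n = integer(), alpha_deg = numeric(),
                      beta_deg = numeric(), wavelength_nm = numeric(),
                      gamma_deg = numeric(), v = numeric(),
                      beta_feasible = logical()))
  }
  dal <- acos(x)
  alphas <- rad2deg(g + c(-1, 1) * dal)
  if (dal == 0) alphas <- alphas[1]            # degenerate branch merge
  betas <- -alphas + 2 * gamma_deg
  data.frame(order_n = order_n, alpha_deg = alphas, beta_deg = betas,
             wavelength_nm = wavelength_nm, gamma_deg = gamma_deg,
             v = blaze_metric(alphas, gamma_deg, wavelength_nm, cfg),
             beta_feasible = abs(betas) < 90)
}

#' Second wavelength sharing a blazed incidence
#'
#' Two wavelengths can share one incidence angle, diffraction angle and
#' tilt state if their blazed orders satisfy `n1 * lambda1 = n2 * lambda2`.
#'
#' @param lambda1_nm First wavelength in nanometres.
#' @param n1,n2 Integer orders (n2 != 0).
#' @return `lambda2_nm = (n1 / n2) * lambda1_nm`.
#' @examples
#' second_wavelength(488, -4, -3) # 650.67 nm
#' @export
second_wavelength <- function(lambda1_nm, n1, n2) {
  if (n2 == 0) stop("n2 must be non-zero")
  (n1 / n2) * lambda1_nm
}

#' Third wavelength on the opposite tilt state
#'
#' A third colour can reuse the shared diffraction angle beta through the
#' opposite tilt state: its incidence is the specular partner
#' `alpha3 = -beta + 2*gamma_plus`, and the blazed wavelength follows
#' from the diagonal grating equation
#' `lambda3 = (m' / n3) * (sin(alpha3) + sin(beta))`.
#'
#' @param beta_deg Shared diagonal diffraction angle in degrees.
#' @param gamma_plus_deg Opposite tilt state in degrees.
#' @param n3 Integer order (non-zero).
#' @param cfg A [diagonal_config()].
#' @return List with `alpha3_deg` and `lambda3_nm`.
#' @examples
#' third_wavelength(16.6, 12, 4) # alpha3 = 7.4 deg, lambda3 = 553.93 nm
#' @export
third_wavelength <- function(beta_deg, gamma_plus_deg, n3,
                             cfg = diagonal_config()) {
  if (n3 == 0) stop("n3 must be non-zero")
  alpha3 <- -beta_deg + 2 * gamma_plus_deg
  lambda3 <- (cfg$m_prime_um * 1000 / n3) *
    (sin(deg2rad(alpha3)) + sin(deg2rad(beta_deg)))
  if (lambda3 <= 0)
    stop(sprintf("unphysical wavelength (%.2f nm) for beta = %g, gamma+ = %g, n3 = %d",
                 lambda3, beta_deg, gamma_plus_deg, n3))
  list(alpha3_deg = alpha3, lambda3_nm = lambda3)
}

#' Plan a three-colour blazed wavelength set
#'
#' End-to-end multicolour design: solve the blaze condition for
#' (n1, gamma-) at lambda1 to get the shared incidence alpha12 and
#' diffraction beta, pair a second wavelength on the same geometry via
#' `n1 lambda1 = n2 lambda2`, then route a third colour through the
#' gamma+ state at the same beta.
#'
#' @param lambda1_nm First wavelength in nanometres.
#' @param n1,n2,n3 Integer orders for the three colours.
#' @param cfg A [diagonal_config()].
#' @param branch `"negative"` (default, the larger-|alpha| branch with
#'   alpha < gamma) or `"positive"`.
#' @return List with `lambda1_nm`, `lambda2_nm`, `lambda3_nm`,
#'   `alpha12_deg`, `beta_deg`, `alpha3_deg`, the orders, and the
#'   underlying `solutions` data.frame.
#' @examples
#' plan_three_colours() # the 488 / 650.67 / 553.93 nm design
#' @export
plan_three_colours <- function(lambda1_nm = 488, n1 = -4, n2 = -3, n3 = 4,
                               cfg = diagonal_config(),
                               branch = c("negative", "positive")) {
  branch <- match.arg(branch)
  sols <- solve_blaze_incidence(n1, cfg$gamma_minus_deg, lambda1_nm, cfg)
  if (nrow(sols) == 0L)
    stop("blaze condition unsatisfiable for lambda1 at order n1")
  sol <- sols[order(sols$alpha_deg), ]
  sol <- if (branch == "negative") sol[1, ] else sol[nrow(sol), ]
  lambda2 <- second_wavelength(lambda1_nm, n1, n2)
  third <- third_wavelength(sol$beta_deg, cfg$gamma_plus_deg, n3, cfg)
  list(lambda1_nm = lambda1_nm, lambda2_nm = lambda2,
       lambda3_nm = third$lambda3_nm,
       alpha12_deg = sol$alpha_deg, beta_deg = sol$beta_deg,
       alpha3_deg = third$alpha3_deg,
       n1 = n1, n2 = n2, n3 = n3, solutions = sols)
}

#' Blaze-metric scan over wavelength and incidence
#'
#' Evaluates the blaze metric v on a (wavelength, alpha) grid. Dark
#' (near-zero) curves are the blaze loci; vertical cuts through two loci
#' at one alpha identify wavelength pairs sharing an incidence angle.
#'
#' @param cfg A [diagonal_config()].
#' @param gamma_deg Tilt in degrees.
#' @param lambda_nm Vector of wavelengths in nanometres (or a length-2
#'   range expanded with `lambda_step`).
#' @param alpha_deg Vector of diagonal incidence angles in degrees (or a
#'   length-2 range expanded with `alpha_step`).
#' @param lambda_step,alpha_step Steps used when ranges are given.
#' @return List with `lambda_nm`, `alpha_deg` axis vectors, the `v`
#'   matrix (rows lambda, columns alpha) and the matching real-order
#'   matrix `n_real`.
#' @export
diagonal_scan <- function(cfg = diagonal_config(), gamma_deg = cfg$gamma_minus_deg,
                          lambda_nm = c(380, 700), alpha_deg = c(-90 + 1e-6, 90 - 1e-6),
                          lambda_step = 1, alpha_step = 0.25) {
  if (lambda_step <= 0 || alpha_step <= 0) stop("steps must be > 0")
  if (length(lambda_nm) == 2L)
    lambda_nm <- seq(lambda_nm[1], lambda_nm[2], by = lambda_step)
  if (length(alpha_deg) == 2L)
    alpha_deg <- seq(alpha_deg[1], alpha_deg[2], by = alpha_step)
  nr <- outer(lambda_nm, alpha_deg,
              function(l, al) blaze_order_real(al, gamma_deg, l, cfg))
  list(lambda_nm = lambda_nm, alpha_deg = alpha_deg,
       v = abs(sin(pi * nr)), n_real = nr)
}
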