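#' Passive myocardium material constants
#'
#' Constants of the transversely isotropic exponential (Guccione) strain
#' energy together with the bulk penalty enforcing near
#' incompressibility.  The defaults are the literature exponents
#' (`b_f = 18.48`, `b_t = 3.58`, `b_fs = 1.627`) and the mean fitted
#' scale `C = 0.262` kPa.
#'
#' @param C stress scale (kPa).
#' @param b_f fiber exponent (dimensionless).
#' @param b_t transverse exponent.
#' @param b_fs fiber-transverse shear exponent.
#' @param kappa volumetric penalty modulus (kPa).
#' @return An object of class `"passive_params"`.
#' @export
passive_params <- function(C = 0.262, b_f = 18.48, b_t = 3.58,
                           b_fs = 1.627, kappa = 1000) {
  stopifnot(C > 0, b_f > 0, b_t > 0, b_fs > 0, kappa > 0)
  if (b_f < b_t)
    stop("transverse isotropy with a stiffer fiber direction requires b_f >= b_t")
  structure(list(C = C, b_f = b_f, b_t = b_t, b_fs = b_fs, kappa = kappa),
            class = "passive_params")
}

#' @method print passive_params
#' @export
print.passive_params <- function(x, ...) {
  cat(sprintf(
    "Guccione passive law: C = %.3f kPa, b_f = %.3f, b_t = %.3f, b_fs = %.3f; kappa = %g kPa\n",
    x$C, x$b_f, x$b_t, x$b_fs, x$kappa))
  invisible(x)
}

guccione_Q <- function(E, p) {
  p$b_f * E[1, 1]^2 +
    p$b_t * (E[2, 2]^2 + E[3, 3]^2 + E[2, 3]^2 + E[3, 2]^2) +
    p$b_fs * (E[1, 2]^2 + E[2, 1]^2 + E[1, 3]^2 + E[3, 1]^2)
}

#' Passive strain energy density
#'
#' `W = C/2 (exp(Q) - 1)` with
#' `Q = b_f E11^2 + b_t (E22^2 + E33^2 + E23^2 + E32^2)
#'      + b_fs (E12^2 + E21^2 + E13^2 + E31^2)`,
#' where axis 1 is the fiber direction, 2 the cross-fiber (sheet)
#' direction and 3 the radial direction.
#'
#' @param E 3x3 Green-Lagrange strain in fiber coordinates (symmetric).
#' @param p a [passive_params()] object.
#' @return Strain energy density (kPa).
#' @export
strain_energy <- function(E, p) {
  stopifnot(is.matrix(E), all(dim(E) == c(3, 3)))
  if (max(abs(E - t(E))) > 1e-8) stop("strain tensor must be symmetric")
  p$C / 2 * (exp(guccione_Q(E, p)) - 1)
}

#' Passive second Piola-Kirchhoff stress
#'
#' Analytic derivative of [strain_energy()]:
#' `S_ij = C exp(Q) b_(ij) E_ij` (no sum), plus, when the deformation
#' gradient `F` is supplied, the volumetric penalty
#' `kappa (J - 1) J C_right^-1` from the energy `kappa/2 (J - 1)^2`.
#'
#' @inheritParams strain_energy
#' @param F optional 3x3 deformation gradient (fiber coordinates); when
#'   given, the volumetric penalty stress is included and `det(F) <= 0`
#'   is an error.
#' @return 3x3 second Piola-Kirchhoff stress (kPa) in fiber coordinates.
#' @export
passive_stress <- function(E, p, F = NULL) {
  stopifnot(is.matrix(E), all(dim(E) == c(3, 3)))
  eQ <- exp(guccione_Q(E, p))
  B <- matrix(c(p$b_f, p$b_fs, p$b_fs,
                p$b_fs, p$b_t, p$b_t,
                p$b_fs, p$b_t, p$b_t), 3, 3, byrow = TRUE)
  S <- p$C * eQ * B * E
  if (!is.null(F)) {
    J <- det(F)
    if (J <= 0) stop("element inversion: det(F) = ", signif(J, 4))
    Cr <- 2 * E + diag(3)
    S <- S + p$kappa * (J - 1) * J * solve(Cr)
  }
  S
}

#' Total (passive + active) stress in fiber coordinates
#'
#' Adds the active fiber stress of the half-sarcomere state to the
#' passive response: the full tension `T` acts along the fiber axis and
#' 25 percent of it along each of the two cross-fiber axes, with no
#' active shear in the fiber frame.
#'
#' @inheritParams passive_stress
#' @param pp a [passive_params()] object.
#' @param hs an [hs_state()] object supplying the active tension.
#' @param ap an [active_params()] object.
#' @param cross_frac fraction of the fiber tension applied to each
#'   cross-fiber direction.
#' @return 3x3 total stress (kPa) in fiber coordinates.
#' @export
total_stress <- function(E, hs, pp, ap, F = NULL, cross_frac = 0.25) {
  S <- passive_stress(E, pp, F = F)
  T_act <- active_stress(hs, ap) / 1e3  # Pa -> kPa
  S + diag(c(T_act, cross_frac * T_act, cross_frac * T_act))
}

#' Orthonormal fiber frame from a helix angle
#'
#' Builds the right-handed (fiber, sheet, radial) triad from local
#' circumferential/longitudinal/radial wall axes and a helix angle
#' measured from the circumferential direction.
#'
#' @param e_c,e_l,e_r unit circumferential, longitudinal and radial
#'   vectors (mutually orthogonal).
#' @param angle_deg helix angle (degrees).
#' @return 3x3 matrix with columns fiber, sheet, radial.
#' @export
fiber_frame <- function(e_c, e_l, e_r, angle_deg) {
  a <- angle_deg * pi / 180
  f <- cos(a) * e_c + sin(a) * e_l
  s <- -sin(a) * e_c + cos(a) * e_l
  Q <- cbind(f / sqrt(sum(f^2)), s / sqrt(sum(s^2)), e_r / sqrt(sum(e_r^2)))
  if (max(abs(crossprod(Q) - diag(3))) > 1e-10)
    stop("fiber frame is not orthonormal; check the input axes")
  Q
}
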