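#' Define a lossy dielectric medium
#'
#' A medium is described by its relative permittivity, loss tangent and the
#' operating frequency. Under the \eqn{e^{+j\omega t}} time convention the
#' complex relative permittivity is \eqn{\epsilon_r (1 - j\tan\delta)}, so the
#' imaginary part of the complex permittivity is non-positive and outgoing
#' cylindrical waves (Hankel functions of the second kind) decay.
#'
#' @param rel_permittivity dimensionless real relative permittivity, > 0.
#' @param loss_tangent dimensionless loss tangent, >= 0.
#' @param frequency operating frequency in Hz, > 0.
#'
#' @return An object of class `lcbp_medium`.
#' @examples
#' blood <- medium(52.18, 0.39, 6e9)
#' propagation_constant(blood)
#' @export
medium <- function(rel_permittivity, loss_tangent, frequency) {
  if (!is.numeric(rel_permittivity) || length(rel_permittivity) != 1 ||
      !is.finite(rel_permittivity) || rel_permittivity <= 0)
    stop("rel_permittivity must be a single finite positive number")
  if (!is.numeric(loss_tangent) || length(loss_tangent) != 1 ||
      !is.finite(loss_tangent) || loss_tangent < 0)
    stop("loss_tangent must be a single finite non-negative number")
  if (!is.numeric(frequency) || length(frequency) != 1 ||
      !is.finite(frequency) || frequency <= 0)
    stop("frequency must be a single finite positive number (Hz)")
  structure(
    list(rel_permittivity = rel_permittivity,
         loss_tangent = loss_tangent,
         frequency = frequency),
    class = "lcbp_medium")
}

#' @export
print.lcbp_medium <- function(x, ...) {
  cat(sprintf("<lcbp_medium> eps_r = %g, tan(delta) = %g, f = %g GHz\n",
              x$rel_permittivity, x$loss_tangent, x$frequency / 1e9))
  invisible(x)
}

#' Complex permittivity of a medium
#'
#' Returns \eqn{\epsilon_0 \epsilon_r (1 - j \tan\delta)} in F/m.
#'
#' @param m an [medium()] object.
#' @return A complex scalar (F/m) with non-positive imaginary part.
#' @examples
#' complex_permittivity(medium(4.94, 0.19, 6e9))
#' @export
complex_permittivity <- function(m) {
  stopifnot(inherits(m, "lcbp_medium"))
  .eps0 * m$rel_permittivity * complex(real = 1, imaginary = -m$loss_tangent)
}

#' Complex propagation constant of a medium
#'
#' Computes \eqn{\beta = \omega \sqrt{\mu_0 \epsilon}} (rad/m) with the root
#' chosen so that \eqn{Re(\beta) > 0} and \eqn{Im(\beta) \le 0}: outgoing
#' waves propagate and decay.
#'
#' @param m an [medium()] object.
#' @return A complex scalar in rad/m.
#' @examples
#' propagation_constant(medium(1, 0, 6e9))  # free space: 2*pi*f/c, real
#' @export
propagation_constant <- function(m) {
  stopifnot(inherits(m, "lcbp_medium"))
  omega <- 2 * pi * m$frequency
  beta <- omega * sqrt(as.complex(.mu0 * complex_permittivity(m)))
  # principal sqrt of a fourth-quadrant-times-positive argument already has
  # Re > 0, Im <= 0; flip defensively if a boundary case lands elsewhere
  if (Re(beta) < 0) beta <- -beta
  beta
}
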