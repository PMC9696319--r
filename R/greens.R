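#' Kernel configuration for the cylindrical-harmonic Green's function
#'
#' Selects the kernel variant and the truncation of the harmonic series.
#' `free_space` is the homogeneous lossy-medium kernel
#' \eqn{J_n(\beta\rho_<) H^{(2)}_n(\beta\rho_>)}; `rod_scatter` is the field
#' scattered by the central conducting (PEC) rod only, with coefficient
#' \eqn{-J_n(\beta a)/H^{(2)}_n(\beta a)}; `rod_total` is their sum, the exact
#' Green's function of a lossy medium containing a PEC rod of radius `a` (its
#' total field vanishes on the rod surface).
#'
#' @param mode one of `"free_space"`, `"rod_scatter"`, `"rod_total"`.
#' @param n_max highest harmonic order retained (>= 0).
#' @param rel_tol relative truncation tolerance; the series stops once two
#'   consecutive increments fall below `rel_tol` times the partial sum.
#'   `rel_tol = 0` forces summation of all `n_max + 1` harmonic orders.
#' @param rod_radius rod radius `a` in mm; required (> 0) by the rod modes.
#'
#' @return An object of class `lcbp_kernel`.
#' @examples
#' kernel_config("free_space", n_max = 30)
#' @export
kernel_config <- function(mode = c("rod_total", "free_space", "rod_scatter"),
                          n_max = 40, rel_tol = 1e-8, rod_radius = 0.8) {
  mode <- match.arg(mode)
  if (n_max < 0) stop("n_max must be >= 0")
  if (rel_tol < 0) stop("rel_tol must be >= 0")
  if (mode != "free_space" && (!is.numeric(rod_radius) || rod_radius <= 0))
    stop("rod kernels require rod_radius > 0")
  structure(list(mode = mode, n_max = as.integer(n_max), rel_tol = rel_tol,
                 rod_radius = rod_radius),
            class = "lcbp_kernel")
}

# harmonic series terms t_n (n = 0..n_max) and the common prefactor
# beta^2 / (4 omega eps). rho in mm, converted to m at this boundary.
# Folding +-n uses J_{-n} = (-1)^n J_n and H_{-n} = (-1)^n H_n, so the
# two-sided series equals t_0 + sum_{n>=1} 2 cos(n dphi) t_n.
.greens_series_terms <- function(rho_obs, rho_src, medium, config) {
  beta <- propagation_constant(medium)
  omega <- 2 * pi * medium$frequency
  prefac <- beta^2 / (4 * omega * complex_permittivity(medium))
  nmax <- config$n_max
  rho_lo <- min(rho_obs, rho_src) * 1e-3
  rho_hi <- max(rho_obs, rho_src) * 1e-3
  mode <- match(config$mode,
                c("free_space", "rod_scatter", "rod_total")) - 1L
  z_a <- if (mode > 0) beta * config$rod_radius * 1e-3 else 1 + 0i
  t <- greens_terms_cpp(beta * rho_lo, beta * rho_hi, z_a, nmax, mode)
  list(prefac = prefac, t = t)
}

.greens_check_domain <- function(rho_obs, rho_src, config) {
  if (rho_obs <= 0 || rho_src <= 0)
    stop("observation and source radii must be positive (mm)")
  if (config$mode != "free_space" &&
      (rho_obs < config$rod_radius || rho_src < config$rod_radius))
    stop("in rod kernels both radii must be >= rod_radius")
}

#' Evaluate the 2D Green's function of the medium
#'
#' Truncated cylindrical-harmonic series
#' \deqn{G = \frac{\beta^2}{4\omega\epsilon}
#'   \sum_{n=-n_{max}}^{n_{max}} t_n\, e^{jn\Delta\phi}}
#' where the term \eqn{t_n} depends on the kernel mode (see
#' [kernel_config()]). The series stops early once two consecutive increments
#' fall below `rel_tol` of the running partial sum.
#'
#' @param rho_obs,rho_src observation and source radial coordinates (mm).
#' @param delta_phi azimuthal separation in degrees.
#' @param medium the propagation [medium()].
#' @param config a [kernel_config()].
#'
#' @return A complex scalar with attributes `n_used` (harmonic orders actually
#'   summed, counting from 0), `tail_estimate` (magnitude of the last
#'   increment) and `converged` (logical; `FALSE` triggers a warning).
#' @examples
#' blood <- medium(52.18, 0.39, 6e9)
#' greens_2d(4, 1.5, 30, blood, kernel_config("free_space"))
#' @export
greens_2d <- function(rho_obs, rho_src, delta_phi, medium, config) {
  stopifnot(inherits(medium, "lcbp_medium"), inherits(config, "lcbp_kernel"))
  .greens_check_domain(rho_obs, rho_src, config)
  st <- .greens_series_terms(rho_obs, rho_src, medium, config)
  nmax <- config$n_max
  w <- c(1, 2 * cos(seq_len(nmax) * .deg2rad(delta_phi)))
  inc <- w * st$t
  partial <- cumsum(inc)
  n_keep <- nmax + 1             # index into inc/partial; order n_keep - 1
  converged <- config$rel_tol == 0
  if (config$rel_tol > 0 && nmax >= 1) {
    small <- abs(inc) <= config$rel_tol * abs(partial)
    ok <- which(small[-length(small)] & small[-1])
    if (length(ok)) {
      n_keep <- ok[1]
      converged <- TRUE
    }
  }
  if (!converged)
    warning("harmonic series did not converge within n_max orders")
  value <- st$prefac * partial[n_keep]
  structure(value, n_used = n_keep - 1L, tail_estimate = abs(inc[n_keep]),
            converged = converged)
}

#' Diagnose truncation of the harmonic series
#'
#' Reports how many harmonic orders [greens_2d()] actually summed and the
#' magnitude of the last increment.
#'
#' @inheritParams greens_2d
#' @return A list with `n_used`, `tail_estimate` and `converged`.
#' @examples
#' blood <- medium(52.18, 0.39, 6e9)
#' series_convergence_report(4, 1.5, 30, blood, kernel_config("free_space"))
#' @export
series_convergence_report <- function(rho_obs, rho_src, delta_phi, medium,
                                      config) {
  g <- suppressWarnings(
    greens_2d(rho_obs, rho_src, delta_phi, medium, config))
  list(n_used = attr(g, "n_used"),
       tail_estimate = attr(g, "tail_estimate"),
       converged = attr(g, "converged"))
}
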