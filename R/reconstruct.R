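#' Per-pixel coordinate frame
#'
#' The imaging functional is evaluated in a frame re-centered on each pixel:
#' for every element, `rho` is the 3D Euclidean distance from the pixel to the
#' element and `phi` is the element's azimuth about the axis through the pixel
#' parallel to z.
#'
#' @param pixel numeric (x, y, z) in mm.
#' @param layout an [build_array()] layout.
#'
#' @return A data frame with one row per element: `id`, `rho` (mm), `phi`
#'   (degrees).
#' @examples
#' pixel_frame(c(0, 0, 0), build_array())[1:3, ]
#' @export
pixel_frame <- function(pixel, layout) {
  stopifnot(length(pixel) == 3, inherits(layout, "lcbp_array"))
  dx <- layout$x - pixel[1]
  dy <- layout$y - pixel[2]
  dz <- layout$z - pixel[3]
  data.frame(id = layout$id,
             rho = sqrt(dx^2 + dy^2 + dz^2),
             phi = .rad2deg(atan2(dy, dx)))
}

# shared argument checks and C++ call
.reconstruct_core <- function(data, layout, medium, kernel, pattern, vox) {
  stopifnot(inherits(data, "lcbp_multistatic"),
            inherits(layout, "lcbp_array"),
            inherits(medium, "lcbp_medium"),
            inherits(kernel, "lcbp_kernel"),
            inherits(pattern, "lcbp_pattern"))
  if (nrow(data$matrix) != nrow(layout))
    stop("data matrix dimension does not match the array layout")
  if (!identical(data$layout_id, attr(layout, "layout_id")))
    stop(sprintf("layout mismatch: data '%s' vs layout '%s'",
                 data$layout_id, attr(layout, "layout_id")))
  beta <- propagation_constant(medium)            # rad/m
  omega <- 2 * pi * medium$frequency
  prefac <- beta^2 / (4 * omega * complex_permittivity(medium))
  kmode <- match(kernel$mode,
                 c("free_space", "rod_scatter", "rod_total")) - 1L
  lcbp_image_cpp(vox, cbind(layout$x, layout$y, layout$z),
                 .deg2rad(layout$azimuth_deg), .element_axes(layout),
                 data$matrix, beta * 1e-3, prefac, kmode,
                 if (kmode > 0) kernel$rod_radius else 0,
                 kernel$n_max, .pattern_mode_code(pattern),
                 pattern$back_lobe_level, pattern$g1, pattern$g2, 1e-3)
}

#' Loss-compensated back-propagation on a 2D plane
#'
#' Per pixel, the coherent sum over all ordered element pairs (q, m), q != m,
#' of \eqn{\rho \rho' \, G^*(\rho, \rho', \Delta\phi) \, S_{qm}} evaluated in
#' the pixel-centered frame, followed by the modulus. The
#' \eqn{\rho \rho'} product compensates cylindrical spreading and tissue
#' loss. No pattern or polarization weighting is applied on a single plane.
#'
#' @param data differential (scattered-field) [multistatic_data()].
#' @param layout an [build_array()] layout.
#' @param medium the background [medium()].
#' @param kernel a [kernel_config()].
#' @param plane_z axial position (mm) of the imaging plane.
#' @param grid an [image_grid()]; its x/y axes and in-plane mask are used.
#'
#' @return An object of class `lcbp_image2d`: list with `x`, `y`, `plane_z`,
#'   `intensity` matrix and `normalized` flag.
#' @export
reconstruct_2d <- function(data, layout, medium, kernel = kernel_config(),
                           plane_z = 0, grid = NULL) {
  if (is.null(grid)) grid <- image_grid(attr(layout, "geometry"))
  stopifnot(inherits(grid, "lcbp_grid"))
  mask2d <- grid$mask[, , 1]
  idx <- which(mask2d, arr.ind = TRUE)
  vox <- cbind(grid$x[idx[, 1]], grid$y[idx[, 2]], plane_z)
  vals <- .reconstruct_core(data, layout, medium, kernel,
                            pattern_config("isotropic", g1 = 0, g2 = 0), vox)
  intensity <- matrix(0, length(grid$x), length(grid$y))
  intensity[idx] <- vals
  structure(list(x = grid$x, y = grid$y, plane_z = plane_z,
                 intensity = intensity, normalized = FALSE),
            class = "lcbp_image2d")
}

#' @export
print.lcbp_image2d <- function(x, ...) {
  cat(sprintf("<lcbp_image2d> z = %g mm, %d x %d, max = %g%s\n", x$plane_z,
              nrow(x$intensity), ncol(x$intensity), max(x$intensity),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Loss-compensated back-propagation over the 3D cylindrical domain
#'
#' Extends [reconstruct_2d()] to every voxel of the grid: each (q, m) term is
#' additionally weighted by the element pattern gains gT, gR towards the voxel
#' and by the polarization factors
#' \eqn{|[\cos\alpha_1]^{g_1} [\cos\alpha_2]^{g_2}|} for the constant-azimuth
#' plane containing the voxel. The modulus is taken of the coherent pair sum;
#' the weights are non-negative by construction. With isotropic patterns and
#' zero polarization exponents the functional reduces to the 2D one on each
#' plane.
#'
#' @inheritParams reconstruct_2d
#' @param pattern a [pattern_config()].
#' @param grid an [image_grid()].
#'
#' @return A raw (unnormalized) [image3d()] object.
#' @export
reconstruct_3d <- function(data, layout, medium, kernel = kernel_config(),
                           pattern = pattern_config(), grid = NULL) {
  if (is.null(grid)) grid <- image_grid(attr(layout, "geometry"))
  stopifnot(inherits(grid, "lcbp_grid"))
  gv <- .grid_voxels(grid)
  vals <- .reconstruct_core(data, layout, medium, kernel, pattern, gv$xyz)
  intensity <- array(0, dim = dim(grid$mask))
  intensity[gv$idx] <- vals
  image3d(grid, intensity, normalized = FALSE)
}
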