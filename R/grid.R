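#' Voxel grid over the artery interior
#'
#' A regular grid with a cylindrical validity mask: only voxels with
#' `catheter_radius < rho <= artery_radius` are imaged; voxels inside the
#' catheter or beyond the artery wall never contribute to detection.
#'
#' @param geometry a [catheter_geometry()].
#' @param spacing grid spacing (mm).
#' @param z_extent numeric length-2, axial extent (mm).
#'
#' @return An object of class `lcbp_grid` with axis vectors `x`, `y`, `z`
#'   (mm) and a logical `mask` array.
#' @examples
#' g <- image_grid(spacing = 0.5)
#' sum(g$mask)
#' @export
image_grid <- function(geometry = catheter_geometry(), spacing = 0.25,
                       z_extent = c(-5, 5)) {
  stopifnot(inherits(geometry, "lcbp_geometry"))
  if (spacing <= 0) stop("spacing must be positive")
  ra <- geometry$artery_radius
  ax <- seq(-ra, ra, by = spacing)
  z <- seq(z_extent[1], z_extent[2], by = spacing)
  rho <- sqrt(outer(ax^2, ax^2, "+"))
  mask2d <- rho > geometry$catheter_radius & rho <= ra
  mask <- array(mask2d, dim = c(length(ax), length(ax), length(z)))
  structure(list(x = ax, y = ax, z = z, spacing = spacing, mask = mask,
                 geometry = geometry),
            class = "lcbp_grid")
}

#' @export
print.lcbp_grid <- function(x, ...) {
  cat(sprintf("<lcbp_grid> %d x %d x %d at %g mm, %d voxels in mask\n",
              length(x$x), length(x$y), length(x$z), x$spacing, sum(x$mask)))
  invisible(x)
}

# matrix of masked voxel centers (mm) and their array indices
.grid_voxels <- function(grid) {
  idx <- which(grid$mask, arr.ind = TRUE)
  list(idx = idx,
       xyz = cbind(grid$x[idx[, 1]], grid$y[idx[, 2]], grid$z[idx[, 3]]))
}

#' 3D intensity image
#'
#' @param grid an [image_grid()].
#' @param intensity non-negative numeric array matching the grid dimensions.
#' @param normalized logical: has [normalize_threshold()] been applied?
#'
#' @return An object of class `lcbp_image3d`.
#' @export
image3d <- function(grid, intensity, normalized = FALSE) {
  stopifnot(inherits(grid, "lcbp_grid"))
  if (!identical(dim(intensity), dim(grid$mask)))
    stop("intensity array does not match the grid dimensions")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(grid = grid, intensity = intensity, normalized = normalized),
            class = "lcbp_image3d")
}

#' @export
print.lcbp_image3d <- function(x, ...) {
  cat(sprintf("<lcbp_image3d> %s, max = %g, %d nonzero voxels%s\n",
              paste(dim(x$intensity), collapse = " x "), max(x$intensity),
              sum(x$intensity > 0),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Normalize an image to \[0, 1\] and zero the low-intensity floor
#'
#' Divides by the maximum intensity (when positive) and sets values below
#' `threshold` to zero, so the displayed image keeps only voxels within
#' `threshold` of the peak. An all-zero image is returned unchanged except
#' for the normalized flag.
#'
#' @param image an `lcbp_image3d` or `lcbp_image2d` object.
#' @param threshold display threshold on the normalized scale, default 0.2.
#'
#' @return The image with `normalized = TRUE`; all retained values lie in
#'   `[threshold, 1]` (or are zero).
#' @export
normalize_threshold <- function(image, threshold = 0.2) {
  UseMethod("normalize_threshold")
}

.normthresh <- function(v, threshold) {
  mx <- max(v)
  if (mx > 0) {
    v <- v / mx
    v[v < threshold] <- 0
  }
  v
}

#' @rdname normalize_threshold
#' @export
normalize_threshold.lcbp_image3d <- function(image, threshold = 0.2) {
  image$intensity <- .normthresh(image$intensity, threshold)
  image$normalized <- TRUE
  image
}

#' @rdname normalize_threshold
#' @export
normalize_threshold.lcbp_image2d <- function(image, threshold = 0.2) {
  image$intensity <- .normthresh(image$intensity, threshold)
  image$normalized <- TRUE
  image
}
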