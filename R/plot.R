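#' Standard slice panels of a reconstructed volume
#'
#' Renders the reconstructed volume on the nine standard cut planes (xy at
#' z = -4, 0, 4 mm; yz at x = -4, 0, 4 mm; zx at y = -4, 0, 4 mm) as a 3 x 3
#' panel figure, the conventional way of inspecting the full 3D
#' reconstruction.
#'
#' @param image an [image3d()] object (normalized or raw).
#' @param path optional PNG output path; when `NULL`, draws on the active
#'   device.
#' @param z_planes,x_planes,y_planes cut positions in mm.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_slices <- function(image, path = NULL, z_planes = c(-4, 0, 4),
                        x_planes = c(-4, 0, 4), y_planes = c(-4, 0, 4)) {
  stopifnot(inherits(image, "lcbp_image3d"))
  if (!is.null(path)) {
    png(path, width = 1200, height = 1200, res = 120)
    on.exit(dev.off())
  }
  op <- par(mfrow = c(3, 3), mar = c(3, 3, 2, 1))
  on.exit(par(op), add = TRUE)
  zlim <- c(0, max(image$intensity, 1e-300))
  cols <- gray.colors(128, start = 0, end = 1, rev = TRUE)
  draw <- function(axis, value) {
    sl <- .extract_slice(image, axis, value)
    image(sl$rows, sl$cols, sl$m, zlim = zlim, col = cols,
          xlab = "", ylab = "", useRaster = TRUE, asp = 1)
    title(sprintf("%s = %g mm", axis, sl$at), cex.main = 0.9)
  }
  for (v in z_planes) draw("z", v)
  for (v in x_planes) draw("x", v)
  for (v in y_planes) draw("y", v)
  invisible(path)
}
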