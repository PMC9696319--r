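#' Catheter and artery geometry
#'
#' The imaging scene: a blood-filled artery modeled as a circular cylinder, a
#' plastic catheter on whose outer surface the dipole elements sit, and a
#' central metallic rod that shields the back half-space of each element.
#' All lengths in mm.
#'
#' @param artery_radius artery radius (mm).
#' @param catheter_radius catheter radius (mm); the antenna elements sit at
#'   this radial position.
#' @param rod_radius radius of the central metallic rod (mm).
#' @param dipole_length dipole element length (mm); carried for reference.
#' @param n_antennas total number of antenna elements.
#'
#' @return An object of class `lcbp_geometry`.
#' @examples
#' catheter_geometry()
#' @export
catheter_geometry <- function(artery_radius = 5, catheter_radius = 1.5,
                              rod_radius = 0.8, dipole_length = 1.8,
                              n_antennas = 48) {
  if (!(rod_radius < catheter_radius && catheter_radius < artery_radius))
    stop("geometry requires rod_radius < catheter_radius < artery_radius")
  if (rod_radius < 0) stop("rod_radius must be non-negative")
  if (n_antennas < 2) stop("n_antennas must be at least 2")
  structure(
    list(artery_radius = artery_radius, catheter_radius = catheter_radius,
         rod_radius = rod_radius, dipole_length = dipole_length,
         n_antennas = as.integer(n_antennas)),
    class = "lcbp_geometry")
}

#' @export
print.lcbp_geometry <- function(x, ...) {
  cat(sprintf(
    "<lcbp_geometry> artery %g mm | catheter %g mm | rod %g mm | %d antennas\n",
    x$artery_radius, x$catheter_radius, x$rod_radius, x$n_antennas))
  invisible(x)
}

#' Specify a cylindrical anomaly
#'
#' A ground-truth inclusion: a z-aligned circular cylinder of given radius and
#' height with its own dielectric properties (e.g. fat coagulated on the
#' artery wall). The anomaly must clear the catheter; it may straddle the
#' artery wall, in which case only the part inside the artery (the blood
#' region) is discretized.
#'
#' @param center numeric length-3, cylinder center (x, y, z) in mm.
#' @param radius cylinder radius (mm).
#' @param height cylinder height (mm), along z.
#' @param medium a [medium()] with the anomaly's dielectric properties.
#' @param geometry a [catheter_geometry()]; used for validation.
#'
#' @return An object of class `lcbp_anomaly`.
#' @examples
#' fat <- medium(4.94, 0.19, 6e9)
#' anomaly_spec(c(-4, 3, 4), 1, 2, fat)
#' @export
anomaly_spec <- function(center, radius, height, medium,
                         geometry = catheter_geometry()) {
  if (length(center) != 3 || !is.numeric(center))
    stop("center must be a numeric (x, y, z) triple in mm")
  if (radius <= 0 || height <= 0) stop("radius and height must be positive")
  stopifnot(inherits(medium, "lcbp_medium"), inherits(geometry, "lcbp_geometry"))
  rho_c <- sqrt(center[1]^2 + center[2]^2)
  if (rho_c - radius <= geometry$catheter_radius)
    stop("anomaly overlaps the catheter (radial clearance violated)")
  if (rho_c > geometry$artery_radius)
    stop("anomaly center lies outside the artery")
  structure(
    list(center = as.numeric(center), radius = radius, height = height,
         medium = medium),
    class = "lcbp_anomaly")
}

#' Build a conformal antenna array on the catheter surface
#'
#' Places `n_rings` rings of `per_ring` elements each on the catheter surface,
#' uniformly spaced in azimuth within a ring and uniformly spaced in z across
#' `z_span`, centered on z = 0. Element ordering is ring-major (ring 1 first),
#' then by increasing azimuth, and is deterministic.
#'
#' @param geometry a [catheter_geometry()]; `n_rings * per_ring` must equal
#'   `geometry$n_antennas`.
#' @param n_rings number of rings.
#' @param per_ring elements per ring.
#' @param z_span axial extent (mm) covered by the ring centers.
#' @param orientation `"axial"` (dipole axis along z) or `"azimuthal"`
#'   (tangential to the catheter surface).
#'
#' @return An object of class `lcbp_array`: a data frame with one row per
#'   element (id, ring, azimuth_deg, x, y, z in mm, radial position) and the
#'   geometry, orientation and a layout identifier as attributes.
#' @examples
#' build_array(catheter_geometry(), n_rings = 6, per_ring = 8, z_span = 10)
#' @export
build_array <- function(geometry = catheter_geometry(), n_rings = 6,
                        per_ring = 8, z_span = 10,
                        orientation = c("axial", "azimuthal")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(geometry, "lcbp_geometry"))
  if (n_rings < 1 || per_ring < 1)
    stop("n_rings and per_ring must be positive integers")
  if (n_rings * per_ring != geometry$n_antennas)
    stop(sprintf("n_rings * per_ring = %d does not match n_antennas = %d",
                 n_rings * per_ring, geometry$n_antennas))
  if (z_span < 0) stop("z_span must be non-negative")
  z_ring <- if (n_rings == 1) 0 else
    seq(-z_span / 2, z_span / 2, length.out = n_rings)
  az <- seq(0, 360, length.out = per_ring + 1)[seq_len(per_ring)]
  rc <- geometry$catheter_radius
  el <- expand.grid(azimuth_deg = az, ring = seq_len(n_rings),
                    KEEP.OUT.ATTRS = FALSE)
  el <- el[order(el$ring, el$azimuth_deg), , drop = FALSE]
  phi <- .deg2rad(el$azimuth_deg)
  layout <- data.frame(
    id = seq_len(nrow(el)),
    ring = el$ring,
    azimuth_deg = el$azimuth_deg,
    x = rc * cos(phi),
    y = rc * sin(phi),
    z = z_ring[el$ring],
    radial = rc)
  rownames(layout) <- NULL
  structure(layout,
            class = c("lcbp_array", "data.frame"),
            geometry = geometry,
            orientation = orientation,
            layout_id = sprintf("rings%dx%d_z%g_rc%g_%s", n_rings, per_ring,
                                z_span, rc, orientation))
}

#' @export
print.lcbp_array <- function(x, ...) {
  cat(sprintf("<lcbp_array> %d elements on catheter surface (%s dipoles), id %s\n",
              nrow(x), attr(x, "orientation"), attr(x, "layout_id")))
  print.data.frame(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more elements\n", nrow(x) - 4))
  invisible(x)
}

# unit dipole-axis vectors, one row per element
.element_axes <- function(layout) {
  phi <- .deg2rad(layout$azimuth_deg)
  if (attr(layout, "orientation") == "axial")
    cbind(0, 0, rep(1, nrow(layout)))
  else
    cbind(-sin(phi), cos(phi), 0)
}
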