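#' Bundled imaging scenarios
#'
#' Returns a complete scenario configuration as a plain nested list (the same
#' structure the YAML scenario files use). Three study scenarios are bundled:
#'
#' * `"two_anomaly"`: two fat anomalies on the artery wall, centers
#'   (-4, 3, 4) and (4, 1.5, -2) mm, radii 1 and 1 mm, heights 2 and 1 mm,
#'   rod present (rod-total forward propagation, rod-shadowed dipole
#'   patterns), 20 dB AWGN.
#' * `"single_anomaly_rod"`: one anomaly at (-4, 3, 0), rod present.
#' * `"single_anomaly_no_rod"`: the same anomaly with the rod absent
#'   (free-space forward propagation, unshadowed dipole patterns); exhibits
#'   the mirror ghost.
#'
#' All scenarios reconstruct with the rod-scatter imaging kernel, the series
#' whose re-centered rod term acts as the matched filter of the functional.
#'
#' @param name scenario name.
#' @return A list of class `lcbp_scenario`.
#' @examples
#' sc <- default_scenario("two_anomaly")
#' sc$anomalies[[1]]$center
#' @export
default_scenario <- function(name = c("two_anomaly", "single_anomaly_rod",
                                      "single_anomaly_no_rod")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    frequency_hz = 6e9,
    geometry = list(artery_radius = 5, catheter_radius = 1.5,
                    rod_radius = 0.8, dipole_length = 1.8, n_antennas = 48L),
    media = list(
      background = list(rel_permittivity = 52.18, loss_tangent = 0.39),
      anomaly_default = list(rel_permittivity = 4.94, loss_tangent = 0.19),
      catheter = list(rel_permittivity = 5, loss_tangent = 0.001)),
    array = list(n_rings = 6L, per_ring = 8L, z_span = 10,
                 orientation = "axial"),
    kernel = list(mode = "rod_scatter", forward_mode = "rod_total",
                  n_max = 40L, rel_tol = 1e-8),
    pattern = list(mode = "short_dipole_shadowed", back_lobe_level = 0.05,
                   g1 = 1, g2 = 1),
    noise = list(snr_db = 20),
    forward = list(voxel_size = 0.25, coupling_constant = 1),
    grid = list(spacing = 0.25, z_min = -5, z_max = 5),
    threshold = 0.2)
  base$anomalies <- switch(
    name,
    two_anomaly = list(
      list(center = c(-4, 3, 4), radius = 1, height = 2),
      list(center = c(4, 1.5, -2), radius = 1, height = 1)),
    single_anomaly_rod = list(
      list(center = c(-4, 3, 0), radius = 1, height = 2)),
    single_anomaly_no_rod = list(
      list(center = c(-4, 3, 0), radius = 1, height = 2)))
  if (name == "single_anomaly_no_rod") {
    # rod absent from the scene: free-space propagation, no back-lobe shadow;
    # the imaging functional itself is unchanged (rod_scatter kernel)
    base$kernel$forward_mode <- "free_space"
    base$pattern$mode <- "short_dipole"
  }
  structure(base, class = c("lcbp_scenario", "list"))
}

.req <- function(x, path) {
  node <- x
  for (p in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(node[[p]]))
      stop(sprintf("scenario is missing required field '%s'", path))
    node <- node[[p]]
  }
  node
}

#' Validate a scenario configuration
#'
#' Checks presence and basic sanity of every required field; errors name the
#' offending field path.
#'
#' @param scenario a scenario list.
#' @return The scenario, invisibly, with class `lcbp_scenario`.
#' @export
validate_scenario <- function(scenario) {
  for (f in c("frequency_hz", "geometry.artery_radius",
              "geometry.catheter_radius", "geometry.rod_radius",
              "geometry.n_antennas", "media.background.rel_permittivity",
              "media.background.loss_tangent", "array.n_rings",
              "array.per_ring", "array.z_span", "array.orientation",
              "kernel.mode", "kernel.n_max", "kernel.rel_tol",
              "pattern.mode", "pattern.back_lobe_level", "pattern.g1",
              "pattern.g2", "forward.voxel_size", "grid.spacing",
              "grid.z_min", "grid.z_max", "threshold"))
    .req(scenario, f)
  if (!.req(scenario, "kernel.mode") %in%
      c("free_space", "rod_scatter", "rod_total"))
    stop("scenario field 'kernel.mode' must be one of free_space, rod_scatter, rod_total")
  if (!.req(scenario, "pattern.mode") %in%
      c("isotropic", "short_dipole", "short_dipole_shadowed"))
    stop("scenario field 'pattern.mode' is not a known pattern mode")
  if (is.null(scenario$anomalies)) scenario$anomalies <- list()
  for (i in seq_along(scenario$anomalies)) {
    a <- scenario$anomalies[[i]]
    for (f in c("center", "radius", "height"))
      if (is.null(a[[f]]))
        stop(sprintf("scenario is missing required field 'anomalies[%d].%s'",
                     i, f))
    if (length(a$center) != 3)
      stop(sprintf("scenario field 'anomalies[%d].center' must have 3 components", i))
  }
  class(scenario) <- c("lcbp_scenario", "list")
  invisible(scenario)
}

#' Read / write scenario files (YAML)
#'
#' @param path file path.
#' @return `read_scenario` returns a validated scenario list.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  for (i in seq_along(sc$anomalies))
    sc$anomalies[[i]]$center <- as.numeric(sc$anomalies[[i]]$center)
  validate_scenario(sc)
}

#' @rdname read_scenario
#' @param scenario a scenario list.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' Instantiate the domain objects a scenario describes
#'
#' @param scenario a validated scenario list.
#' @return A list with `geometry`, `background`, `layout`, `anomalies`,
#'   `kernel` (reconstruction kernel), `kernel_forward` (propagation kernel
#'   used by the forward simulator; defaults to `kernel.forward_mode`, or the
#'   reconstruction mode when absent), `pattern`, `grid`.
#' @export
scenario_objects <- function(scenario) {
  scenario <- validate_scenario(scenario)
  g <- scenario$geometry
  geometry <- catheter_geometry(g$artery_radius, g$catheter_radius,
                                g$rod_radius,
                                if (is.null(g$dipole_length)) 1.8
                                else g$dipole_length,
                                g$n_antennas)
  background <- medium(scenario$media$background$rel_permittivity,
                       scenario$media$background$loss_tangent,
                       scenario$frequency_hz)
  layout <- build_array(geometry, scenario$array$n_rings,
                        scenario$array$per_ring, scenario$array$z_span,
                        scenario$array$orientation)
  adef <- scenario$media$anomaly_default
  anomalies <- lapply(scenario$anomalies, function(a) {
    er <- if (is.null(a$rel_permittivity)) adef$rel_permittivity
    else a$rel_permittivity
    td <- if (is.null(a$loss_tangent)) adef$loss_tangent else a$loss_tangent
    anomaly_spec(a$center, a$radius, a$height,
                 medium(er, td, scenario$frequency_hz), geometry)
  })
  kernel <- kernel_config(scenario$kernel$mode, scenario$kernel$n_max,
                          scenario$kernel$rel_tol, g$rod_radius)
  fm <- scenario$kernel$forward_mode
  if (is.null(fm)) fm <- scenario$kernel$mode
  kernel_forward <- kernel_config(fm, scenario$kernel$n_max,
                                  scenario$kernel$rel_tol, g$rod_radius)
  pattern <- pattern_config(scenario$pattern$mode,
                            scenario$pattern$back_lobe_level,
                            scenario$pattern$g1, scenario$pattern$g2)
  grid <- image_grid(geometry, scenario$grid$spacing,
                     c(scenario$grid$z_min, scenario$grid$z_max))
  list(geometry = geometry, background = background, layout = layout,
       anomalies = anomalies, kernel = kernel,
       kernel_forward = kernel_forward, pattern = pattern, grid = grid)
}

# md5 of the scenario's canonical YAML serialization
.scenario_hash <- function(scenario) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(scenario), f)
  unname(tools::md5sum(f))
}
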