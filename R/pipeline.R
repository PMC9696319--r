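#' Run the differential imaging pipeline for a scenario
#'
#' Chains the study protocol end to end: Born forward simulation of the
#' reference acquisition (anomalies outside the imaging zone, i.e. an empty
#' scene) and of the target acquisition (anomalies present), the differential
#' `SS = S1 - S2`, additive white Gaussian noise on the differential at the
#' scenario SNR, 3D loss-compensated back-propagation, normalization with the
#' display threshold, connected-component detection and localization against
#' the scenario's ground truth.
#'
#' @param scenario a scenario list (see [default_scenario()]).
#' @param seed integer seed for the noise draw.
#' @param grid optional [image_grid()] overriding the scenario grid.
#'
#' @return A list of class `lcbp_pipeline` with elements `reference`,
#'   `target`, `differential`, `data` (the noisy differential actually
#'   imaged), `image` (raw), `normalized`, `detections`, `localization`,
#'   `truth`, `objects` and `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(default_scenario("two_anomaly"), seed = 1)
#' res$detections
#' }
#' @export
run_pipeline <- function(scenario, seed = 1L, grid = NULL) {
  scenario <- validate_scenario(scenario)
  obj <- scenario_objects(scenario)
  if (!is.null(grid)) obj$grid <- grid
  timing <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  cc <- scenario$forward$coupling_constant
  if (is.null(cc)) cc <- 1
  ref <- simulate_multistatic(
    discretize_anomalies(list(), obj$background,
                         scenario$forward$voxel_size, obj$geometry),
    obj$layout, obj$background, obj$kernel_forward, obj$pattern,
    as.complex(cc))
  vox <- discretize_anomalies(obj$anomalies, obj$background,
                              scenario$forward$voxel_size, obj$geometry)
  tgt <- simulate_multistatic(vox, obj$layout, obj$background,
                              obj$kernel_forward, obj$pattern,
                              as.complex(cc))
  ss <- differential(ref, tgt)
  timing["forward_s"] <- tic() - t0
  t0 <- tic()
  snr <- scenario$noise$snr_db
  data <- if (is.null(snr) || (is.character(snr) && snr == "none")) ss
  else add_awgn(ss, snr, seed)
  img <- reconstruct_3d(data, obj$layout, obj$background, obj$kernel,
                        obj$pattern, obj$grid)
  timing["reconstruct_s"] <- tic() - t0
  t0 <- tic()
  norm <- normalize_threshold(img, scenario$threshold)
  det <- find_components(norm)
  loc <- localization_error(det, obj$anomalies)
  timing["detect_s"] <- tic() - t0
  manifest <- list(
    scenario_name = scenario$name,
    scenario_hash = .scenario_hash(scenario),
    seed = seed,
    package_version = as.character(utils::packageVersion("lcbp")),
    r_version = as.character(getRversion()),
    timing_s = as.list(timing))
  structure(list(reference = ref, target = tgt, differential = ss,
                 data = data, image = img, normalized = norm,
                 detections = det, localization = loc,
                 truth = obj$anomalies, objects = obj, manifest = manifest),
            class = "lcbp_pipeline")
}

#' @export
print.lcbp_pipeline <- function(x, ...) {
  cat(sprintf("<lcbp_pipeline> scenario '%s', seed %s\n",
              x$manifest$scenario_name, x$manifest$seed))
  cat(sprintf("  %d detections, %d matched, %d misses, %d false alarms\n",
              nrow(x$detections), nrow(x$localization$matches),
              length(x$localization$misses),
              length(x$localization$false_alarms)))
  if (nrow(x$localization$matches))
    print.data.frame(x$localization$matches)
  invisible(x)
}
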