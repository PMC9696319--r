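#' Write / read multistatic data as delimited text
#'
#' Tabular container: a `#`-prefixed metadata header (format version,
#' frequency, layout id, matrix side, noise provenance) followed by one row
#' per (tx, rx) entry with real and imaginary parts printed to 9 significant
#' digits. Write -> read -> write round-trips to identical bytes.
#'
#' @param data a [multistatic_data()] object.
#' @param path output file path.
#' @return `write_multistatic` returns `path` invisibly; `read_multistatic`
#'   returns the [multistatic_data()] object.
#' @export
write_multistatic <- function(data, path) {
  stopifnot(inherits(data, "lcbp_multistatic"))
  Q <- nrow(data$matrix)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("# lcbp multistatic v1",
           sprintf("# frequency_hz: %.9g", data$frequency),
           sprintf("# layout_id: %s", data$layout_id),
           sprintf("# q: %d", Q),
           sprintf("# noise_snr_db: %s",
                   if (is.null(data$noise)) "none"
                   else paste(data$noise$snr_db, collapse = ",")),
           sprintf("# noise_seed: %s",
                   if (is.null(data$noise)) "none"
                   else paste(data$noise$seed, collapse = ",")),
           "tx rx real imag")
  writeLines(hdr, con, sep = "\n")
  tx <- rep(seq_len(Q), times = Q)
  rx <- rep(seq_len(Q), each = Q)
  m <- as.vector(data$matrix)  # column-major: rx varies slowest
  writeLines(sprintf("%d %d %.8e %.8e", tx, rx, Re(m), Im(m)), con, sep = "\n")
  invisible(path)
}

#' @rdname write_multistatic
#' @export
read_multistatic <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getf <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(ln)) stop(sprintf("header field '%s' missing in %s", key, path))
    trimws(sub(paste0("# ", key, ":"), "", ln[1], fixed = TRUE))
  }
  freq <- as.numeric(getf("frequency_hz"))
  layout_id <- getf("layout_id")
  Q <- as.integer(getf("q"))
  snr <- getf("noise_snr_db")
  seed <- getf("noise_seed")
  noise <- if (snr == "none") NULL
  else list(snr_db = as.numeric(strsplit(snr, ",")[[1]]),
            seed = as.integer(strsplit(seed, ",")[[1]]))
  body <- read.table(text = lines[!startsWith(lines, "#")][-1],
                     col.names = c("tx", "rx", "real", "imag"))
  m <- matrix(0 + 0i, Q, Q)
  m[cbind(body$tx, body$rx)] <- complex(real = body$real,
                                        imaginary = body$imag)
  multistatic_data(m, freq, layout_id, noise)
}

#' Write / read a 3D image volume
#'
#' The voxel intensities are stored as a flat little-endian double array with
#' a JSON sidecar (`<path>.json`) holding the grid axes, spacing, geometry,
#' mask definition and normalization state.
#'
#' @param image an [image3d()] object.
#' @param path output path for the binary volume.
#' @return `write_image3d` returns `path` invisibly; `read_image3d` the
#'   reconstructed [image3d()].
#' @export
write_image3d <- function(image, path) {
  stopifnot(inherits(image, "lcbp_image3d"))
  g <- image$grid
  meta <- list(dims = dim(image$intensity), x = g$x, y = g$y, z = g$z,
               spacing = g$spacing, normalized = image$normalized,
               geometry = unclass(g$geometry),
               mask = "catheter_radius < rho <= artery_radius")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(image$intensity), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_image3d
#' @export
read_image3d <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- do.call(catheter_geometry, as.list(meta$geometry))
  grid <- image_grid(geom, meta$spacing, range(meta$z))
  if (!identical(dim(grid$mask), as.integer(meta$dims)))
    stop("image sidecar is inconsistent with the reconstructed grid")
  n <- prod(meta$dims)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  image3d(grid, array(v, dim = meta$dims), normalized = meta$normalized)
}

#' Write a detection report
#'
#' Emits the detection table as tab-separated text and a machine-readable
#' JSON summary (matches, misses, false alarms, manifest fields).
#'
#' @param detections a [find_components()] result.
#' @param localization a [localization_error()] result (optional).
#' @param path output path for the TSV table; the JSON summary goes to
#'   `<path>.json`.
#' @param manifest optional manifest list recorded in the summary.
#' @return `path`, invisibly.
#' @export
write_detection_report <- function(detections, localization = NULL, path,
                                   manifest = NULL) {
  stopifnot(inherits(detections, "lcbp_detections"))
  write.table(as.data.frame(detections), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  summary <- list(n_detections = nrow(detections),
                  detections = as.data.frame(detections))
  if (!is.null(localization)) {
    summary$matches <- localization$matches
    summary$misses <- localization$misses
    summary$false_alarms <- localization$false_alarms
  }
  if (!is.null(manifest)) summary$manifest <- manifest
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Export a 2D slice of a 3D image as CSV
#'
#' @param image an [image3d()] object.
#' @param axis `"x"`, `"y"` or `"z"`: the axis normal to the slice.
#' @param value position (mm) along that axis; the nearest grid plane is
#'   exported.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_slice_csv <- function(image, axis = c("z", "x", "y"), value, path) {
  axis <- match.arg(axis)
  sl <- .extract_slice(image, axis, value)
  df <- cbind(expand.grid(a = sl$rows, b = sl$cols, KEEP.OUT.ATTRS = FALSE),
              intensity = as.vector(sl$m))
  names(df)[1:2] <- sl$axes
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# nearest-plane slice of an image3d; returns the slice matrix and axes
.extract_slice <- function(image, axis, value) {
  g <- image$grid
  switch(axis,
         z = {
           k <- which.min(abs(g$z - value))
           list(m = image$intensity[, , k], rows = g$x, cols = g$y,
                axes = c("x_mm", "y_mm"), at = g$z[k])
         },
         x = {
           k <- which.min(abs(g$x - value))
           list(m = image$intensity[k, , ], rows = g$y, cols = g$z,
                axes = c("y_mm", "z_mm"), at = g$x[k])
         },
         y = {
           k <- which.min(abs(g$y - value))
           list(m = image$intensity[, k, ], rows = g$x, cols = g$z,
                axes = c("x_mm", "z_mm"), at = g$y[k])
         })
}
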