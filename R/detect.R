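#' Connected components of a thresholded image
#'
#' Labels maximal connected sets of nonzero voxels (union-find over the
#' chosen neighborhood) and summarizes each as a detection: voxel count, peak
#' value and position, and intensity-weighted centroid.
#'
#' @param image a normalized, thresholded [image3d()] object.
#' @param connectivity 6, 18 or 26 (face, face+edge, full neighborhood).
#'
#' @return A data frame of class `lcbp_detections`, one row per component,
#'   sorted by decreasing peak value: `component_id`, `voxel_count`,
#'   `peak_value`, `peak_x/y/z`, `centroid_x/y/z` (mm). Zero rows for a blank
#'   image.
#' @export
find_components <- function(image, connectivity = 26) {
  stopifnot(inherits(image, "lcbp_image3d"))
  if (!isTRUE(image$normalized))
    stop("image must be normalized and thresholded before detection")
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  dims <- dim(image$intensity)
  nz <- which(image$intensity > 0)
  empty <- data.frame(component_id = integer(0), voxel_count = integer(0),
                      peak_value = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      centroid_z = numeric(0))
  class(empty) <- c("lcbp_detections", "data.frame")
  if (!length(nz)) return(empty)
  arr <- arrayInd(nz, dims)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off <- off[rowSums(abs(off)) <= switch(as.character(connectivity),
                                         "6" = 1, "18" = 2, "26" = 3), ,
             drop = FALSE]
  # half-neighborhood: each unordered pair visited once
  off <- off[off[, 3] < 0 | (off[, 3] == 0 & off[, 2] < 0) |
               (off[, 3] == 0 & off[, 2] == 0 & off[, 1] < 0), ,
             drop = FALSE]
  parent <- seq_along(nz)
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (o in seq_len(nrow(off))) {
    ni <- sweep(arr, 2, off[o, ], "+")
    valid <- ni[, 1] >= 1 & ni[, 1] <= dims[1] &
      ni[, 2] >= 1 & ni[, 2] <= dims[2] &
      ni[, 3] >= 1 & ni[, 3] <= dims[3]
    lin <- ni[, 1] + dims[1] * (ni[, 2] - 1) + dims[1] * dims[2] * (ni[, 3] - 1)
    j <- match(lin[valid], nz)
    a <- which(valid)[!is.na(j)]
    b <- j[!is.na(j)]
    for (k in seq_along(a)) {
      ra <- uf_find(a[k])
      rb <- uf_find(b[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_along(nz), uf_find, integer(1))
  labs <- match(root, unique(root))
  g <- image$grid
  vx <- g$x[arr[, 1]]; vy <- g$y[arr[, 2]]; vz <- g$z[arr[, 3]]
  iv <- image$intensity[nz]
  comp <- lapply(seq_len(max(labs)), function(l) {
    s <- labs == l
    w <- iv[s] / sum(iv[s])
    p <- which.max(iv[s])
    data.frame(voxel_count = sum(s), peak_value = max(iv[s]),
               peak_x = vx[s][p], peak_y = vy[s][p], peak_z = vz[s][p],
               centroid_x = sum(w * vx[s]), centroid_y = sum(w * vy[s]),
               centroid_z = sum(w * vz[s]))
  })
  out <- do.call(rbind, comp)
  out <- out[order(-out$peak_value), , drop = FALSE]
  out <- cbind(component_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("lcbp_detections", "data.frame")
  out
}

# all injective maps of seq_len(k) into seq_len(n), as a list of index vectors
.injections <- function(k, n) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(chosen, remaining) {
    if (length(chosen) == k) {
      out[[length(out) + 1]] <<- chosen
      return(invisible())
    }
    for (r in remaining) rec(c(chosen, r), setdiff(remaining, r))
  }
  rec(integer(0), seq_len(n))
  out
}

#' Match detections to ground-truth anomalies
#'
#' Finds the one-to-one assignment between truth anomalies and detections
#' that minimizes the total centroid-to-center distance (exhaustive search
#' over assignments; intended for the handful of anomalies of a single
#' scene). Unmatched truths are misses, unmatched detections false alarms.
#'
#' @param detections a [find_components()] result.
#' @param truth list of [anomaly_spec()] objects.
#' @param by match on the `"centroid"` (default, more stable under noise) or
#'   the `"peak"` position.
#'
#' @return A list with `matches` (data frame: `truth`, `detection`,
#'   `error_mm`), `misses` (truth indices) and `false_alarms` (detection
#'   component ids).
#' @export
localization_error <- function(detections, truth, by = c("centroid", "peak")) {
  by <- match.arg(by)
  stopifnot(inherits(detections, "lcbp_detections"))
  nt <- length(truth)
  nd <- nrow(detections)
  pts <- if (by == "centroid")
    cbind(detections$centroid_x, detections$centroid_y, detections$centroid_z)
  else cbind(detections$peak_x, detections$peak_y, detections$peak_z)
  centers <- t(vapply(truth, function(a) a$center, numeric(3)))
  if (nt == 0 || nd == 0)
    return(list(matches = data.frame(truth = integer(0),
                                     detection = integer(0),
                                     error_mm = numeric(0)),
                misses = seq_len(nt),
                false_alarms = detections$component_id))
  if (max(nt, nd) > 8)
    stop("exhaustive assignment supports at most 8 truths/detections")
  cost <- outer(seq_len(nt), seq_len(nd), Vectorize(function(i, j)
    sqrt(sum((centers[i, ] - pts[j, ])^2))))
  if (nt <= nd) {
    maps <- .injections(nt, nd)
    tot <- vapply(maps, function(m) sum(cost[cbind(seq_len(nt), m)]),
                  numeric(1))
    m <- maps[[which.min(tot)]]
    matches <- data.frame(truth = seq_len(nt),
                          detection = detections$component_id[m],
                          error_mm = cost[cbind(seq_len(nt), m)])
    misses <- integer(0)
    fa <- detections$component_id[setdiff(seq_len(nd), m)]
  } else {
    maps <- .injections(nd, nt)
    tot <- vapply(maps, function(m) sum(cost[cbind(m, seq_len(nd))]),
                  numeric(1))
    m <- maps[[which.min(tot)]]
    matches <- data.frame(truth = m,
                          detection = detections$component_id,
                          error_mm = cost[cbind(m, seq_len(nd))])
    misses <- setdiff(seq_len(nt), m)
    fa <- integer(0)
  }
  list(matches = matches[order(matches$truth), , drop = FALSE],
       misses = misses, false_alarms = fa)
}

#' Ghost (mirror-ambiguity) metric for a single-anomaly scene
#'
#' Without the central rod, back-propagation produces a spurious anomaly
#' roughly diametrically opposite the true one. The metric splits the image
#' by azimuth about the catheter axis: the near zone is within 90 degrees of
#' the truth azimuth, the far zone is the rest. `ghost_ratio` is the far-zone
#' peak over the near-zone peak; `ghost_azimuth_offset` is the azimuth
#' difference (degrees, in \[0, 360)) between the far-zone peak and the truth.
#'
#' @param image a (normalized or raw) [image3d()] or `lcbp_image2d` object.
#' @param truth a single [anomaly_spec()].
#'
#' @return A list with `ghost_ratio` and `ghost_azimuth_offset`.
#' @export
ghost_metric <- function(image, truth) {
  stopifnot(inherits(truth, "lcbp_anomaly"))
  if (inherits(image, "lcbp_image3d")) {
    gv <- .grid_voxels(image$grid)
    xy <- gv$xyz[, 1:2, drop = FALSE]
    iv <- image$intensity[gv$idx]
  } else if (inherits(image, "lcbp_image2d")) {
    idx <- which(is.finite(image$intensity), arr.ind = TRUE)
    xy <- cbind(image$x[idx[, 1]], image$y[idx[, 2]])
    iv <- image$intensity[idx]
  } else stop("image must be an lcbp_image3d or lcbp_image2d")
  if (all(iv == 0)) stop("blank image: ghost metric undefined")
  truth_az <- atan2(truth$center[2], truth$center[1])
  offset <- .wrap_angle(atan2(xy[, 2], xy[, 1]) - truth_az)
  near <- abs(offset) <= pi / 2
  peak_near <- if (any(near)) max(iv[near]) else 0
  peak_far <- if (any(!near)) max(iv[!near]) else 0
  if (peak_far == 0) {
    return(list(ghost_ratio = 0, ghost_azimuth_offset = NA_real_))
  }
  far_idx <- which(!near)[which.max(iv[!near])]
  list(ghost_ratio = peak_far / peak_near,
       ghost_azimuth_offset = .rad2deg(offset[far_idx]) %% 360)
}
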