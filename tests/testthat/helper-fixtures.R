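# shared small fixtures, built in code

blood_6ghz <- function() medium(52.18, 0.39, 6e9)
fat_6ghz <- function() medium(4.94, 0.19, 6e9)

# small array for fast tests: 8 elements on the standard catheter
tiny_geometry <- function(n = 8L)
  catheter_geometry(artery_radius = 5, catheter_radius = 1.5,
                    rod_radius = 0.8, n_antennas = n)

tiny_layout <- function(n_rings = 2L, per_ring = 4L, z_span = 4)
  build_array(tiny_geometry(n_rings * per_ring), n_rings, per_ring, z_span)

# one-voxel scatterer, for hand-assembled oracles
point_voxels <- function(center, contrast = -0.9 + 0.3i, volume = 0.015625)
  structure(list(centers = matrix(center, 1), contrast = contrast,
                 voxel_volume = volume),
            class = "lcbp_voxels")

# small fast scenario for pipeline/cli plumbing tests
tiny_scenario <- function() {
  sc <- default_scenario("two_anomaly")
  sc$geometry$n_antennas <- 16L
  sc$array$n_rings <- 4L
  sc$array$per_ring <- 4L
  sc$kernel$n_max <- 25L
  sc$forward$voxel_size <- 0.5
  sc$grid$spacing <- 1
  sc$grid$z_min <- -4
  sc$grid$z_max <- 4
  validate_scenario(sc)
}

# wrap an intensity array (already in [0,1]) as a normalized image
as_norm_image <- function(arr, spacing = 1) {
  geom <- catheter_geometry(artery_radius = 50, catheter_radius = 0.5,
                            rod_radius = 0.2)
  g <- list(x = seq_len(dim(arr)[1]), y = seq_len(dim(arr)[2]),
            z = seq_len(dim(arr)[3]), spacing = spacing,
            mask = array(TRUE, dim(arr)), geometry = geom)
  class(g) <- "lcbp_grid"
  image3d(g, arr, normalized = TRUE)
}

# independent BFS flood fill, the oracle for component labeling
flood_fill_labels <- function(arr, connectivity = 26) {
  dims <- dim(arr)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off <- off[rowSums(abs(off)) <= switch(as.character(connectivity),
                                         "6" = 1, "18" = 2, "26" = 3), ,
             drop = FALSE]
  labels <- array(0L, dims)
  nextlab <- 0L
  nz <- which(arr > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    if (labels[nz[r, 1], nz[r, 2], nz[r, 3]] > 0) next
    nextlab <- nextlab + 1L
    queue <- list(nz[r, ])
    labels[nz[r, 1], nz[r, 2], nz[r, 3]] <- nextlab
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(off))) {
        nb <- cur + off[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        if (arr[nb[1], nb[2], nb[3]] > 0 &&
            labels[nb[1], nb[2], nb[3]] == 0) {
          labels[nb[1], nb[2], nb[3]] <- nextlab
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  labels
}

# random sparse binary volume with a few seeded blobs
random_sparse_volume <- function(dims = c(12, 12, 8), p = 0.04) {
  arr <- array(0, dims)
  n <- prod(dims)
  arr[sample.int(n, ceiling(p * n))] <- runif(ceiling(p * n), 0.3, 1)
  arr
}
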