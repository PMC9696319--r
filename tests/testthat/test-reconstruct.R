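blood <- blood_6ghz()
fat <- fat_6ghz()

test_that("pixel frame returns 3D distances and azimuths about the pixel", {
  lay <- tiny_layout()
  set.seed(21)
  for (i in 1:5) {
    p <- c(runif(1, -4, 4), runif(1, -4, 4), runif(1, -3, 3))
    pf <- pixel_frame(p, lay)
    for (q in sample(nrow(lay), 3)) {
      d_oracle <- sqrt((lay$x[q] - p[1])^2 + (lay$y[q] - p[2])^2 +
                         (lay$z[q] - p[3])^2)
      expect_equal(pf$rho[q], d_oracle)
    }
  }
  # pixel on the axis, element ring at the same z: rho = catheter radius
  ring <- build_array(catheter_geometry(n_antennas = 4), 1, 4, 0)
  pf0 <- pixel_frame(c(0, 0, 0), ring)
  expect_equal(pf0$rho, rep(1.5, 4))
  # two elements mirror-symmetric about the pixel azimuth have equal rho
  pf <- pixel_frame(c(2, 0, 0), ring)
  expect_equal(pf$rho[ring$azimuth_deg == 90], pf$rho[ring$azimuth_deg == 270])
})

test_that("vectorized reconstruction matches a naive triple-loop reference", {
  # small scene: 4 elements, coarse grid, every term assembled from the
  # scalar module functions with exhaustive series summation
  lay <- build_array(catheter_geometry(n_antennas = 4), 1, 4, 0)
  geom <- attr(lay, "geometry")
  kern <- kernel_config("rod_scatter", n_max = 25, rel_tol = 0,
                        rod_radius = 0.8)
  pat <- pattern_config("short_dipole_shadowed", back_lobe_level = 0.05)
  an <- anomaly_spec(c(-3.5, 2.5, 0), 1, 2, fat, geom)
  data <- simulate_multistatic(discretize_anomalies(list(an), blood, 0.5,
                                                    geom),
                               lay, blood, kernel_config("rod_total",
                                                         n_max = 25),
                               pat)
  grid <- image_grid(geom, spacing = 2, z_extent = c(1, 1))
  img <- reconstruct_3d(data, lay, blood, kern, pat, grid)
  gv <- lcbp:::.grid_voxels(grid)
  S <- data$matrix
  for (v in seq_len(nrow(gv$xyz))) {
    p <- gv$xyz[v, ]
    pf <- pixel_frame(p, lay)
    phi_pix <- atan2(p[2], p[1]) * 180 / pi
    acc <- 0 + 0i
    for (q in 1:4) for (m in 1:4) {
      if (q == m) next
      if (pf$rho[q] < 0.8 || pf$rho[m] < 0.8) next  # inside the virtual rod
      g <- greens_2d(pf$rho[q], pf$rho[m], pf$phi[q] - pf$phi[m], blood, kern)
      wq <- pf$rho[q] * pattern_gain(lay[q, ], p, pat) *
        polarization_factor(lay[q, ], phi_pix, pat$g1)
      wm <- pf$rho[m] * pattern_gain(lay[m, ], p, pat) *
        polarization_factor(lay[m, ], phi_pix, pat$g2)
      acc <- acc + wq * wm * Conj(as.complex(g)) * S[q, m]
    }
    expect_equal(img$intensity[gv$idx[v, , drop = FALSE]], Mod(acc),
                 tolerance = 1e-10)
  }
})

test_that("zero data give a zero image and scaling the data scales the image", {
  lay <- tiny_layout()
  geom <- attr(lay, "geometry")
  grid <- image_grid(geom, spacing = 1, z_extent = c(-2, 2))
  zero <- multistatic_data(matrix(0 + 0i, nrow(lay), nrow(lay)), 6e9,
                           attr(lay, "layout_id"))
  img0 <- reconstruct_3d(zero, lay, blood, kernel_config(n_max = 25),
                         pattern_config(), grid)
  expect_true(all(img0$intensity == 0))
  an <- anomaly_spec(c(-4, 3, 0), 1, 2, fat, geom)
  data <- simulate_multistatic(discretize_anomalies(list(an), blood, 0.5,
                                                    geom),
                               lay, blood,
                               kernel_config("rod_total", n_max = 25),
                               pattern_config())
  img1 <- reconstruct_3d(data, lay, blood, kernel_config(n_max = 25),
                         pattern_config(), grid)
  scaled <- multistatic_data((3 - 4i) * data$matrix, 6e9, data$layout_id)
  img2 <- reconstruct_3d(scaled, lay, blood, kernel_config(n_max = 25),
                         pattern_config(), grid)
  # modulus linearity: I(a S) = |a| I(S); normalized images identical
  expect_equal(img2$intensity, 5 * img1$intensity, tolerance = 1e-10)
  expect_equal(normalize_threshold(img2)$intensity,
               normalize_threshold(img1)$intensity, tolerance = 1e-10)
})

test_that("the 3D functional reduces to the 2D one on a single plane", {
  # isotropic patterns, zero polarization exponents, one ring at z = 0
  lay <- build_array(catheter_geometry(n_antennas = 8), 1, 8, 0)
  geom <- attr(lay, "geometry")
  kern <- kernel_config("rod_scatter", n_max = 30)
  pat0 <- pattern_config("isotropic", g1 = 0, g2 = 0)
  an <- anomaly_spec(c(-4, 3, 0), 1, 2, fat, geom)
  data <- simulate_multistatic(discretize_anomalies(list(an), blood, 0.5,
                                                    geom),
                               lay, blood,
                               kernel_config("rod_total", n_max = 30), pat0)
  grid2d <- image_grid(geom, spacing = 0.5, z_extent = c(0, 0))
  i3 <- reconstruct_3d(data, lay, blood, kern, pat0, grid2d)
  i2 <- reconstruct_2d(data, lay, blood, kern, plane_z = 0, grid = grid2d)
  expect_equal(i3$intensity[, , 1], i2$intensity, tolerance = 1e-12)
})

test_that("a point scatterer is recovered at its own position", {
  lay <- build_array(catheter_geometry(), 6, 8, 10)
  geom <- attr(lay, "geometry")
  kern_f <- kernel_config("rod_total", n_max = 40)
  kern_r <- kernel_config("rod_scatter", n_max = 40)
  pat <- pattern_config("short_dipole_shadowed")
  vx <- point_voxels(c(-4, 3, 2))
  data <- simulate_multistatic(vx, lay, blood, kern_f, pat)
  grid <- image_grid(geom, spacing = 0.5)
  img <- reconstruct_3d(data, lay, blood, kern_r, pat, grid)
  pk <- which(img$intensity == max(img$intensity), arr.ind = TRUE)
  peak <- c(img$grid$x[pk[1]], img$grid$y[pk[2]], img$grid$z[pk[3]])
  expect_true(all(abs(peak - c(-4, 3, 2)) <= 0.5))  # within one voxel
})

test_that("consistent relabeling of antennas leaves the image unchanged", {
  lay <- tiny_layout()
  geom <- attr(lay, "geometry")
  an <- anomaly_spec(c(-4, 3, 0), 1, 2, fat, geom)
  data <- simulate_multistatic(discretize_anomalies(list(an), blood, 0.5,
                                                    geom),
                               lay, blood,
                               kernel_config("rod_total", n_max = 25),
                               pattern_config())
  grid <- image_grid(geom, spacing = 1, z_extent = c(-2, 2))
  kern <- kernel_config("rod_scatter", n_max = 25)
  img1 <- reconstruct_3d(data, lay, blood, kern, pattern_config(), grid)
  set.seed(8)
  perm <- sample(nrow(lay))
  lay_p <- lay[perm, ]
  for (a in c("geometry", "orientation", "layout_id"))
    attr(lay_p, a) <- attr(lay, a)
  data_p <- multistatic_data(data$matrix[perm, perm], data$frequency,
                             data$layout_id)
  img2 <- reconstruct_3d(data_p, lay_p, blood, kern, pattern_config(), grid)
  expect_equal(img2$intensity, img1$intensity, tolerance = 1e-12)
})

test_that("normalize_threshold rescales to [0, 1] and floors small values", {
  g <- image_grid(tiny_geometry(), spacing = 2.5, z_extent = c(0, 0))
  mk <- function(vals) {
    a <- array(0, dim(g$mask))
    a[which(g$mask)[seq_along(vals)]] <- vals
    image3d(g, a)
  }
  n1 <- normalize_threshold(mk(c(0.5, 1, 2)), 0.2)
  expect_equal(sort(n1$intensity[n1$intensity > 0]), c(0.25, 0.5, 1))
  n2 <- normalize_threshold(mk(c(0.1, 1)), 0.2)
  expect_equal(sort(n2$intensity[n2$intensity > 0]), 1)  # 0.1 floored
  n3 <- normalize_threshold(mk(rep(3, 4)), 0.2)
  expect_equal(sort(unique(n3$intensity[n3$intensity > 0])), 1)
  # all-zero image passes through with the flag set
  n0 <- normalize_threshold(mk(numeric(0)), 0.2)
  expect_true(n0$normalized)
  expect_true(all(n0$intensity == 0))
  # invariant: no retained value lies in (0, threshold)
  expect_true(all(n1$intensity == 0 | n1$intensity >= 0.2))
})

test_that("mismatched data and layout are rejected", {
  lay <- tiny_layout()
  bad <- multistatic_data(matrix(0 + 0i, 4, 4), 6e9, "other")
  expect_error(reconstruct_3d(bad, lay, blood), "does not match")
  bad2 <- multistatic_data(matrix(0 + 0i, nrow(lay), nrow(lay)), 6e9, "other")
  expect_error(reconstruct_3d(bad2, lay, blood), "layout mismatch")
})
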