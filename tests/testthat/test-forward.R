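blood <- blood_6ghz()
fat <- fat_6ghz()

test_that("anomaly discretization matches a brute-force point-in-cylinder count", {
  geom <- catheter_geometry()
  # empty scene
  v0 <- discretize_anomalies(list(), blood, 0.25, geom)
  expect_equal(nrow(v0$centers), 0L)
  an <- anomaly_spec(c(-4, 3, 0), 1, 2, fat, geom)
  vx <- discretize_anomalies(list(an), blood, 0.25, geom)
  # independent brute-force count over a generous box of voxel centers
  h <- 0.25
  cand <- expand.grid(x = h * (-40:40) + h / 2, y = h * (-40:40) + h / 2,
                      z = h * (-40:40) + h / 2)
  ok <- (cand$x + 4)^2 + (cand$y - 3)^2 <= 1 & abs(cand$z) <= 1 &
    sqrt(cand$x^2 + cand$y^2) > geom$catheter_radius
  expect_equal(nrow(vx$centers), sum(ok))
  expect_equal(vx$voxel_volume, 0.25^3)
  # fat-in-blood contrast, arithmetic forced by the dielectric values
  eb <- complex_permittivity(blood)
  ea <- complex_permittivity(fat)
  expect_equal(unique(vx$contrast), (ea - eb) / eb)
  # anomaly overlapping the catheter is rejected
  bad <- structure(list(center = c(2, 0, 0), radius = 1, height = 2,
                        medium = fat), class = "lcbp_anomaly")
  expect_error(discretize_anomalies(list(bad), blood, 0.25, geom), "catheter")
})

test_that("a single in-plane voxel gives the hand-assembled Born product", {
  lay <- build_array(catheter_geometry(n_antennas = 2), 1, 2, 0)
  kern <- kernel_config("rod_total", n_max = 40, rel_tol = 0, rod_radius = 0.8)
  pat <- pattern_config("short_dipole_shadowed", back_lobe_level = 0.05)
  p <- c(-3.5, 2.25, 0)
  chi <- -0.7 + 0.2i
  vx <- point_voxels(p, contrast = chi, volume = 0.125)
  d <- simulate_multistatic(vx, lay, blood, kern, pat, 2 - 1i)
  rho_v <- sqrt(p[1]^2 + p[2]^2)
  phi_v <- atan2(p[2], p[1]) * 180 / pi
  E <- vapply(1:2, function(q) {
    g <- greens_2d(rho_v, lay$radial[q], phi_v - lay$azimuth_deg[q], blood, kern)
    as.complex(g) * pattern_gain(lay[q, ], p, pat) *
      polarization_factor(lay[q, ], phi_v, pat$g1)
  }, complex(1))
  expect_equal(d$matrix[1, 2], (2 - 1i) * chi * 0.125 * E[1] * E[2],
               tolerance = 1e-12)
  expect_equal(d$matrix[2, 1], d$matrix[1, 2])
  expect_equal(d$matrix[1, 1], 0 + 0i)
})

test_that("out-of-plane propagation applies the slant-path factor", {
  geom <- catheter_geometry(n_antennas = 2)
  lay2 <- build_array(geom, 2, 1, 6)  # elements at z = -3 and 3, azimuth 0
  kern <- kernel_config("free_space", n_max = 40, rel_tol = 0)
  pat <- pattern_config("isotropic", g1 = 0, g2 = 0)
  p <- c(4, 0, 0)
  vx <- point_voxels(p, contrast = -0.5 + 0i, volume = 1)
  d <- simulate_multistatic(vx, lay2, blood, kern, pat)
  beta_mm <- propagation_constant(blood) * 1e-3
  E <- vapply(1:2, function(q) {
    g <- as.complex(greens_2d(4, 1.5, 0, blood, kern))  # in-plane kernel
    r2 <- 4 - 1.5
    r3 <- sqrt(r2^2 + lay2$z[q]^2)
    g * exp(-1i * beta_mm * (r3 - r2)) * sqrt(r2 / r3)
  }, complex(1))
  expect_equal(d$matrix[1, 2], -0.5 * E[1] * E[2], tolerance = 1e-12)
})

test_that("Born linearity: scaling contrast scales the matrix; scenes add", {
  lay <- tiny_layout()
  kern <- kernel_config("rod_total", n_max = 30)
  pat <- pattern_config("short_dipole_shadowed")
  a1 <- anomaly_spec(c(-4, 3, 1), 1, 2, fat, attr(lay, "geometry"))
  a2 <- anomaly_spec(c(4, 1.5, -1), 1, 1, fat, attr(lay, "geometry"))
  geom <- attr(lay, "geometry")
  vA <- discretize_anomalies(list(a1), blood, 0.5, geom)
  vB <- discretize_anomalies(list(a2), blood, 0.5, geom)
  vAB <- discretize_anomalies(list(a1, a2), blood, 0.5, geom)
  sA <- simulate_multistatic(vA, lay, blood, kern, pat)
  sB <- simulate_multistatic(vB, lay, blood, kern, pat)
  sAB <- simulate_multistatic(vAB, lay, blood, kern, pat)
  # differential of (A u B) against A isolates B
  expect_equal(differential(sAB, sA)$matrix, sB$matrix, tolerance = 1e-12)
  # scalar scaling of the contrast
  v2 <- vA; v2$contrast <- 3 * v2$contrast
  s2 <- simulate_multistatic(v2, lay, blood, kern, pat)
  expect_equal(s2$matrix, 3 * sA$matrix, tolerance = 1e-12)
  # reciprocity for every kernel/pattern mode
  for (km in c("free_space", "rod_scatter", "rod_total"))
    for (pm in c("isotropic", "short_dipole", "short_dipole_shadowed")) {
      s <- simulate_multistatic(vA, lay, blood,
                                kernel_config(km, n_max = 25),
                                pattern_config(pm))
      expect_equal(s$matrix, t(s$matrix))
    }
  # empty scene gives the zero matrix
  s0 <- simulate_multistatic(discretize_anomalies(list(), blood, 0.5, geom),
                             lay, blood, kern, pat)
  expect_true(all(s0$matrix == 0))
})

test_that("differential requires matching acquisitions and is antisymmetric", {
  m <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4, 4)
  s1 <- multistatic_data(m, 6e9, "layA")
  s2 <- multistatic_data(m * 2, 6e9, "layA")
  expect_true(all(differential(s1, s1)$matrix == 0))
  expect_equal(differential(s1, s2)$matrix, -differential(s2, s1)$matrix)
  s3 <- multistatic_data(m, 6e9, "layB")
  expect_error(differential(s1, s3), "layout mismatch")
  s4 <- multistatic_data(m, 5e9, "layA")
  expect_error(differential(s1, s4), "frequency")
})

test_that("additive noise honours the requested SNR contract", {
  set.seed(99)
  Q <- 101  # 10100 off-diagonal entries
  m <- matrix(complex(real = rnorm(Q * Q), imaginary = rnorm(Q * Q)), Q, Q)
  clean <- multistatic_data(m, 6e9, "big")
  noisy <- add_awgn(clean, snr_db = 20, seed = 42)
  off <- row(m) != col(m)
  snr_hat <- 10 * log10(mean(Mod(clean$matrix[off])^2) /
                          mean(Mod(noisy$matrix[off] - clean$matrix[off])^2))
  expect_lt(abs(snr_hat - 20), 0.2)
  expect_true(all(diag(noisy$matrix) == 0))
  # determinism and provenance
  noisy2 <- add_awgn(clean, snr_db = 20, seed = 42)
  expect_identical(noisy$matrix, noisy2$matrix)
  expect_equal(noisy$noise, list(snr_db = 20, seed = 42))
  expect_error(add_awgn(noisy, 20, 1), "twice")
  # infinite SNR sentinel leaves the data untouched
  inf <- add_awgn(clean, snr_db = Inf, seed = 1)
  expect_identical(inf$matrix, clean$matrix)
  # the global RNG stream is not disturbed
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(add_awgn(clean, 20, 5)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("tabular multistatic files round-trip bit-exactly", {
  lay <- tiny_layout()
  geom <- attr(lay, "geometry")
  an <- anomaly_spec(c(-4, 3, 0), 1, 2, fat, geom)
  s <- simulate_multistatic(discretize_anomalies(list(an), blood, 0.5, geom),
                            lay, blood, kernel_config(n_max = 25),
                            pattern_config())
  s <- add_awgn(s, 20, 3)
  f1 <- tempfile(fileext = ".dat"); f2 <- tempfile(fileext = ".dat")
  write_multistatic(s, f1)
  r <- read_multistatic(f1)
  expect_equal(r$matrix, s$matrix, tolerance = 1e-8)
  expect_equal(r$frequency, s$frequency)
  expect_equal(r$layout_id, s$layout_id)
  expect_equal(r$noise$snr_db, 20)
  write_multistatic(r, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
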