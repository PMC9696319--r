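#' Multistatic scattered-field data container
#'
#' Holds the Q x Q complex matrix of scattered fields: entry (q, m) is the
#' field measured at element m when element q transmits. The diagonal is not
#' measured and is kept at zero; downstream sums always exclude it.
#'
#' @param mat Q x Q complex matrix.
#' @param frequency operating frequency (Hz).
#' @param layout_id identifier of the array layout the data refer to.
#' @param noise `NULL` for noiseless data, else a list with `snr_db`, `seed`.
#'
#' @return An object of class `lcbp_multistatic`.
#' @export
multistatic_data <- function(mat, frequency, layout_id, noise = NULL) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("mat must be a square matrix")
  mat <- matrix(as.complex(mat), nrow(mat), ncol(mat))
  diag(mat) <- 0 + 0i
  structure(list(matrix = mat, frequency = frequency,
                 layout_id = layout_id, noise = noise),
            class = "lcbp_multistatic")
}

#' @export
print.lcbp_multistatic <- function(x, ...) {
  cat(sprintf("<lcbp_multistatic> %d x %d at %g GHz, layout %s, %s\n",
              nrow(x$matrix), ncol(x$matrix), x$frequency / 1e9, x$layout_id,
              if (is.null(x$noise)) "noiseless"
              else sprintf("AWGN %g dB (seed %s)", x$noise$snr_db,
                           x$noise$seed)))
  invisible(x)
}

#' Discretize anomalies onto a voxel grid
#'
#' Voxelizes a list of cylindrical anomalies on a regular grid of spacing
#' `voxel_size`: a voxel belongs to an anomaly iff its center lies inside the
#' anomaly cylinder. Anomalies must clear the catheter but may straddle the
#' artery wall (wall-coagulated plaque does); the whole cylinder scatters.
#' The dielectric contrast per voxel is
#' \eqn{(\epsilon_{anom} - \epsilon_{bg})/\epsilon_{bg}} from the complex
#' permittivities.
#'
#' @param anomalies list of [anomaly_spec()] objects (may be empty).
#' @param background the background [medium()] (blood).
#' @param voxel_size grid spacing (mm).
#' @param geometry a [catheter_geometry()].
#'
#' @return A list of class `lcbp_voxels` with `centers` (N x 3 matrix, mm),
#'   `contrast` (complex length N) and `voxel_volume` (mm^3).
#' @examples
#' fat <- medium(4.94, 0.19, 6e9)
#' blood <- medium(52.18, 0.39, 6e9)
#' vx <- discretize_anomalies(list(anomaly_spec(c(-4, 3, 0), 1, 2, fat)),
#'                            blood, 0.5)
#' @export
discretize_anomalies <- function(anomalies, background, voxel_size = 0.25,
                                 geometry = catheter_geometry()) {
  stopifnot(inherits(background, "lcbp_medium"),
            inherits(geometry, "lcbp_geometry"))
  if (voxel_size <= 0) stop("voxel_size must be positive")
  centers <- matrix(numeric(0), 0, 3)
  contrast <- complex(0)
  eps_bg <- complex_permittivity(background)
  grid_axis <- function(lo, hi) {
    k <- seq(floor(lo / voxel_size), ceiling(hi / voxel_size))
    voxel_size * (k + 0.5)
  }
  for (an in anomalies) {
    stopifnot(inherits(an, "lcbp_anomaly"))
    rho_c <- sqrt(an$center[1]^2 + an$center[2]^2)
    if (rho_c - an$radius <= geometry$catheter_radius)
      stop("anomaly overlaps the catheter")
    xs <- grid_axis(an$center[1] - an$radius, an$center[1] + an$radius)
    ys <- grid_axis(an$center[2] - an$radius, an$center[2] + an$radius)
    zs <- grid_axis(an$center[3] - an$height / 2, an$center[3] + an$height / 2)
    g <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                               KEEP.OUT.ATTRS = FALSE))
    inside <- (g[, 1] - an$center[1])^2 + (g[, 2] - an$center[2])^2 <=
      an$radius^2 & abs(g[, 3] - an$center[3]) <= an$height / 2
    inside <- inside & sqrt(g[, 1]^2 + g[, 2]^2) > geometry$catheter_radius
    if (!any(inside)) next
    eps_an <- complex_permittivity(an$medium)
    centers <- rbind(centers, g[inside, , drop = FALSE])
    contrast <- c(contrast, rep((eps_an - eps_bg) / eps_bg, sum(inside)))
  }
  structure(list(centers = centers, contrast = contrast,
                 voxel_volume = voxel_size^3),
            class = "lcbp_voxels")
}

#' Born-approximation multistatic forward simulation
#'
#' Synthetic stand-in for a full-wave solver: under the first-order Born
#' approximation the scattered field for transmit element q and receive
#' element m is a sum over scatterer voxels,
#' \deqn{S_{qm} = c \sum_v \chi_v \, V \, E_q(v) \, E_m(v)}
#' where \eqn{\chi_v} is the dielectric contrast, V the voxel volume, and
#' \eqn{E_q(v)} the incident field of element q at the voxel: the medium
#' Green's function (rod-centered frame) times the element's pattern gain and
#' polarization factor for the constant-azimuth plane through the voxel. The
#' matrix is symmetric (reciprocity) and its diagonal is zero.
#'
#' The 2D cylindrical-harmonic kernel describes in-plane propagation; for
#' voxels and elements at different axial positions the incident field is
#' corrected by the slant-path factor
#' \eqn{e^{-j\beta(R_{3D}-R_{2D})}\sqrt{R_{2D}/R_{3D}}}, which applies the
#' propagation delay, tissue loss and cylindrical spreading along the oblique
#' element-to-voxel path. In-plane (\eqn{\Delta z = 0}) the factor is 1 and
#' the field is exactly the 2D kernel.
#'
#' @param voxels a [discretize_anomalies()] result.
#' @param layout an [build_array()] layout.
#' @param background the background [medium()].
#' @param kernel a [kernel_config()].
#' @param pattern a [pattern_config()].
#' @param coupling_constant complex scale absorbing the unspecified
#'   field-to-measurement proportionality; images are max-normalized, so the
#'   default 1 is inconsequential.
#'
#' @return A noiseless [multistatic_data()] object.
#' @export
simulate_multistatic <- function(voxels, layout, background,
                                 kernel = kernel_config(),
                                 pattern = pattern_config(),
                                 coupling_constant = 1 + 0i) {
  stopifnot(inherits(voxels, "lcbp_voxels"), inherits(layout, "lcbp_array"),
            inherits(background, "lcbp_medium"),
            inherits(kernel, "lcbp_kernel"),
            inherits(pattern, "lcbp_pattern"))
  geometry <- attr(layout, "geometry")
  Q <- nrow(layout)
  S <- matrix(0 + 0i, Q, Q)
  nv <- nrow(voxels$centers)
  if (nv > 0) {
    rho_v_all <- sqrt(voxels$centers[, 1]^2 + voxels$centers[, 2]^2)
    if (any(rho_v_all <= geometry$rod_radius))
      stop("scatterer voxel inside the metallic rod")
    phi_e <- .deg2rad(layout$azimuth_deg)
    rc <- layout$radial[1]
    nmax <- kernel$n_max
    axes <- .element_axes(layout)
    iso <- pattern$pattern_mode == "isotropic"
    shadowed <- pattern$pattern_mode == "short_dipole_shadowed"
    for (v in seq_len(nv)) {
      p <- voxels$centers[v, ]
      rho_v <- rho_v_all[v]
      phi_v <- atan2(p[2], p[1])
      st <- .greens_series_terms(rho_v, rc, background, kernel)
      dphi <- .wrap_angle(phi_v - phi_e)
      # G for all elements: t_0 + sum_n 2 cos(n dphi) t_n
      cosmat <- cos(outer(seq_len(nmax), dphi))          # nmax x Q
      G <- st$prefac *
        (st$t[1] + 2 * as.vector(crossprod(cosmat, st$t[-1])))
      dx <- p[1] - layout$x; dy <- p[2] - layout$y; dz <- p[3] - layout$z
      nd <- sqrt(dx^2 + dy^2 + dz^2)
      if (any(nd < 1e-9)) stop("scatterer voxel coincides with an element")
      r2d <- sqrt(dx^2 + dy^2)
      beta_mm <- propagation_constant(background) * 1e-3
      slant <- exp(-1i * beta_mm * (nd - r2d)) * sqrt(r2d / nd)
      G <- G * slant
      if (iso) gains <- rep(1, Q) else {
        ux <- dx / nd; uy <- dy / nd; uz <- dz / nd
        cx <- axes[, 2] * uz - axes[, 3] * uy
        cy <- axes[, 3] * ux - axes[, 1] * uz
        cz <- axes[, 1] * uy - axes[, 2] * ux
        gains <- sqrt(cx^2 + cy^2 + cz^2)
        if (shadowed)
          gains[abs(dphi) > pi / 2] <-
            gains[abs(dphi) > pi / 2] * pattern$back_lobe_level
      }
      pol <- if (pattern$g1 == 0) rep(1, Q) else abs(cos(dphi))^pattern$g1
      E <- G * gains * pol
      S <- S + voxels$contrast[v] * voxels$voxel_volume * (E %o% E)
    }
    S <- coupling_constant * S
  }
  multistatic_data(S, background$frequency, attr(layout, "layout_id"))
}

#' Add complex white Gaussian noise at a prescribed SNR
#'
#' Adds independent circular complex Gaussian noise to every off-diagonal
#' entry. The per-entry noise variance is set so that the mean off-diagonal
#' signal power divided by the noise variance equals `10^(snr_db/10)`.
#' `snr_db = Inf` returns the data unchanged (zero noise). Data that already
#' carry noise provenance cannot be noised again.
#'
#' @param data a noiseless [multistatic_data()] object.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param seed integer seed recorded in the noise provenance.
#'
#' @return A [multistatic_data()] object with noise metadata.
#' @export
add_awgn <- function(data, snr_db = 20, seed = 1L) {
  stopifnot(inherits(data, "lcbp_multistatic"))
  if (!is.null(data$noise))
    stop("data already carry noise provenance; refusing to add noise twice")
  if (is.infinite(snr_db) && snr_db > 0) {
    data$noise <- list(snr_db = Inf, seed = seed)
    return(data)
  }
  Q <- nrow(data$matrix)
  off <- row(data$matrix) != col(data$matrix)
  p_sig <- mean(Mod(data$matrix[off])^2)
  sigma2 <- p_sig / 10^(snr_db / 10)
  n_off <- sum(off)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  noise <- complex(real = rnorm(n_off, sd = sqrt(sigma2 / 2)),
                   imaginary = rnorm(n_off, sd = sqrt(sigma2 / 2)))
  m <- data$matrix
  m[off] <- m[off] + noise
  multistatic_data(m, data$frequency, data$layout_id,
                   noise = list(snr_db = snr_db, seed = seed))
}

#' Differential measurement
#'
#' Forms `SS = S1 - S2`, the entrywise difference between a reference
#' acquisition (anomalies outside the imaging zone) and a target acquisition
#' (anomalies present). Under the Born model the differential isolates the
#' anomalies' scattered field.
#'
#' @param s1 reference [multistatic_data()].
#' @param s2 target [multistatic_data()].
#' @return A [multistatic_data()] object.
#' @export
differential <- function(s1, s2) {
  stopifnot(inherits(s1, "lcbp_multistatic"), inherits(s2, "lcbp_multistatic"))
  if (!identical(s1$layout_id, s2$layout_id))
    stop(sprintf("layout mismatch: '%s' vs '%s'", s1$layout_id, s2$layout_id))
  if (!identical(s1$frequency, s2$frequency))
    stop("frequency mismatch between the two acquisitions")
  noise <- if (is.null(s1$noise) && is.null(s2$noise)) NULL else
    list(snr_db = c(s1$noise$snr_db, s2$noise$snr_db),
         seed = c(s1$noise$seed, s2$noise$seed))
  multistatic_data(s1$matrix - s2$matrix, s1$frequency, s1$layout_id, noise)
}
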