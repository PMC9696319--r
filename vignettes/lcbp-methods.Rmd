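---
title: "Loss-compensated back-propagation for intravascular microwave imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loss-compensated back-propagation for intravascular microwave imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcbp)
```

## The imaging problem

A catheter of radius 1.5 mm carrying 48 conformal dipole elements is pushed
through a blood-filled coronary artery (modeled as a circular cylinder of
radius 5 mm). A central metallic rod of radius 0.8 mm runs along the catheter
axis. The elements acquire multistatic data: each element transmits in turn
at 6 GHz while all others receive, giving a 48 x 48 complex matrix per
acquisition. Fat or calcium coagulated on the artery wall perturbs the
scattered field; the goal is to detect such anomalies and localize them in
3D, in a strongly lossy medium (blood at 6 GHz: relative permittivity 52.18,
loss tangent 0.39, skin-depth scale of a few millimetres).

Because the anomalies move out of and into the imaging zone as the catheter
advances, a differential protocol isolates their signature: a reference
acquisition `S1` with the anomalies outside the zone is subtracted from the
target acquisition `S2`, and the difference `SS = S1 - S2` is imaged.

## The imaging functional

The reconstruction is qualitative (an intensity map, not a permittivity
estimate). For a pixel at position $p$, with $\rho_q$ the Euclidean distance
from $p$ to element $q$ and $\phi_q$ the azimuth of element $q$ about the
axis through $p$ parallel to the catheter axis,

$$
I(p) \;=\; \Bigl|\sum_{q}\sum_{m\neq q}
  \rho_q\,\rho_m\; G^*\!\left(\rho_q,\rho_m,\phi_q-\phi_m\right)\,
  g_T(q,p)\, g_R(m,p)\,
  \bigl|\cos\alpha_q\bigr|^{g_1}\bigl|\cos\alpha_m\bigr|^{g_2}\;
  S_{qm}\Bigr| ,
$$

where $G$ is the cylindrical-harmonic Green's function of the medium
(next section) evaluated in the frame re-centered on the pixel, the
$\rho_q\rho_m$ product compensates cylindrical spreading and tissue loss
(hence *loss-compensated* back-propagation), $g_T,g_R$ are the element
pattern gains towards the pixel, and the $|\cos\alpha|^{g}$ factors weight
each element by the azimuthal angle $\alpha$ between its own meridian plane
and the constant-azimuth plane containing the pixel (TM-polarization
selection: the factors are unity when the pixel lies on the element's
plane). The modulus is taken of the coherent pair sum; the pattern and
polarization weights are non-negative, so their placement inside or outside
the inner modulus is immaterial.

On a single plane with unity weights this reduces to the plain 2D
functional implemented by `reconstruct_2d()`; `reconstruct_3d()` evaluates
every voxel of the cylindrical grid directly, which subsumes a
plane-by-plane reading.

## The Green's function and why the rod term is the matched filter

`greens_2d()` evaluates the truncated two-sided harmonic series

$$
G(\rho,\rho',\Delta\phi) = \frac{\beta^2}{4\omega\epsilon}
 \sum_{n=-N}^{N} t_n\, e^{jn\Delta\phi},
$$

with three selectable term families (`kernel_config()`):

* `free_space`: $t_n = J_n(\beta\rho_<)\,H^{(2)}_n(\beta\rho_>)$, the
  homogeneous lossy-medium kernel;
* `rod_scatter`: $t_n = -\dfrac{J_n(\beta a)}{H^{(2)}_n(\beta a)}
  H^{(2)}_n(\beta\rho')\,H^{(2)}_n(\beta\rho)$, the field scattered by a
  perfectly conducting rod of radius $a$ *centered at the origin of the
  evaluation frame*;
* `rod_total`: their sum, the exact Green's function of the medium with the
  rod; its total field vanishes on the rod surface, which the tests assert.

Under the per-pixel coordinate transformation the evaluation origin is the
pixel itself. This has a consequence that drives the whole design: by
Graf's addition theorem the free-space series collapses to
$H^{(2)}_0(\beta R)$ with $R$ the *element-to-element* distance — it carries
no pixel-dependent phase at all. The pixel dependence of the functional
lives in the rod-scatter term, which is the field scattered by a virtual
rod placed at the pixel; its $n=0$ term
$\propto H^{(2)}_0(\beta\rho_q)H^{(2)}_0(\beta\rho_m)$ is phase-conjugate to
the data produced by a scatterer at that pixel, i.e. a matched filter.
Reconstruction therefore defaults to the `rod_scatter` kernel; including
the free-space part (`rod_total`) adds a pixel-independent-phase clutter
term, amplified by the $\rho\rho'$ weights, that empirically relocates the
global maximum to the diametric mirror of the target. The forward simulator
by contrast models physical propagation and defaults to `rod_total`.
A scenario file carries both choices (`kernel.mode` for reconstruction,
`kernel.forward_mode` for the simulated physics).

The time convention is $e^{+j\omega t}$, so outgoing waves are Hankel
functions of the second kind and the propagation constant
$\beta=\omega\sqrt{\mu_0\epsilon}$ is taken with $\mathrm{Re}\,\beta>0$,
$\mathrm{Im}\,\beta\le 0$. Bessel and Hankel functions are evaluated at
complex argument directly (power series for $Y_0,Y_1$, Miller backward
recurrence for $J_n$, stable forward recurrence for $Y_n$), validated
against an independent special-function library.

Two numerical facts shape the defaults:

* Convergence of the free-space series is governed by the *radius ratio*:
  terms decay like $(\rho_</\rho_>)^n/n$, so comparable radii need hundreds
  to thousands of orders. At such orders individual factors leave double
  range while the products stay $O(1)$; the term sequences are therefore
  computed in scaled arithmetic (mantissa plus base-10 exponent carried
  separately). The adaptive truncation (`rel_tol`, two consecutive
  increments below tolerance) reports `n_used` and flags non-convergence.
  The default `n_max = 40` is ample for the separated-radii geometry of the
  forward model and for the rod-scatter kernel, whose coefficients decay on
  the rod scale ($\sim(\beta a/2)^{2n}/(n!(n-1)!)$, converged by $n\approx 8$
  for the 0.8 mm rod).
* A 2D conductor's scattering vanishes only like $1/\ln(\beta a)$ as
  $a\to 0$, so the rod kernels approach the free-space kernel
  logarithmically, not polynomially; the corresponding test asserts the
  trend rather than a tight limit.

In rod modes the series is meaningful only for radii at or outside the rod;
in the re-centered frame a pixel can sit closer than $a$ to an element, and
such element contributions are excluded (zero weight) consistently in the
fast path and in the reference implementations.

## Antenna model

The elements are modeled as short dipoles: gain $|\sin\theta|$ about the
dipole axis (axial by default; azimuthal orientation is a configuration
option). The metallic rod blocks each element's view of the far half-space;
this is modeled as a two-level azimuthal shadow: full gain within 90
degrees of the element's outward normal, `back_lobe_level` (default 0.05,
about -26 dB) beyond. The level is a free parameter of the model — the
published patterns are only qualitative — and `back_lobe_level = 1`
recovers the rod-free pattern. The polarization exponents `g1`, `g2`
default to 1. Magnitudes (`|cos|`, `|sin|`) are used throughout because the
functional images intensity; signed factors would create sign ambiguities
inside the modulus.

This shadow is the mechanism behind the mirror-ghost phenomenology: with
unshadowed patterns each element also receives from its back side, the data
cannot distinguish a scatterer from its diametric mirror, and the
reconstruction shows a second blob roughly 180 degrees opposite the true
one. With the shadow applied (in the data and in the reconstruction
weights) the ghost falls below the 0.2 display threshold. `ghost_metric()`
quantifies both regimes.

## The Born forward model and what it does not emulate

The synthetic-data generator replaces full-wave simulation with a
first-order Born model: the field scattered from voxelized anomalies is

$$
S_{qm} = c\sum_v \chi_v\, V\, E_q(v)\, E_m(v),\qquad
\chi_v = \frac{\epsilon_{anom}-\epsilon_{bg}}{\epsilon_{bg}},
$$

with $E_q(v)$ the incident field of element $q$ at the voxel: the 2D
medium kernel in the rod-centered frame (mode `kernel.forward_mode`,
`rod_total` when the rod is present) times the element's pattern gain and
polarization factor. Because the 2D kernel describes in-plane propagation
only, out-of-plane element-voxel paths are corrected by the slant-path
factor $e^{-j\beta(R_{3D}-R_{2D})}\sqrt{R_{2D}/R_{3D}}$ — the propagation
delay, tissue loss and spreading along the oblique path. The factor is
exactly 1 in-plane, and it is what gives the simulated data the axial phase
diversity that the published full-wave data possess; without it the
multistatic matrix would carry no z information and no 3D localization
would be possible.

This is a deliberate inverse-crime setup: forward and inverse models share
the same kernel family, because the artifact verifies the imaging
functional, not electromagnetic fidelity. The generator does not emulate
mutual coupling between the 48 dipoles, the catheter plastic as a
propagation layer, multiple scattering between anomalies, resonant element
behaviour, or the (never specified) proportionality between VNA
S-parameters and field products — the latter is absorbed into the complex
`coupling_constant`, which is inconsequential because images are
max-normalized. Passing tests therefore demonstrate the functional's
behaviour under its own physics, not performance on measured data.

Noise: `add_awgn()` adds circular complex white Gaussian noise to the
off-diagonal entries, with the variance referenced to the mean off-diagonal
power of the matrix being noised. In the pipeline the noise is applied to
the differential (anomaly-only) matrix, which makes the stated 20 dB SNR
refer to the anomaly signature rather than to the (identically zero Born)
reference field. Every stochastic step takes an explicit seed recorded in
the output provenance, and the global RNG stream is left undisturbed.

## Study scenarios and defaults

The bundled scenarios (`default_scenario()`, YAML copies under
`inst/extdata/`) encode the study conditions: blood background
(52.18, tan-delta 0.39), fat anomalies (4.94, 0.19), 6 GHz, 48 elements.
Values the source material leaves open were fixed once:

* **Array tiling**: 6 rings of 8 elements over a 10 mm axial span, rings
  azimuthally aligned, elements ordered ring-major. A symmetric tiling of
  the stated 10 mm imaging zone; rings/elements per ring are configurable.
* **Two-anomaly scene**: cylinders at (-4, 3, 4) and (4, 1.5, -2) mm with
  radii 1 and 1 mm and heights 2 and 1 mm. The first straddles the artery
  wall; the whole cylinder scatters (wall-coagulated plaque does not stop
  at the lumen boundary).
* **Single-anomaly scenes** place the same cylinder at (-4, 3, 0) so the
  ghost analysis can run on the z = 0 plane; the `no_rod` variant uses
  free-space forward propagation and unshadowed patterns, everything else
  unchanged.
* **Grid**: 0.25 mm spacing, z from -5 to 5 mm, cylindrical validity mask
  `catheter_radius < rho <= artery_radius` (about 47 000 voxels); pixels
  inside the catheter are never imaged. Forward voxelization 0.25 mm
  (8 voxels across the smallest anomaly diameter).
* **Post-processing**: the image is divided by its maximum and values below
  0.2 are zeroed. The source description of this step is ambiguous about
  order; normalizing first is the only scale-invariant reading under an
  arbitrary coupling constant, so that is the implemented order.
* Single frequency (6 GHz); multi-frequency summation is out of scope.

## Detection metrics

`find_components()` labels nonzero voxels by union-find over a
26-neighborhood (6/18 available); each component reports voxel count, peak
and intensity-weighted centroid. `localization_error()` matches components
to ground truth by minimizing total centroid-to-center distance over all
assignments (exhaustive, intended for a handful of blobs; peak-position
matching is available by flag). `ghost_metric()` splits the volume by
azimuth about the catheter axis at 90 degrees from the truth azimuth and
reports the far-zone to near-zone peak ratio and the far-peak azimuth
offset.

## Known limitations

* The shadowed aperture (roughly 90 degrees of arc) limits radial
  resolution: the matched term stays partially coherent over ~3 mm of
  radial displacement, so the 0.2-threshold blob of a wall anomaly extends
  inward and along the wall. The intensity-weighted centroid of such an
  arc-shaped blob lies inward of the arc; peak positions are markedly more
  accurate than centroids in the radial direction. This is a property of
  the functional with this aperture, not of the noise level (it persists
  noiselessly).
* Axial resolution comes entirely from the slant-path phase across the
  10 mm aperture (about 2 mm at these parameters); anomalies near the array
  edge blur axially toward the array center.
* The free-space and rod-total reconstruction kernels are retained for
  comparison but cannot localize (the addition-theorem degeneracy above);
  they are not defaults anywhere.
* Quantitative inversion (permittivity estimation), layered-media kernels
  (catheter plastic, artery wall) and 3D dyadic kernels are out of scope.

## Problem sizes

The shipped tests reconstruct the full 0.25 mm study grid once for the
two-anomaly pipeline (about 47 000 voxels, a few tens of seconds with the
compiled kernel) and use reduced scenes (8-16 elements, 0.5-1 mm grids)
for the property and oracle suites, which keeps the complete suite around
half a minute.
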