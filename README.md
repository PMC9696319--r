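# lcbp — loss-compensated back-propagation for intravascular microwave imaging

`lcbp` simulates and reconstructs catheter-based microwave images of
coronary-artery wall anomalies. A cylindrical catheter carrying 48 conformal
dipole antennas (with a central metallic rod along its axis) acquires
multistatic scattered-field data at 6 GHz inside a blood-filled artery;
anomalies such as fat or calcium coagulated on the inner wall are detected
and localized in 3D from differential measurements. The package is aimed at
researchers in microwave/biomedical imaging who want a reproducible,
end-to-end reference implementation of the method: forward data generation,
reconstruction, and quantitative detection metrics.

## The method

The qualitative imaging functional evaluated at every voxel $p$ is

$$
I(p)=\Bigl|\sum_{q}\sum_{m\neq q}\rho_q\rho_m\,
G^{*}(\rho_q,\rho_m,\phi_q-\phi_m)\,g_T g_R\,
|\cos\alpha_q|^{g_1}|\cos\alpha_m|^{g_2}\,S_{qm}\Bigr|,
$$

where $S_{qm}$ is the (differential) multistatic matrix, $\rho_q,\phi_q$ are
each element's distance and azimuth in a frame re-centered on the pixel,
$\rho_q\rho_m$ compensates spreading and tissue loss, $g_T,g_R$ are the
element pattern gains and the $|\cos\alpha|^g$ factors select the
TM-consistent polarization for the pixel's meridian plane. The kernel $G$
is the cylindrical-harmonic (Bessel/Hankel) series of the lossy medium with
a perfectly conducting rod,

$$
G(\rho,\rho',\Delta\phi)=\frac{\beta^2}{4\omega\epsilon}\sum_n
\Bigl[-\tfrac{J_n(\beta a)}{H_n^{(2)}(\beta a)}\Bigr]
H_n^{(2)}(\beta\rho')H_n^{(2)}(\beta\rho)\,e^{jn\Delta\phi},
$$

evaluated at complex argument ($\beta=\omega\sqrt{\mu_0\epsilon}$,
blood at 6 GHz: $\beta \approx 925 - 174j$ rad/m). Re-centered on the pixel,
this rod-scatter series is the matched filter of the functional; the
accompanying vignette derives why (and why the free-space series cannot
focus). Synthetic data come from a first-order Born model sharing the same
kernel family, with additive complex white Gaussian noise at a prescribed
SNR, and a differential protocol `SS = S1 - S2` against an anomaly-free
reference. A two-level azimuthal shadow on the element patterns models the
rod's blocking of each element's back half-space — the feature that removes
the 180-degree "ghost" ambiguity.

## Worked example

The bundled two-anomaly scenario places fat cylinders (relative
permittivity 4.94, loss tangent 0.19) at (-4, 3, 4) mm and (4, 1.5, -2) mm
on the wall of a blood-filled artery and runs the full protocol — Born
forward simulation, differential, 20 dB noise, 3D reconstruction on a
0.25 mm grid, thresholding at 0.2 and component detection:

```r
library(lcbp)
res <- run_pipeline(default_scenario("two_anomaly"), seed = 1)
res
#> <lcbp_pipeline> scenario 'two_anomaly', seed 1
#>   2 detections, 2 matched, 0 misses, 0 false alarms
#>   truth detection  error_mm
#> 1     1         1 1.5896957
#> 2     2         2 0.7114434
```

Both anomalies are recovered as exactly one connected component each, with
no misses or false alarms. The centroid errors (1.6 mm and 0.7 mm) reflect
the method's point-spread: blobs hug the curved wall, and the centroid of
an arc sits slightly inward of it — peak positions land within one or two
voxels of the truth. `plot_slices(res$normalized)` renders the standard
nine cut planes; `ghost_metric()`, `find_components()` and
`localization_error()` expose the individual metrics.

A thin command-line wrapper is installed at `inst/cli/lcbp`
(subcommands `simulate`, `reconstruct`, `detect`, `pipeline`), driven by
YAML scenario files such as those under `inst/extdata/`.

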