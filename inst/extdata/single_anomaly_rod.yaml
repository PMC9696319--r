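name: single_anomaly_rod
frequency_hz: 6.0e+09
geometry:
  artery_radius: 5.0
  catheter_radius: 1.5
  rod_radius: 0.8
  dipole_length: 1.8
  n_antennas: 48
media:
  background:
    rel_permittivity: 52.18
    loss_tangent: 0.39
  anomaly_default:
    rel_permittivity: 4.94
    loss_tangent: 0.19
  catheter:
    rel_permittivity: 5.0
    loss_tangent: 0.001
array:
  n_rings: 6
  per_ring: 8
  z_span: 10.0
  orientation: axial
kernel:
  mode: rod_scatter
  forward_mode: rod_total
  n_max: 40
  rel_tol: 1.0e-08
pattern:
  mode: short_dipole_shadowed
  back_lobe_level: 0.05
  g1: 1.0
  g2: 1.0
noise:
  snr_db: 20.0
forward:
  voxel_size: 0.25
  coupling_constant: 1.0
grid:
  spacing: 0.25
  z_min: -5.0
  z_max: 5.0
threshold: 0.2
anomalies:
- center:
  - -4.0
  - 3.0
  - 0.0
  radius: 1.0
  height: 2.0
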