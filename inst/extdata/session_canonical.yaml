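# Canonical scripted biopsy session on the default synthetic phantom:
# scan (0-2.5 s), aim (2.5-3.5 s), insert 30 mm at 5 mm/s (3.5-9.5 s),
# retract (9.5-10 s). Identical to the built-in default trajectory; kept as
# an editable starting point. Coordinates are world mm; the default phantom
# kidney centre is (51.2, 51.2, 38.4) with a 45 mm long semi-axis along x.
seed: 1
duration_s: 10.0
phantom:
  dims: [128, 128, 96]
  spacing: [0.8, 0.8, 0.8]
  semi_axes: [45.0, 25.0, 25.0]
  sigma_s: 0.5
material:
  E_pa: 1.0e5
  nu: 0.3
  rho: 1050.0
  rayleigh_alpha: 1.0
  rayleigh_beta: 0.01
solver:
  dt: 0.016666666666666666
  cg_tol: 1.0e-8
  cg_maxiter: 500
needle:
  length_mm: 150.0
  coupling:
    d_thr_mm: 4.0
    k_perp: 0.3
    mu_viscous: 0.05
    f_coulomb: 0.02
    f_puncture: 1.5
    k_membrane: 0.5
    drop_factor: 0.3
view:
  width_px: 128
  height_px: 96
  pixel_spacing_mm: 1.0
  slab_halfthickness_mm: 2.0
overlay:
  amplitude: 200.0
  sigma_mm: 0.6
haptics:
  rate_hz: 1000
  smoothing_window: 1
trajectory:
  interpolation: linear
  duration: 10.0
  keyframes:
    - t: 0.0
      probe_centre: [51.2, 51.2, 28.4]
      tip: [121.2, 51.2, 38.4]
      dir: [-1.0, 0.0, 0.0]
    - t: 2.5
      probe_centre: [51.2, 51.2, 38.4]
      tip: [121.2, 51.2, 38.4]
      dir: [-1.0, 0.0, 0.0]
    - t: 3.5
      probe_centre: [51.2, 51.2, 38.4]
      tip: [101.2, 51.2, 38.4]
      dir: [-1.0, 0.0, 0.0]
    - t: 9.5
      probe_centre: [51.2, 51.2, 38.4]
      tip: [71.2, 51.2, 38.4]
      dir: [-1.0, 0.0, 0.0]
    - t: 10.0
      probe_centre: [51.2, 51.2, 38.4]
      tip: [121.2, 51.2, 38.4]
      dir: [-1.0, 0.0, 0.0]
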