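geometry:
  parent_length_cm: 0.72
  daughter_length_cm: 1.2
  parent_diameter_cm: 0.56
  daughter_diameter_cm: 0.45
  bifurcation_angle_deg: 35.0
  daughter_curvature_radius_cm: 1.43
  carinal_radius_cm: 0.1
calibration:
  et_a_diff: 21.94
  unattached_fraction:
    po218: 0.52
    pb214: 0.31
    bi214: 0.186
  attached_gm_nm: 275.0
  attached_gsd: 2.0
  alveolar_mixing: 0.1
  slow_zone_depth: 0.9985
  slow_zone_sigma_mm: 2.55
  slow_zone_shape: 0.9
  hotspot_weight_inhalation: 0.8
  hotspot_weight_exhalation: 0.05
  hotspot_sigma_mm: 0.2515
exposure:
  radon_Bq_m3: 46.0
  ratios:
  - 0.58
  - 0.44
  - 0.29
  equilibrium_factor: 0.4
  number_concentration_m3:
  - 7820.0
  - 51270.0
  - 25090.0
mucus_metadata:
  mucus_density_kg_m3: 100.0
  mucus_viscosity_Pa_s: 1.0
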