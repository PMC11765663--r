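# Example run configuration: two survey scanners 90 degrees apart,
# scanning a 5 cm cylinder (vertical axis) at 100 m and 50 m.
seed: 1
tangent_lines: 1000
max_updates: 10
ransac_subsets: 100
scanners:
  - position: [0, 100, 0]
    exit_diameter_m: 0.00212
    divergence_half_angle_rad: 0.00015
    base_range_sigma_m: 0.001
    angular_step_deg: 0.018
  - position: [50, 0, 0]
    exit_diameter_m: 0.00212
    divergence_half_angle_rad: 0.00015
    base_range_sigma_m: 0.001
    angular_step_deg: 0.018
truth:
  radius_m: 0.05
  azimuth_deg: 0
  elevation_deg: 90
  center: [0, 0, 0]
  length_m: 0.25
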