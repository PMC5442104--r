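# Example radca configuration: conventional 2 Gy daily arm.
# Any omitted field takes the package default (see default_config()).
seed: 1

geometry:
  grid_side: 600          # pixels (15 um each)
  tumour_radius_px: 50    # 1.5 mm diameter disk, 7845 cells
  normal_fraction: 0.20
  vessel_density: 0.038
  n_layers: 3

oxygen:
  sigma: 2.4              # px; diffusion coefficient D = sigma^2 = 5.76 px^2
  s: 0.02356              # wall amplitude calibrated to 3% mean tumour O2
  cap: 0.05
  hypoxia_threshold: 0.002

radiobiology:
  alpha: 0.0441           # tumour LQ at 21% O2, 1/Gy
  beta: 0.0898            # 1/Gy^2
  hrf_m: 2.804
  hrf_K: 0.001076
  # surrogate endothelial LQ coefficients (vessel hit probability);
  # replace with values fitted from endothelial clonogenic data
  alpha_ec: 0.28
  beta_ec: 0.045
  leak_factor: 1.5
  vessel_death_threshold: 6
  vessel_death_max: 35
  arrest_slope: 9         # h/Gy (36 h after 4 Gy)

protocol:
  frac_dose: 2
  total_dose: 20
  interval_days: 1
  start_day: 21           # a Monday
  weekends_off: true
  horizon_days: 80

cohort:
  n_mice: 100
  scenario: dlo_vperf_vdeath

output:
  dir: radca-out
  snapshots: true
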