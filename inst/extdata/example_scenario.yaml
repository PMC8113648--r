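# Example socesim scenario: two IP3Rs open next to the junction, all five
# ORAI1 channels present and gated by the sensed ER Ca2+, slow ER diffusion.
# Solve with: solve_steady(read_scenario_config("example_scenario.yaml"))
geometry:
  box_side: 400
  gap: 15
  junction_radius: 100
  cone_top_radius: 100
  cone_bottom_radius: 200
  cone_depth: 485
layout:
  n_orai: 5
  orai_ring_radius: 40
  n_serca: 10
  serca_ring_radius: 70
  n_ip3r: 8
  ip3r_depth: 90
  sensing_edge: 108
params:
  D_C: 220
  D_S: 10
gating:
  thresholds: [360, 250, 150]
  fractions: [0.21, 0.50, 0.79, 1.00]
scenario:
  mode: steady
  open_orai: [1, 2, 3, 4, 5]
  open_ip3r: [1, 2]
  orai_gated_by_sensing: true
  event_window_ms: [0, 44]
  snapshot_times_ms: [22]
mesh:
  target_h_patch: 10
  target_h_bulk: 30
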