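{
  "pulse_delay_ns": 450,
  "sound_speed_m_s": 1500,
  "digitizer_rate_MHz": 250,
  "prf_kHz": 500,
  "bscan_rate_Hz": 300,
  "slow_step_um": 5,
  "channel_range_mm": 14,
  "overlap_mm": 4,
  "fov_fast_mm": 24,
  "fov_slow_mm": 22.5,
  "rpm": 3000,
  "depth_of_focus_mm": 0.221,
  "lateral_res_um": 7.5,
  "axial_res_um": 33,
  "transducer_center_MHz": 30,
  "depth_range_mm": 2,
  "arc_sag_mm": 0.3,
  "lattice_um": 5,
  "geometry": {
    "radius_mm": 7,
    "beam_offset_mm": 5,
    "n_facets": 6,
    "facet_width_mm": 7,
    "facet_height_mm": 10
  }
}
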