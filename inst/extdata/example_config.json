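{
  "wound_edge": [[0, -200], [0, 200]],
  "ap_axis": [-1, 0],
  "scale": 1.0,
  "frame_interval": 1.0,
  "classify_threshold": 200,
  "arrival_radius": 20,
  "recruit_band": 200,
  "t_start": 60
}
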