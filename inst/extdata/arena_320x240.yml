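arena_rect:
  x0: 8.0
  y0: 29.621621621622
  width: 304.0
  height: 180.756756756757
px_per_cm: 8.216216216216
frame_rate: 30.0
stimulus_zones:
  stim1:
  - - 106.594594594595
    - 29.621621621622
  - - 8.0
    - 128.216216216216
  stim2:
  - - 213.405405405405
    - 210.378378378378
  - - 312.0
    - 111.783783783784
compartments:
  compartment1:
  - - 8.0
    - 29.621621621622
  - - 196.151351351351
    - 29.621621621622
  - - 123.848648648649
    - 210.378378378378
  - - 8.0
    - 210.378378378378
  compartment2:
  - - 196.151351351351
    - 29.621621621622
  - - 312.0
    - 29.621621621622
  - - 312.0
    - 210.378378378378
  - - 123.848648648649
    - 210.378378378378
contact_distance_px: 2.0
detection_threshold_low: 90.0
detection_threshold_high: 160.0
min_blob_area_px: 50.0
max_cable_width_px: 2.0
gap_merge_s: 0.5
bin_width_s: 20.0
arena_size_cm:
- 37.0
- 22.0
invert: no
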