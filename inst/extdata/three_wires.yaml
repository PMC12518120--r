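# Three-wire water-tank validation scene: on-axis copper wires at
# 34/37/40 mm imaged with a single plane wave in water.
phantom:
  wire_depths_mm: [34, 37, 40]
  n_diffuse: 0
acquisition:
  noise_snr_db: 40
  attenuation_db_mhz_cm: 0
imaging:
  dynamic_range_db: 30
  n_averages: 10
seed: 7
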