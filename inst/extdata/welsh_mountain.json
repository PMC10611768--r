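{
  "breed": "Welsh Mountain",
  "diameter_um": 36,
  "perimeter_per_100um": 542,
  "spi": 15.1,
  "scale_count": 12,
  "pattern": "coronal_reticulate"
}
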