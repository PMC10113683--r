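{
  "n_pairs_stored": 15140,
  "n_marker_detected": 13244,
  "n_markerless_predicted": 10242,
  "n_compared": 8993
}
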