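regimen:
  route: oral
  dose_mg: 40.0
  start_time_h: 0.0
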