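regimen:
  route: iv_infusion
  dose_mg: 9.9
  infusion_duration_h: 0.5
  start_time_h: 0.0
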