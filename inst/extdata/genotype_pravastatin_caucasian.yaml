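genotype:
  frequencies:
    star1a: 0.56
    star1b: 0.26
    star15: 0.18
  activity_ratio_1b: 0.81
  activity_ratio_15: 0.35
  expression_mult_1b: 2.0
  expression_mult_15: 1.0
  f_OATP1B1: 0.83
  ethnic_scalar: 1.0
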