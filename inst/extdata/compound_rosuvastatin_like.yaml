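compound:
  name: rosuvastatin_like
  fu_p: 0.12
  RB_P: 0.69
  fu_liver: 0.1
  CL_renal_L_per_h: 10.0
  CL_act_tot_L_per_h: 300.0
  CL_bile_L_per_h: 120.0
  CL_pass_liver_L_per_h: 12.0
  pass_ratio_muscle: 2.0
  pass_ratio_adipose: 1.0
  ka_per_h: 0.12
  FaFg: 0.5
  Kp:
    lung: 0.8
    gut: 2.0
    spleen: 1.0
    kidney: 3.0
    rest_of_body: 3.0
    muscle: 2.5
    adipose: 0.4
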