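compound:
  name: pravastatin_like
  fu_p: 0.5
  RB_P: 0.55
  fu_liver: 0.2
  CL_renal_L_per_h: 22.0
  CL_act_tot_L_per_h: 90.0
  CL_bile_L_per_h: 30.0
  CL_pass_liver_L_per_h: 4.0
  pass_ratio_muscle: 2.0
  pass_ratio_adipose: 1.0
  ka_per_h: 0.5
  FaFg: 0.46
  Kp:
    lung: 0.4
    gut: 1.1
    spleen: 0.7
    kidney: 2.0
    rest_of_body: 1.5
    muscle: 0.6
    adipose: 0.15
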