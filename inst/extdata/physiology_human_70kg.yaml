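physiology:
  body_weight_kg: 70.0
  tissue_volumes_L:
    lung: 0.5
    adipose: 18.0
    muscle: 29.0
    gut: 1.2
    spleen: 0.15
    kidney: 0.31
    liver: 1.8
    rest_of_body: 10.0
    arterial_blood: 1.7
    venous_blood: 3.9
  tissue_blood_flows_L_per_h:
    lung: 390.0
    adipose: 20.0
    muscle: 45.0
    gut: 60.0
    spleen: 15.0
    kidney: 70.0
    liver: 97.0
    rest_of_body: 158.0
  n_liver_subunits: 5
  liver_blood_fraction: 0.16
  muscle_ec_fraction: 0.1
  adipose_ec_fraction: 0.05
  bile_flow_mL_per_day: 350.0
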