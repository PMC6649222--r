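# Healthy-lung reference: standard intraoperative ventilation under general
# anesthesia, near-zero shunt, no extracorporeal support.
name: healthy_no_ecmo
patient:
  cardiac_output: 5
  hb: 14
  vo2: 250
  vco2: 200
  shunt_fraction: 0.03
  hco3: 24
  ideal_body_weight: 60
vent:
  mode: VCV
  peep: 5
  vt_ml: 500
  rr: 12
  t_insp: 1.0
  raw: 8
  cst: 50
  fio2: 0.4
ecmo:
  blood_flow: 0
  sweep_flow: 0
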