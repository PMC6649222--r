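# Severe ARDS on protective ventilation, before ECMO cannulation.
# Refractory hypoxemia on FiO2 1.0 despite proning and recruitment; the
# shunt fraction (0.80) is set so that oxygen delivery still just meets
# consumption without extracorporeal support.
name: protective_preecmo
patient:
  cardiac_output: 10      # L/min
  hb: 10                  # g/dL
  vo2: 200                # mL/min
  vco2: 160               # mL/min
  shunt_fraction: 0.80
  hco3: 24                # mEq/L
  ideal_body_weight: 60   # kg
vent:
  mode: VCV
  peep: 18                # cmH2O
  vt_ml: 360              # mL (6 mL/kg IBW); Pplat 38 -> Cst 18
  rr: 35                  # breaths/min
  t_insp: 0.6             # s
  raw: 10                 # cmH2O/L/s
  cst: 18                 # mL/cmH2O
  fio2: 1.0
  dead_space: 240         # mL; Vd/Vt 0.67, typical of severe ARDS
ecmo:
  blood_flow: 0           # L/min - not yet cannulated
  sweep_flow: 0
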