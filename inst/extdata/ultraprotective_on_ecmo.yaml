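# Same patient after VV-ECMO initiation: ultraprotective pressure-controlled
# ventilation with the circuit carrying gas exchange. The membrane CO2
# efficiency is the device model's calibration parameter; here it is
# calibrated once so that the steady-state arterial PCO2 reproduces the
# scenario's blood gas (PaCO2 35 mmHg).
name: ultraprotective_on_ecmo
patient:
  cardiac_output: 10      # L/min
  hb: 10                  # g/dL
  vo2: 200                # mL/min
  vco2: 160               # mL/min
  shunt_fraction: 0.95
  hco3: 24                # mEq/L
  ideal_body_weight: 60   # kg
vent:
  mode: PCV
  peep: 14                # cmH2O
  driving_pressure: 10    # cmH2O -> Vt 140 mL at Cst 14
  rr: 10                  # breaths/min
  t_insp: 1.0             # s
  raw: 10                 # cmH2O/L/s
  cst: 14                 # mL/cmH2O
  fio2: 0.3
ecmo:
  blood_flow: 4.9         # L/min
  sweep_flow: 3           # L/min
  sweep_fio2: 1.0
  membrane_o2_efficiency: 1.0
  membrane_co2_efficiency: 0.85
  recirculation_fraction: 0
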