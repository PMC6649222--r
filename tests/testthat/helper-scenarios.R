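# Shared builders for the prototypical severe-ARDS case used across tests.

proto_patient <- function(...) {
  args <- utils::modifyList(
    list(cardiac_output = 10, hb = 10, vo2 = 200, vco2 = 160,
         shunt_fraction = 0.95, hco3 = 24, ideal_body_weight = 60),
    list(...)
  )
  do.call(patient_params, args)
}

ultraprotective_vent <- function(...) {
  args <- utils::modifyList(
    list(mode = "PCV", peep = 14, driving_pressure = 10, rr = 10,
         t_insp = 1, raw = 10, cst = 14, fio2 = 0.3),
    list(...)
  )
  do.call(vent_settings, args)
}

protective_vent <- function(...) {
  args <- utils::modifyList(
    list(mode = "VCV", peep = 18, vt_ml = 360, rr = 35, t_insp = 0.6,
         raw = 10, cst = 18, fio2 = 1.0, dead_space = 240),
    list(...)
  )
  do.call(vent_settings, args)
}

proto_ecmo <- function(...) {
  args <- utils::modifyList(
    list(blood_flow = 4.9, sweep_flow = 3, sweep_fio2 = 1,
         membrane_o2_efficiency = 1, membrane_co2_efficiency = 0.85,
         recirculation_fraction = 0),
    list(...)
  )
  do.call(ecmo_settings, args)
}

no_ecmo <- function() ecmo_settings(blood_flow = 0, sweep_flow = 0)
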