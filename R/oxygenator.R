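#' ECMO circuit settings
#'
#' Membrane-oxygenator and circuit configuration. Oxygen transfer is
#' modelled as fractional equilibration of blood PO2 toward the sweep-gas
#' PO2 with a single efficiency parameter; CO2 removal as sweep-gas
#' equilibration to inlet blood PCO2 scaled by its own efficiency and capped
#' by the blood-side CO2 content. Both efficiencies default to 1 (fresh
#' membrane) and are the principal calibration parameters of the device
#' model.
#'
#' @param blood_flow ECMO blood flow (L/min), >= 0.
#' @param sweep_flow Sweep gas flow (L/min), >= 0.
#' @param sweep_fio2 Oxygen fraction of the sweep gas, in [0.21, 1].
#' @param membrane_o2_efficiency,membrane_co2_efficiency Fractional
#'   equilibration efficiencies in (0, 1].
#' @param recirculation_fraction Fraction of ECMO return blood re-drained
#'   without transiting the patient, in [0, 1).
#' @return An object of class `ecmo_settings`.
#' @export
#' @examples
#' ecmo_settings(blood_flow = 4.9, sweep_flow = 3, sweep_fio2 = 1)
ecmo_settings <- function(blood_flow, sweep_flow, sweep_fio2 = 1,
                          membrane_o2_efficiency = 1,
                          membrane_co2_efficiency = 1,
                          recirculation_fraction = 0) {
  if (blood_flow < 0 || sweep_flow < 0) {
    stop("flows must be >= 0", call. = FALSE)
  }
  if (sweep_fio2 < 0.21 || sweep_fio2 > 1) {
    stop("sweep_fio2 must lie in [0.21, 1]", call. = FALSE)
  }
  if (membrane_o2_efficiency <= 0 || membrane_o2_efficiency > 1 ||
      membrane_co2_efficiency <= 0 || membrane_co2_efficiency > 1) {
    stop("membrane efficiencies must lie in (0, 1]", call. = FALSE)
  }
  if (recirculation_fraction < 0 || recirculation_fraction >= 1) {
    stop("recirculation_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(blood_flow = blood_flow, sweep_flow = sweep_flow,
         sweep_fio2 = sweep_fio2,
         membrane_o2_efficiency = membrane_o2_efficiency,
         membrane_co2_efficiency = membrane_co2_efficiency,
         recirculation_fraction = recirculation_fraction),
    class = "ecmo_settings"
  )
}

#' @export
print.ecmo_settings <- function(x, ...) {
  cat(sprintf(
    "ecmo_settings: blood flow %g L/min, sweep %g L/min (FiO2 %.2f), eff O2 %.2f / CO2 %.2f, recirc %.2f\n",
    x$blood_flow, x$sweep_flow, x$sweep_fio2, x$membrane_o2_efficiency,
    x$membrane_co2_efficiency, x$recirculation_fraction
  ))
  invisible(x)
}

#' Single-pass blood oxygenation and decarboxylation across the membrane
#'
#' Outlet PO2 moves a fraction `membrane_o2_efficiency` of the way from the
#' inlet PO2 to the sweep-gas PO2 `sweep_fio2 * (Pb - PH2O)`; saturation is
#' recomputed from the outlet PO2, the outlet PCO2/pH come from
#' [co2_removal()], and hemoglobin is unchanged.
#'
#' @param inlet Inlet [blood_state()].
#' @param e [ecmo_settings()] with `blood_flow > 0` (zero blood flow is an
#'   identity pass-through with zero transfer).
#' @param hco3 Patient bicarbonate (mEq/L) for the acid-base closure.
#' @param konst [gas_constants()].
#' @return Outlet [blood_state()].
#' @export
oxygenate <- function(inlet, e, hco3 = 24, konst = gas_constants()) {
  stopifnot(inherits(inlet, "blood_state"), inherits(e, "ecmo_settings"))
  if (e$blood_flow <= 0) return(inlet)
  target_po2 <- e$sweep_fio2 *
    (konst$barometric_pressure - konst$water_vapor_pressure)
  out_po2 <- inlet$po2 + e$membrane_o2_efficiency * (target_po2 - inlet$po2)
  co2 <- co2_removal(inlet, e, hco3 = hco3, konst = konst)
  out_content <- inlet$co2_content - co2$vco2_removed / (e$blood_flow * 10)
  out_content <- max(out_content,
                     co2_content(0.01, ph_closed(0.01, hco3, konst),
                                 inlet$hb, inlet$sat, konst))
  # outlet PCO2 re-inverted at the *outlet* saturation so the pass conserves
  # CO2 mass exactly despite the Haldane shift of the oxygenated blood
  pco2_out <- co2$outlet_pco2
  sat_out <- inlet$sat
  for (i in 1:6) {
    ph_out <- ph_closed(pco2_out, hco3, konst)
    sat_out <- sat_from_po2(out_po2, ph_out, pco2_out)
    f <- function(p) {
      co2_content(p, ph_closed(p, hco3, konst), inlet$hb, sat_out, konst) -
        out_content
    }
    new_pco2 <- stats::uniroot(f, c(1e-6, max(500, inlet$pco2)),
                               tol = 1e-10)$root
    if (abs(new_pco2 - pco2_out) < 1e-8) {
      pco2_out <- new_pco2
      break
    }
    pco2_out <- new_pco2
  }
  ph_out <- ph_closed(pco2_out, hco3, konst)
  blood_state(out_po2, pco2_out, ph_out, inlet$hb,
              sat = sat_from_po2(out_po2, ph_out, pco2_out), konst = konst)
}

#' Oxygen transfer rate across the membrane
#'
#' `blood_flow * 10 * (outlet O2 content - inlet O2 content)` (the factor 10
#' converts mL/dL x L/min to mL/min).
#'
#' @param inlet,outlet [blood_state()] before and after the membrane; same
#'   hemoglobin.
#' @param blood_flow Blood flow through the membrane (L/min).
#' @return O2 transfer (mL O2/min).
#' @export
o2_transfer_rate <- function(inlet, outlet, blood_flow) {
  stopifnot(inherits(inlet, "blood_state"), inherits(outlet, "blood_state"))
  if (abs(inlet$hb - outlet$hb) > 1e-9) {
    stop("inlet and outlet hemoglobin differ", call. = FALSE)
  }
  blood_flow * 10 * (outlet$o2_content - inlet$o2_content)
}

#' Sweep-gas CO2 removal
#'
#' The gas side can carry at most
#' `sweep_flow * 1000 * efficiency * inlet_pco2 / (Pb - PH2O)` mL/min
#' (sweep gas equilibrated to inlet blood PCO2, scaled by the membrane CO2
#' efficiency); the blood side can yield at most its whole CO2 content,
#' `blood_flow * 10 * inlet_co2_content`. Removal is the minimum of the
#' two; the outlet PCO2 is recovered by inverting the content formula.
#'
#' @inheritParams oxygenate
#' @return A list with `vco2_removed` (mL/min) and `outlet_pco2` (mmHg).
#' @export
co2_removal <- function(inlet, e, hco3 = 24, konst = gas_constants()) {
  stopifnot(inherits(inlet, "blood_state"), inherits(e, "ecmo_settings"))
  if (e$blood_flow <= 0 || e$sweep_flow <= 0) {
    return(list(vco2_removed = 0, outlet_pco2 = inlet$pco2))
  }
  p_dry <- konst$barometric_pressure - konst$water_vapor_pressure
  gas_side <- e$sweep_flow * 1000 * e$membrane_co2_efficiency *
    inlet$pco2 / p_dry
  blood_side <- e$blood_flow * 10 * inlet$co2_content
  removed <- min(gas_side, blood_side)
  out_content <- inlet$co2_content - removed / (e$blood_flow * 10)
  # degenerate corner: sweep capacity ~ whole blood-side content; floor the
  # outlet at PCO2 = 0.01 mmHg so the inversion stays bracketed
  floor_content <- co2_content(0.01, ph_closed(0.01, hco3, konst),
                               inlet$hb, inlet$sat, konst)
  if (out_content <= floor_content) {
    out_content <- floor_content
    removed <- e$blood_flow * 10 * (inlet$co2_content - out_content)
  }
  # invert along the fixed-bicarbonate pH closure so the outlet state is
  # acid-base consistent
  f <- function(p) {
    co2_content(p, ph_closed(p, hco3, konst), inlet$hb, inlet$sat, konst) -
      out_content
  }
  out_pco2 <- stats::uniroot(f, c(1e-6, max(500, inlet$pco2)),
                             tol = 1e-10)$root
  list(vco2_removed = removed, outlet_pco2 = out_pco2)
}
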