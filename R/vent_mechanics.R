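#' Ventilator settings
#'
#' Configuration of the mechanical ventilator. Tidal volume follows
#' `Vt = driving_pressure * cst`; when a scenario prescribes the tidal
#' volume instead (volume-controlled ventilation), supply `vt_ml` and the
#' driving pressure is back-computed as `vt_ml / cst`.
#'
#' @param mode `"PCV"` or `"VCV"`; affects only the optional resistive
#'   power term.
#' @param peep Positive end-expiratory pressure (cmH2O), >= 0.
#' @param driving_pressure Plateau minus PEEP (cmH2O), > 0. Exactly one of
#'   `driving_pressure` and `vt_ml` must be given.
#' @param vt_ml Tidal volume (mL); alternative to `driving_pressure`.
#' @param rr Respiratory rate (breaths/min), >= 0.
#' @param t_insp Inspiratory time (s), > 0 and < 60/rr.
#' @param raw Airway resistance (cmH2O/L/s), >= 0.
#' @param cst Static respiratory-system compliance (mL/cmH2O), > 0.
#' @param fio2 Inspired oxygen fraction, in [0.21, 1].
#' @param dead_space Physiologic dead space (mL); `NA` means "resolve from
#'   the patient's ideal body weight at 2.2 mL/kg".
#' @return An object of class `vent_settings`.
#' @export
#' @examples
#' # ultraprotective ventilation on ECMO support
#' vent_settings(mode = "PCV", peep = 14, driving_pressure = 10, rr = 10,
#'               t_insp = 1, cst = 14, fio2 = 0.3)
vent_settings <- function(mode = c("PCV", "VCV"), peep, driving_pressure = NULL,
                          vt_ml = NULL, rr, t_insp = 1, raw = 10, cst,
                          fio2 = 0.21, dead_space = NA_real_) {
  mode <- match.arg(mode)
  if (is.null(driving_pressure) == is.null(vt_ml)) {
    stop("supply exactly one of driving_pressure and vt_ml", call. = FALSE)
  }
  if (cst <= 0) stop("cst must be positive", call. = FALSE)
  if (is.null(driving_pressure)) driving_pressure <- vt_ml / cst
  if (peep < 0 || driving_pressure <= 0 || rr < 0 || t_insp <= 0 || raw < 0) {
    stop("invalid ventilator setting: need peep >= 0, driving_pressure > 0, ",
         "rr >= 0, t_insp > 0, raw >= 0", call. = FALSE)
  }
  if (rr > 0 && t_insp >= 60 / rr) {
    stop("t_insp must be shorter than the respiratory cycle 60/rr",
         call. = FALSE)
  }
  if (fio2 < 0.21 || fio2 > 1) {
    stop("fio2 must lie in [0.21, 1]", call. = FALSE)
  }
  if (!is.na(dead_space) && dead_space < 0) {
    stop("dead_space must be >= 0", call. = FALSE)
  }
  structure(
    list(mode = mode, peep = peep, driving_pressure = driving_pressure,
         rr = rr, t_insp = t_insp,
         ie_ratio = if (rr > 0) t_insp / (60 / rr - t_insp) else NA_real_,
         raw = raw, cst = cst, fio2 = fio2, dead_space = dead_space),
    class = "vent_settings"
  )
}

#' Tidal volume implied by ventilator settings
#'
#' @param v [vent_settings()].
#' @return Tidal volume (L): `driving_pressure * cst / 1000`.
#' @export
#' @examples
#' tidal_volume(vent_settings(peep = 14, driving_pressure = 10, rr = 10,
#'                            cst = 14)) # 0.14 L
tidal_volume <- function(v) {
  stopifnot(inherits(v, "vent_settings"))
  v$driving_pressure * v$cst / 1000
}

#' Static respiratory-system compliance from a volume-controlled breath
#'
#' `Cst = Vt / (Pplat - PEEP)`, the bedside estimate from an
#' end-inspiratory hold.
#'
#' @param vt_ml Tidal volume (mL).
#' @param pplat Plateau pressure (cmH2O).
#' @param peep PEEP (cmH2O); must be below `pplat`.
#' @return Compliance (mL/cmH2O).
#' @export
#' @examples
#' static_compliance(360, 38, 18) # 18 mL/cmH2O
static_compliance <- function(vt_ml, pplat, peep) {
  if (vt_ml <= 0) stop("vt_ml must be positive", call. = FALSE)
  if (pplat <= peep) stop("pplat must exceed peep", call. = FALSE)
  vt_ml / (pplat - peep)
}

#' Mechanical power delivered by the ventilator to the lungs
#'
#' Energy per minute transferred to the respiratory system. The default is
#' the elastic term only: energy per breath `Vt * (PEEP + DP/2)` (L x cmH2O),
#' converted with 0.098 J per L.cmH2O and scaled by the respiratory rate:
#' \deqn{MP = 0.098 \cdot RR \cdot Vt \cdot (PEEP + DP/2)\quad [J/min].}
#' With `include_resistive = TRUE` a constant-flow resistive term
#' `0.098 * rr * Vt * raw * (Vt / t_insp)` is added. The
#' inspiratory-to-expiratory ratio enters only through that optional term,
#' so its effect on power is small.
#'
#' @param v [vent_settings()].
#' @param include_resistive Add the resistive dissipation term
#'   (default `FALSE`).
#' @return Mechanical power (J/min); 0 when `rr = 0`.
#' @export
#' @examples
#' # ultraprotective: PEEP 14, DP 10, Cst 14, RR 10 -> ~2.6 J/min
#' mechanical_power(vent_settings(peep = 14, driving_pressure = 10, rr = 10,
#'                                cst = 14))
mechanical_power <- function(v, include_resistive = FALSE) {
  stopifnot(inherits(v, "vent_settings"))
  if (v$rr == 0) return(0)
  vt <- tidal_volume(v)
  mp <- 0.098 * v$rr * vt * (v$peep + v$driving_pressure / 2)
  if (include_resistive) {
    mp <- mp + 0.098 * v$rr * vt * v$raw * (vt / v$t_insp)
  }
  mp
}

#' Alveolar oxygen partial pressure
#'
#' Alveolar gas equation,
#' `fio2 * (Pb - PH2O) - paco2 / RQ`, floored at 1 mmHg.
#'
#' @param fio2 Inspired oxygen fraction in [0.21, 1].
#' @param paco2 Alveolar (~arterial) PCO2 (mmHg), > 0.
#' @param konst [gas_constants()].
#' @return Alveolar PO2 (mmHg), >= 1.
#' @export
#' @examples
#' alveolar_po2(0.21, 40) # 99.7 mmHg, room air
alveolar_po2 <- function(fio2, paco2, konst = gas_constants()) {
  if (any(fio2 < 0.21) || any(fio2 > 1)) {
    stop("fio2 must lie in [0.21, 1]", call. = FALSE)
  }
  if (any(paco2 <= 0)) stop("paco2 must be positive", call. = FALSE)
  pio2 <- fio2 * (konst$barometric_pressure - konst$water_vapor_pressure)
  pmax(1, pio2 - paco2 / konst$respiratory_quotient)
}

#' Alveolar ventilation
#'
#' `rr * max(0, Vt - dead_space) / 1000`; the native lung's CO2 clearance
#' capacity. Under ultraprotective settings the tidal volume barely exceeds
#' the dead space and alveolar ventilation collapses toward zero.
#'
#' @param v [vent_settings()].
#' @param dead_space Dead space (mL); overrides `v$dead_space` (used by the
#'   solver to resolve the per-patient default of 2.2 mL/kg ideal body
#'   weight).
#' @return Alveolar ventilation (L/min).
#' @export
alveolar_ventilation <- function(v, dead_space = v$dead_space) {
  stopifnot(inherits(v, "vent_settings"))
  if (is.na(dead_space)) {
    stop("dead_space unset: supply it or resolve from ideal body weight",
         call. = FALSE)
  }
  vt_ml <- 1000 * tidal_volume(v)
  v$rr * max(0, vt_ml - dead_space) / 1000
}

#' @export
print.vent_settings <- function(x, ...) {
  cat(sprintf(
    "vent_settings (%s): PEEP %g, DP %g cmH2O, Vt %.0f mL, RR %g/min, Tinsp %g s, FiO2 %.2f\n",
    x$mode, x$peep, x$driving_pressure, 1000 * tidal_volume(x), x$rr,
    x$t_insp, x$fio2
  ))
  invisible(x)
}
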