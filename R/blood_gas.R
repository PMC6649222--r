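#' Physical and chemical gas constants
#'
#' Bundle of the standard constants used throughout the gas-exchange model.
#' All model functions accept a `konst` argument so that non-standard
#' barometric conditions can be explored; defaults are sea-level, 37 degC.
#'
#' @param barometric_pressure Barometric pressure (mmHg).
#' @param water_vapor_pressure Saturated water vapor pressure at body
#'   temperature (mmHg).
#' @param respiratory_quotient Respiratory quotient (VCO2/VO2) used in the
#'   alveolar gas equation.
#' @param hufner Huefner constant: mL O2 bound per g hemoglobin at full
#'   saturation.
#' @param o2_solubility Plasma O2 solubility (mL O2/dL/mmHg).
#' @param co2_solubility Plasma CO2 solubility (mmol/L/mmHg).
#' @param pk_prime Apparent pK of the bicarbonate buffer system.
#' @return An object of class `gas_constants` (a named list).
#' @export
#' @examples
#' gas_constants()
gas_constants <- function(barometric_pressure = 760,
                          water_vapor_pressure = 47,
                          respiratory_quotient = 0.8,
                          hufner = 1.34,
                          o2_solubility = 0.0031,
                          co2_solubility = 0.0307,
                          pk_prime = 6.1) {
  k <- list(
    barometric_pressure = barometric_pressure,
    water_vapor_pressure = water_vapor_pressure,
    respiratory_quotient = respiratory_quotient,
    hufner = hufner,
    o2_solubility = o2_solubility,
    co2_solubility = co2_solubility,
    pk_prime = pk_prime
  )
  for (nm in names(k)) {
    if (!is.numeric(k[[nm]]) || length(k[[nm]]) != 1L || !is.finite(k[[nm]]) ||
        k[[nm]] <= 0) {
      stop("gas constant '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  structure(k, class = "gas_constants")
}

# mmol/L -> mL (STPD) /dL conversion for CO2 (22.26 mL/mmol over 10 dL/L)
MMOL_TO_MLDL <- 2.226

#' Hemoglobin saturation from oxygen partial pressure
#'
#' Severinghaus oxyhemoglobin dissociation curve,
#' \eqn{S = 1/(1 + 23400/(p^3 + 150 p))}, evaluated at a virtual PO2 shifted
#' for the Bohr effect:
#' \eqn{p_v = PO2 \cdot 10^{0.40 (pH - 7.40) + 0.06 (\log_{10} 40 - \log_{10} PCO2)}}.
#' Temperature is fixed at 37 degC.
#'
#' @param po2 Oxygen partial pressure (mmHg), > 0. Vectorized.
#' @param ph Blood pH.
#' @param pco2 CO2 partial pressure (mmHg), used for the Bohr shift.
#' @return Fractional hemoglobin saturation in (0, 1).
#' @seealso [po2_from_sat()] for the inverse.
#' @export
#' @examples
#' sat_from_po2(100, 7.40, 40) # 0.9775
#' sat_from_po2(26.86, 7.40, 40) # ~0.50 (P50 of the standard curve)
sat_from_po2 <- function(po2, ph = 7.40, pco2 = 40) {
  if (any(!is.finite(po2)) || any(po2 <= 0)) {
    stop("po2 must be positive and finite", call. = FALSE)
  }
  if (any(pco2 <= 0)) stop("pco2 must be positive", call. = FALSE)
  shift <- 0.40 * (ph - 7.40) + 0.06 * (log10(40) - log10(pco2))
  pv <- po2 * 10^shift
  1 / (1 + 23400 / (pv^3 + 150 * pv))
}

#' Oxygen partial pressure from hemoglobin saturation
#'
#' Numerical inverse of [sat_from_po2()] on (0.1, 800] mmHg.
#'
#' @param sat Fractional saturation, strictly in (0, 1).
#' @inheritParams sat_from_po2
#' @return PO2 (mmHg); round-trip error below 0.01 mmHg.
#' @export
#' @examples
#' po2_from_sat(0.5, 7.40, 40) # ~26.86
po2_from_sat <- function(sat, ph = 7.40, pco2 = 40) {
  if (length(sat) != 1L || !is.finite(sat) || sat <= 0 || sat >= 1) {
    stop("sat must be a single value strictly between 0 and 1", call. = FALSE)
  }
  lo <- 1e-3
  hi <- 800
  f <- function(p) sat_from_po2(p, ph, pco2) - sat
  if (f(hi) < 0) {
    stop("po2_from_sat: saturation ", sat,
         " not bracketed on (0, 800] mmHg at ph=", ph, ", pco2=", pco2,
         call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Blood oxygen content
#'
#' Hemoglobin-bound plus dissolved oxygen:
#' `hufner * hb * sat + o2_solubility * po2`.
#'
#' @param hb Hemoglobin (g/dL), > 0.
#' @param sat Fractional saturation in [0, 1].
#' @param po2 PO2 (mmHg), >= 0.
#' @param konst [gas_constants()].
#' @return O2 content (mL O2/dL blood).
#' @export
#' @examples
#' o2_content(10, 0.84, 52) # 11.42, on-ECMO arterial blood
o2_content <- function(hb, sat, po2, konst = gas_constants()) {
  if (any(hb <= 0) || any(sat < 0) || any(sat > 1) || any(po2 < 0)) {
    stop("o2_content: need hb > 0, sat in [0,1], po2 >= 0", call. = FALSE)
  }
  konst$hufner * hb * sat + konst$o2_solubility * po2
}

#' Whole-blood carbon dioxide content
#'
#' Douglas-type model: plasma CO2 content (dissolved CO2 plus bicarbonate
#' from Henderson-Hasselbalch) corrected to whole blood with a
#' hemoglobin/saturation factor that carries the Haldane effect:
#' \deqn{C = 2.226 \cdot s\,PCO2\,(1 + 10^{pH - pK'}) \cdot
#'       \left[1 - \frac{0.0289\,Hb}{(3.352 - 0.456\,Sat)(8.142 - pH)}\right]}
#' with \eqn{s} the plasma CO2 solubility (mmol/L/mmHg) and 2.226 the
#' mmol/L to mL/dL conversion.
#'
#' @param pco2 PCO2 (mmHg), > 0.
#' @param ph Blood pH, in (6.5, 8.0).
#' @param hb Hemoglobin (g/dL).
#' @param sat Fractional hemoglobin saturation (Haldane correction input).
#' @param konst [gas_constants()].
#' @return CO2 content (mL CO2 STPD/dL whole blood).
#' @export
#' @examples
#' co2_content(40, 7.40, 15, 0.975) # ~45.8 arterial whole blood
co2_content <- function(pco2, ph, hb, sat, konst = gas_constants()) {
  if (any(pco2 <= 0)) stop("pco2 must be positive", call. = FALSE)
  if (any(ph <= 6.5) || any(ph >= 8.0)) {
    stop("ph out of supported range (6.5, 8.0)", call. = FALSE)
  }
  plasma_mmol <- konst$co2_solubility * pco2 * (1 + 10^(ph - konst$pk_prime))
  haldane <- 1 - 0.0289 * hb / ((3.352 - 0.456 * sat) * (8.142 - ph))
  MMOL_TO_MLDL * plasma_mmol * haldane
}

#' PCO2 from whole-blood CO2 content
#'
#' Numerical inverse of [co2_content()] in its first argument, at fixed pH.
#'
#' @param content CO2 content (mL/dL), > 0.
#' @inheritParams co2_content
#' @return PCO2 (mmHg); round-trip error below 0.01 mmHg.
#' @export
pco2_from_co2_content <- function(content, ph, hb, sat,
                                  konst = gas_constants()) {
  if (length(content) != 1L || !is.finite(content) || content <= 0) {
    stop("content must be a single positive number", call. = FALSE)
  }
  f <- function(p) co2_content(p, ph, hb, sat, konst) - content
  hi <- 500
  if (f(hi) < 0) {
    stop("pco2_from_co2_content: content ", content,
         " exceeds the model range (PCO2 > 500 mmHg)", call. = FALSE)
  }
  stats::uniroot(f, c(1e-6, hi), tol = 1e-10)$root
}

#' Blood pH from PCO2 at fixed bicarbonate
#'
#' Henderson-Hasselbalch closure of the acid-base loop:
#' `pk_prime + log10(hco3 / (co2_solubility * pco2))`. Bicarbonate is a fixed
#' patient parameter; no metabolic compensation dynamics are modelled.
#'
#' @param pco2 PCO2 (mmHg), > 0.
#' @param hco3 Bicarbonate (mEq/L), > 0.
#' @param konst [gas_constants()].
#' @return pH.
#' @export
#' @examples
#' ph_from_pco2(40, 24) # 7.39
ph_from_pco2 <- function(pco2, hco3 = 24, konst = gas_constants()) {
  if (any(pco2 <= 0) || any(hco3 <= 0)) {
    stop("pco2 and hco3 must be positive", call. = FALSE)
  }
  konst$pk_prime + log10(hco3 / (konst$co2_solubility * pco2))
}

# pH along the fixed-bicarbonate closure, clamped to the CO2-content model's
# validity range so that root-finding brackets can be evaluated safely; all
# physiological roots lie strictly inside the clamp.
ph_closed <- function(pco2, hco3, konst = gas_constants()) {
  pmin(7.999, pmax(6.501, ph_from_pco2(pco2, hco3, konst)))
}

#' Construct a blood-stream gas state
#'
#' A `blood_state` carries one blood stream's partial pressures, pH,
#' saturation and hemoglobin together with the derived O2 and CO2 contents;
#' the contents are always consistent with the other fields under the
#' module's formulas.
#'
#' @param po2,pco2 Partial pressures (mmHg), > 0.
#' @param ph Blood pH.
#' @param hb Hemoglobin (g/dL), within [2, 25].
#' @param sat Fractional saturation; computed from `po2` via
#'   [sat_from_po2()] when `NULL`.
#' @param konst [gas_constants()].
#' @return An object of class `blood_state`.
#' @export
#' @examples
#' blood_state(po2 = 40, pco2 = 46, ph = 7.36, hb = 10) # mixed venous blood
blood_state <- function(po2, pco2, ph, hb, sat = NULL,
                        konst = gas_constants()) {
  if (po2 <= 0 || pco2 <= 0) {
    stop("blood_state: partial pressures must be positive", call. = FALSE)
  }
  if (hb < 2 || hb > 25) {
    stop("blood_state: hb must lie in [2, 25] g/dL", call. = FALSE)
  }
  if (is.null(sat)) sat <- sat_from_po2(po2, ph, pco2)
  if (sat < 0 || sat > 1) stop("blood_state: sat outside [0,1]", call. = FALSE)
  structure(
    list(
      po2 = po2, pco2 = pco2, ph = ph, sat = sat, hb = hb,
      o2_content = o2_content(hb, sat, po2, konst),
      co2_content = co2_content(pco2, ph, hb, sat, konst)
    ),
    class = "blood_state"
  )
}

#' @export
print.blood_state <- function(x, ...) {
  cat(sprintf(
    "blood_state: PO2 %.1f mmHg  PCO2 %.1f mmHg  pH %.2f  SatO2 %.1f%%  Hb %.1f g/dL\n             CO2 %.2f mL/dL  CCO2 %.2f mL/dL\n",
    x$po2, x$pco2, x$ph, 100 * x$sat, x$hb, x$o2_content, x$co2_content
  ))
  invisible(x)
}

# Recover a full blood_state from (O2 content, CO2 content, Hb) under the
# fixed-bicarbonate acid-base closure. Used by the stream-mixing and
# steady-state machinery: mixing is exact in contents, pressures are
# re-derived here. The O2 and CO2 inversions are coupled through pH
# (Bohr) and saturation (Haldane), so a short inner fixed point wraps the
# two one-dimensional root finds; it converges in a handful of passes.
blood_state_from_contents <- function(o2c, co2c, hb, hco3 = 24,
                                      konst = gas_constants()) {
  if (!is.finite(o2c) || o2c <= 0) {
    stop("infeasible blood state: non-positive O2 content (", format(o2c),
         " mL/dL)", call. = FALSE)
  }
  if (!is.finite(co2c) || co2c <= 0) {
    stop("infeasible blood state: non-positive CO2 content", call. = FALSE)
  }
  pco2 <- 40
  ph <- ph_closed(pco2, hco3, konst)
  sat <- min(0.99, max(1e-6, o2c / (konst$hufner * hb)))
  po2 <- 40
  for (i in 1:8) {
    # O2: solve hufner*hb*sat(p) + sol*p = o2c at current ph, pco2
    g <- function(p) o2_content(hb, sat_from_po2(p, ph, pco2), p, konst) - o2c
    hi <- 900
    if (g(hi) < 0) {
      stop("infeasible blood state: O2 content ", format(o2c),
           " mL/dL exceeds capacity at Hb ", hb, " g/dL", call. = FALSE)
    }
    po2_new <- stats::uniroot(g, c(1e-4, hi), tol = 1e-9)$root
    sat <- sat_from_po2(po2_new, ph, pco2)
    # CO2: solve content along the fixed-hco3 pH closure
    h <- function(p) {
      co2_content(p, ph_closed(p, hco3, konst), hb, sat, konst) - co2c
    }
    if (h(500) < 0) {
      stop("infeasible blood state: CO2 content ", format(co2c),
           " mL/dL out of model range", call. = FALSE)
    }
    pco2_new <- stats::uniroot(h, c(1e-3, 500), tol = 1e-9)$root
    ph <- ph_closed(pco2_new, hco3, konst)
    done <- abs(po2_new - po2) < 1e-7 && abs(pco2_new - pco2) < 1e-7
    po2 <- po2_new
    pco2 <- pco2_new
    if (done) break
  }
  blood_state(po2, pco2, ph, hb, sat = sat_from_po2(po2, ph, pco2),
              konst = konst)
}
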