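#' Patient physiological parameters
#'
#' @param cardiac_output Cardiac output (L/min), > 0.
#' @param hb Hemoglobin (g/dL), in [2, 25].
#' @param vo2 Oxygen consumption (mL/min), > 0.
#' @param vco2 CO2 production (mL/min), > 0.
#' @param shunt_fraction Pulmonary shunt fraction (Qs/Qt) in [0, 1]: the
#'   fraction of pulmonary blood flow that bypasses ventilated alveoli and
#'   emerges with mixed-venous gas content.
#' @param hco3 Plasma bicarbonate (mEq/L); fixed acid-base closure, no
#'   metabolic compensation.
#' @param ideal_body_weight Ideal body weight (kg); sets the default
#'   physiologic dead space (2.2 mL/kg) when the ventilator settings leave
#'   it unspecified.
#' @return An object of class `patient_params`.
#' @export
#' @examples
#' # prototypical severe-ARDS patient: hyperdynamic and slightly anemic
#' patient_params(cardiac_output = 10, hb = 10, vo2 = 200, vco2 = 160,
#'                shunt_fraction = 0.95)
patient_params <- function(cardiac_output, hb, vo2, vco2, shunt_fraction,
                           hco3 = 24, ideal_body_weight = 60) {
  if (cardiac_output <= 0 || vo2 <= 0 || vco2 <= 0 || hco3 <= 0 ||
      ideal_body_weight <= 0) {
    stop("cardiac_output, vo2, vco2, hco3, ideal_body_weight must be positive",
         call. = FALSE)
  }
  if (hb < 2 || hb > 25) stop("hb must lie in [2, 25] g/dL", call. = FALSE)
  if (shunt_fraction < 0 || shunt_fraction > 1) {
    stop("shunt_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(cardiac_output = cardiac_output, hb = hb, vo2 = vo2, vco2 = vco2,
         shunt_fraction = shunt_fraction, hco3 = hco3,
         ideal_body_weight = ideal_body_weight),
    class = "patient_params"
  )
}

#' @export
print.patient_params <- function(x, ...) {
  cat(sprintf(
    "patient_params: CO %g L/min, Hb %g g/dL, VO2 %g, VCO2 %g mL/min, shunt %.0f%%, HCO3 %g mEq/L\n",
    x$cardiac_output, x$hb, x$vo2, x$vco2, 100 * x$shunt_fraction, x$hco3
  ))
  invisible(x)
}

#' Partition venous return between the ECMO circuit and the native route
#'
#' The circuit drains at most the cardiac output; recirculation reduces the
#' effective (patient-relevant) ECMO flow before the clamp:
#' `drained = min(blood_flow * (1 - recirculation), cardiac_output)`.
#'
#' @param p [patient_params()].
#' @param e [ecmo_settings()].
#' @return List with `drained` and `bypassing` flows (L/min); they sum to
#'   the cardiac output.
#' @export
#' @examples
#' partition_flows(patient_params(10, 10, 200, 160, 0.95),
#'                 ecmo_settings(4.9, 3)) # drained 4.9, bypassing 5.1
partition_flows <- function(p, e) {
  stopifnot(inherits(p, "patient_params"), inherits(e, "ecmo_settings"))
  effective <- e$blood_flow * (1 - e$recirculation_fraction)
  drained <- min(effective, p$cardiac_output)
  list(drained = drained, bypassing = p$cardiac_output - drained)
}

#' Mix blood streams by flow-weighted gas contents
#'
#' O2 and CO2 contents mix as flow-weighted means (mass conservation is
#' exact in contents); partial pressures, pH and saturation are recovered by
#' inverting the content formulas at the mixed contents under the
#' fixed-bicarbonate acid-base closure.
#'
#' @param streams List of streams, each a list with elements `flow` (L/min)
#'   and `blood` (a [blood_state()]). All streams must share the same
#'   hemoglobin; total flow must be positive.
#' @param hco3 Bicarbonate (mEq/L) for the pressure recovery.
#' @param konst [gas_constants()].
#' @return Mixed [blood_state()].
#' @export
mix_streams <- function(streams, hco3 = 24, konst = gas_constants()) {
  if (length(streams) == 0L) stop("no streams to mix", call. = FALSE)
  flows <- vapply(streams, function(s) s$flow, numeric(1))
  if (any(flows < 0)) stop("negative stream flow", call. = FALSE)
  total <- sum(flows)
  if (total <= 0) stop("total flow must be positive", call. = FALSE)
  hbs <- vapply(streams, function(s) s$blood$hb, numeric(1))
  if (diff(range(hbs)) > 1e-9) {
    stop("streams have differing hemoglobin; mixing assumes a common Hb",
         call. = FALSE)
  }
  o2c <- sum(flows * vapply(streams, function(s) s$blood$o2_content,
                            numeric(1))) / total
  co2c <- sum(flows * vapply(streams, function(s) s$blood$co2_content,
                             numeric(1))) / total
  blood_state_from_contents(o2c, co2c, hbs[[1L]], hco3, konst)
}

#' Native-lung gas exchange with shunt admixture
#'
#' Pulmonary-artery blood splits into a shunted fraction that passes through
#' unchanged and a ventilated fraction that equilibrates to alveolar gas.
#' The alveolar PCO2 is solved so that the CO2 the perfused alveoli take up
#' from blood equals what alveolar ventilation carries away:
#' \deqn{Q_{CO}(1-Q_s/Q_t)\,10\,(C_{pa} - C_{cap}(PACO2)) =
#'       \dot V_A \cdot 1000 \cdot PACO2/(P_b - P_{H_2O}).}
#' End-capillary PO2 equals the alveolar PO2 from the alveolar gas equation
#' at that PACO2. Arterial blood is the flow-weighted content mix of the
#' two streams.
#'
#' @param pa_blood Pulmonary-artery [blood_state()].
#' @param v [vent_settings()].
#' @param p [patient_params()].
#' @param konst [gas_constants()].
#' @return Arterial [blood_state()]. With `shunt_fraction = 1` the
#'   pulmonary-artery blood passes through unchanged.
#' @export
lung_exchange <- function(pa_blood, v, p, konst = gas_constants()) {
  stopifnot(inherits(pa_blood, "blood_state"), inherits(v, "vent_settings"),
            inherits(p, "patient_params"))
  shunt <- p$shunt_fraction
  if (shunt >= 1) return(pa_blood)
  dead <- if (is.na(v$dead_space)) 2.2 * p$ideal_body_weight else v$dead_space
  va <- alveolar_ventilation(v, dead)
  q_cap <- p$cardiac_output * (1 - shunt)
  p_dry <- konst$barometric_pressure - konst$water_vapor_pressure

  cap_state <- function(paco2) {
    ph <- ph_closed(paco2, p$hco3, konst)
    pao2 <- alveolar_po2(v$fio2, paco2, konst)
    sat <- sat_from_po2(pao2, ph, paco2)
    blood_state(pao2, paco2, ph, p$hb, sat = sat, konst = konst)
  }
  balance <- function(paco2) {
    q_cap * 10 * (pa_blood$co2_content - cap_state(paco2)$co2_content) -
      va * 1000 * paco2 / p_dry
  }
  # balance() is decreasing in PACO2: low PACO2 -> large blood-side release,
  # high PACO2 -> capillary blood holds more CO2 than pulmonary-artery blood
  lo <- 0.5
  hi <- max(200, 2 * pa_blood$pco2)
  if (balance(lo) < 0) {
    paco2 <- lo # pathological corner: essentially CO2-free inflow
  } else {
    while (balance(hi) > 0 && hi < 1000) hi <- hi * 1.5
    paco2 <- stats::uniroot(balance, c(lo, hi), tol = 1e-9)$root
  }
  cap <- cap_state(paco2)
  mix_streams(
    list(list(flow = shunt, blood = pa_blood),
         list(flow = 1 - shunt, blood = cap)),
    hco3 = p$hco3, konst = konst
  )
}

#' Tissue gas exchange by the Fick principle
#'
#' Venous O2 content = arterial content - VO2/(CO x 10); venous CO2
#' content = arterial content + VCO2/(CO x 10); venous pressures and
#' saturation re-inverted from the contents.
#'
#' @param arterial Arterial [blood_state()].
#' @param p [patient_params()].
#' @param konst [gas_constants()].
#' @return Mixed-venous [blood_state()]. If oxygen demand exceeds delivery
#'   (venous content would be non-positive) an error of class
#'   `ecmosim_infeasible` is thrown; the steady-state solver catches it and
#'   reports an infeasible, non-converged result.
#' @export
tissue_exchange <- function(arterial, p, konst = gas_constants()) {
  stopifnot(inherits(arterial, "blood_state"), inherits(p, "patient_params"))
  cv_o2 <- arterial$o2_content - p$vo2 / (p$cardiac_output * 10)
  cv_co2 <- arterial$co2_content + p$vco2 / (p$cardiac_output * 10)
  if (cv_o2 <= 1e-3) {
    stop(structure(
      class = c("ecmosim_infeasible", "error", "condition"),
      list(message = paste0(
        "oxygen demand exceeds delivery: venous O2 content would be ",
        format(cv_o2, digits = 3), " mL/dL (VO2 ", p$vo2, " mL/min at DO2 ",
        format(arterial$o2_content * p$cardiac_output * 10, digits = 4),
        " mL/min)"), call = NULL)
    ))
  }
  blood_state_from_contents(cv_o2, cv_co2, p$hb, p$hco3, konst)
}

#' Solve the coupled ECMO / native-lung steady state
#'
#' Damped successive substitution on the mixed-venous (O2, CO2) contents.
#' Each iteration runs the circulation loop once: venous blood is
#' partitioned between circuit and native route ([partition_flows()]), the
#' drained stream crosses the membrane ([oxygenate()]), the streams remix
#' into pulmonary-artery blood ([mix_streams()]), the native lung adds
#' shunt-limited exchange ([lung_exchange()]), and tissue Fick exchange
#' ([tissue_exchange()]) closes the loop. Convergence when the largest
#' absolute content change is below `tol`.
#'
#' @param p [patient_params()].
#' @param v [vent_settings()].
#' @param e [ecmo_settings()].
#' @param konst [gas_constants()].
#' @param tol Convergence tolerance on contents (mL/dL).
#' @param max_iter Iteration cap.
#' @param damping Fraction of the proposed update applied per iteration;
#'   0.5 keeps the two-variable fixed point stable at extreme shunt and
#'   flow settings.
#' @param init Optional warm start: a list with `o2_content` and
#'   `co2_content` (mL/dL) for the initial mixed-venous guess, e.g. the
#'   converged contents of a neighbouring sweep point.
#' @return An object of class `ecmo_steady_state`: converged arterial,
#'   mixed-venous, post-oxygenator and pulmonary-artery [blood_state()]s,
#'   the O2/CO2 transfer decomposition between membrane and native lung
#'   (mL/min), iteration diagnostics, and `converged`/`infeasible` flags.
#' @export
#' @examples
#' p <- patient_params(10, 10, 200, 160, 0.95)
#' v <- vent_settings(peep = 14, driving_pressure = 10, rr = 10, cst = 14,
#'                    fio2 = 0.3)
#' e <- ecmo_settings(blood_flow = 4.9, sweep_flow = 3, sweep_fio2 = 1)
#' solve_steady_state(p, v, e)
solve_steady_state <- function(p, v, e, konst = gas_constants(),
                               tol = 1e-4, max_iter = 10000, damping = 0.5,
                               init = NULL) {
  stopifnot(inherits(p, "patient_params"), inherits(v, "vent_settings"),
            inherits(e, "ecmo_settings"))
  flows <- partition_flows(p, e)

  if (!is.null(init)) {
    cv_o2 <- init$o2_content
    cv_co2 <- init$co2_content
  } else {
    # initial guess: moderately desaturated, mildly hypercapnic venous blood
    ph0 <- ph_from_pco2(45, p$hco3, konst)
    cv_o2 <- o2_content(p$hb, 0.70, po2_from_sat(0.70, ph0, 45), konst)
    cv_co2 <- co2_content(45, ph0, p$hb, 0.70, konst)
  }

  loop_once <- function(cv_o2, cv_co2) {
    venous <- blood_state_from_contents(cv_o2, cv_co2, p$hb, p$hco3, konst)
    if (flows$drained > 0 && e$blood_flow > 0) {
      post_ox <- oxygenate(venous, e, hco3 = p$hco3, konst = konst)
      pa <- mix_streams(
        list(list(flow = flows$drained, blood = post_ox),
             list(flow = flows$bypassing, blood = venous)),
        hco3 = p$hco3, konst = konst
      )
    } else {
      post_ox <- venous
      pa <- venous
    }
    arterial <- lung_exchange(pa, v, p, konst)
    new_venous <- tissue_exchange(arterial, p, konst)
    list(venous = venous, post_ox = post_ox, pa = pa, arterial = arterial,
         new_venous = new_venous)
  }

  converged <- FALSE
  infeasible <- FALSE
  message_txt <- NULL
  iter <- 0L
  residual <- NA_real_
  state <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    state <- tryCatch(loop_once(cv_o2, cv_co2), ecmosim_infeasible = identity)
    if (inherits(state, "condition")) {
      infeasible <- TRUE
      message_txt <- conditionMessage(state)
      state <- NULL
      break
    }
    d_o2 <- state$new_venous$o2_content - cv_o2
    d_co2 <- state$new_venous$co2_content - cv_co2
    residual <- max(abs(d_o2), abs(d_co2))
    cv_o2 <- cv_o2 + damping * d_o2
    cv_co2 <- cv_co2 + damping * d_co2
    if (residual < tol) {
      converged <- TRUE
      break
    }
  }

  if (is.null(state)) {
    res <- list(converged = FALSE, infeasible = TRUE, message = message_txt,
                iterations = iter, residual = residual,
                arterial = NULL, mixed_venous = NULL, post_oxygenator = NULL,
                pulmonary_artery = NULL,
                ecmo_o2_transfer = NA_real_, lung_o2_transfer = NA_real_,
                ecmo_vco2 = NA_real_, lung_vco2 = NA_real_,
                patient = p, vent = v, ecmo = e)
    class(res) <- "ecmo_steady_state"
    return(res)
  }

  venous <- state$venous
  q10 <- p$cardiac_output * 10
  ecmo_o2 <- o2_transfer_rate(venous, state$post_ox, flows$drained)
  lung_o2 <- q10 * (state$arterial$o2_content - state$pa$o2_content)
  ecmo_vco2 <- flows$drained * 10 *
    (venous$co2_content - state$post_ox$co2_content)
  lung_vco2 <- q10 * (state$pa$co2_content - state$arterial$co2_content)

  res <- list(
    converged = converged, infeasible = FALSE,
    message = if (converged) NULL else "max iterations exceeded",
    iterations = iter, residual = residual,
    arterial = state$arterial, mixed_venous = venous,
    post_oxygenator = state$post_ox, pulmonary_artery = state$pa,
    ecmo_o2_transfer = ecmo_o2, lung_o2_transfer = lung_o2,
    ecmo_vco2 = ecmo_vco2, lung_vco2 = lung_vco2,
    patient = p, vent = v, ecmo = e
  )
  class(res) <- "ecmo_steady_state"
  res
}

#' @export
print.ecmo_steady_state <- function(x, ...) {
  if (x$infeasible) {
    cat("ecmo_steady_state: INFEASIBLE --", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("ecmo_steady_state (%s, %d iterations)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  arterial:     PO2 %6.1f  PCO2 %5.1f  pH %.2f  SatO2 %5.1f%%\n",
              x$arterial$po2, x$arterial$pco2, x$arterial$ph,
              100 * x$arterial$sat))
  cat(sprintf("  mixed venous: PO2 %6.1f  PCO2 %5.1f  pH %.2f  SatO2 %5.1f%%\n",
              x$mixed_venous$po2, x$mixed_venous$pco2, x$mixed_venous$ph,
              100 * x$mixed_venous$sat))
  cat(sprintf("  O2 transfer:  ECMO %6.1f + lung %6.1f = %6.1f mL/min\n",
              x$ecmo_o2_transfer, x$lung_o2_transfer,
              x$ecmo_o2_transfer + x$lung_o2_transfer))
  cat(sprintf("  CO2 removal:  ECMO %6.1f + lung %6.1f = %6.1f mL/min\n",
              x$ecmo_vco2, x$lung_vco2, x$ecmo_vco2 + x$lung_vco2))
  invisible(x)
}

#' @export
summary.ecmo_steady_state <- function(object, ...) {
  x <- object
  if (x$infeasible) {
    return(data.frame(converged = FALSE, infeasible = TRUE,
                      iterations = x$iterations))
  }
  data.frame(
    converged = x$converged, infeasible = FALSE, iterations = x$iterations,
    residual = x$residual,
    pao2 = x$arterial$po2, paco2 = x$arterial$pco2, ph_a = x$arterial$ph,
    sat_a = x$arterial$sat,
    pvo2 = x$mixed_venous$po2, pvco2 = x$mixed_venous$pco2,
    sat_v = x$mixed_venous$sat,
    pa_po2 = x$pulmonary_artery$po2,
    ecmo_o2_transfer = x$ecmo_o2_transfer,
    lung_o2_transfer = x$lung_o2_transfer,
    ecmo_vco2 = x$ecmo_vco2, lung_vco2 = x$lung_vco2
  )
}
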