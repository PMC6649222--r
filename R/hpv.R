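#' Oxygen stimulus of hypoxic pulmonary vasoconstriction
#'
#' The effective oxygen tension sensed by the pulmonary vasculature is a
#' weighted geometric mean of the alveolar and mixed-venous PO2,
#' \deqn{P_{s}O_2 = P_AO_2^{\,w_A} \cdot P_vO_2^{\,w_v},\qquad w_A + w_v = 1,}
#' with the classical weighting of 0.62 (alveolar) and 0.38 (venous) as
#' default. Raising either tension relieves vasoconstriction; during VV-ECMO
#' support the venous term is the one the circuit can drive up.
#'
#' @param pao2_alveolar Alveolar PO2 (mmHg), > 0.
#' @param pvo2 Mixed-venous PO2 after ECMO mixing (mmHg), > 0.
#' @param alveolar_weight,venous_weight Positive exponents summing to 1.
#' @return Stimulus PO2 (mmHg), always between the two input tensions.
#' @export
#' @examples
#' p_stimulus_o2(100, 40) # 70.6 mmHg
p_stimulus_o2 <- function(pao2_alveolar, pvo2, alveolar_weight = 0.62,
                          venous_weight = 0.38) {
  if (any(pao2_alveolar <= 0) || any(pvo2 <= 0)) {
    stop("partial pressures must be positive", call. = FALSE)
  }
  if (alveolar_weight <= 0 || venous_weight <= 0 ||
      abs(alveolar_weight + venous_weight - 1) > 1e-9) {
    stop("weights must be positive and sum to 1", call. = FALSE)
  }
  exp(alveolar_weight * log(pao2_alveolar) + venous_weight * log(pvo2))
}

#' Vasoconstriction-stimulus curve over inspired oxygen
#'
#' Evaluates the alveolar gas equation and [p_stimulus_o2()] across a grid
#' of inspired oxygen fractions at a given mixed-venous PO2 and alveolar
#' PCO2, reproducing stimulus-vs-FiO2 scenario curves. The shunt fraction
#' does not enter the stimulus formula itself (it acts through the
#' achievable venous PO2, computed by the circulation model); it is carried
#' as a scenario label column.
#'
#' @param fio2_grid Inspired oxygen fractions, each in [0.21, 1].
#' @param shunt Scenario shunt fraction (label only).
#' @param pvo2 Mixed-venous PO2 (mmHg).
#' @param paco2 Alveolar PCO2 (mmHg).
#' @param alveolar_weight,venous_weight Stimulus exponents.
#' @param konst [gas_constants()].
#' @return `data.frame` with columns `fio2`, `shunt`, `pvo2`, `pao2_alveolar`,
#'   `pstimulus`; one row per grid value, monotone non-decreasing in FiO2.
#' @export
#' @examples
#' stimulus_curve(c(0.21, 0.5, 1.0), shunt = 0.6, pvo2 = 180, paco2 = 40)
stimulus_curve <- function(fio2_grid, shunt, pvo2, paco2,
                           alveolar_weight = 0.62, venous_weight = 0.38,
                           konst = gas_constants()) {
  if (length(fio2_grid) == 0L) stop("empty fio2 grid", call. = FALSE)
  pao2 <- alveolar_po2(fio2_grid, paco2, konst)
  data.frame(
    fio2 = fio2_grid,
    shunt = shunt,
    pvo2 = pvo2,
    pao2_alveolar = pao2,
    pstimulus = p_stimulus_o2(pao2, pvo2, alveolar_weight, venous_weight)
  )
}
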