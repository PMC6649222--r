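---
title: "Modelling gas exchange during venous-venous ECMO support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gas exchange during venous-venous ECMO support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmosim)
```

## What the simulator computes

`ecmosim` is a deterministic steady-state model of a severe-respiratory-failure
patient on venous-venous extracorporeal membrane oxygenation (VV-ECMO). It
answers four coupled questions for a given patient, ventilator and circuit
configuration:

1. how much energy per minute the ventilator transfers to the lungs
   (mechanical power, J/min);
2. whether the oxygen transferred by the membrane lung plus the residual
   native lung matches the patient's oxygen consumption, and at what arterial
   saturation that match is achieved;
3. what arterial PCO2 results from the combination of sweep-gas CO2 removal
   and (minimal) alveolar ventilation;
4. what effective oxygen tension drives hypoxic pulmonary vasoconstriction
   (HPV) once the circuit oxygenates the venous return.

Everything is closed-form chemistry plus one two-variable fixed point; there
is no randomness anywhere, and identical inputs produce bit-identical
outputs.

## Blood gas chemistry

**Oxygen.** Hemoglobin saturation follows the Severinghaus form
$S = \left(1 + \frac{23400}{p^3 + 150\,p}\right)^{-1}$, evaluated at a
virtual PO2 shifted for the Bohr effect,
$p_v = \mathrm{PO_2}\cdot 10^{\,0.40(\mathrm{pH}-7.40) +
0.06(\log_{10}40 - \log_{10}\mathrm{PCO_2})}$, with temperature fixed at
37&nbsp;°C. This is the standard simple invertible dissociation curve
(P50 ≈ 26.9 mmHg); it was chosen over table-based or higher-order fits
because the circulation solver inverts it thousands of times per run.
Oxygen content is Hüfner binding plus physical solution,
$C_{O_2} = 1.34\,\mathrm{Hb}\,S + 0.0031\,\mathrm{PO_2}$ (mL/dL).

**Carbon dioxide.** Whole-blood CO2 content uses the Douglas closed form:
plasma content (dissolved CO2 plus Henderson–Hasselbalch bicarbonate,
converted at 2.226 mL·dL⁻¹ per mmol·L⁻¹) times the hemoglobin/saturation
correction
$1 - \frac{0.0289\,\mathrm{Hb}}{(3.352-0.456\,S)(8.142-\mathrm{pH})}$,
which carries the Haldane effect: deoxygenated blood holds more CO2 at the
same PCO2. Both content formulas have numerical inverses (root-finding with
`uniroot`, bracket tolerances 1e-9 to 1e-10 mmHg) with round-trip errors
below 0.01 mmHg.

**Acid–base closure.** pH is recomputed from PCO2 through
Henderson–Hasselbalch at a *fixed* patient bicarbonate (default
24 mEq/L); there is no metabolic compensation. This makes extreme PCO2
excursions produce larger pH swings than a buffered patient would show. The
Douglas correction is only valid for pH in (6.5, 8.0), so internal root
brackets evaluate the closure with pH clamped to that interval; all
physiological solutions lie strictly inside the clamp, which only exists so
bracket endpoints can be evaluated.

## Ventilator mechanics

Tidal volume is `Vt = DP × Cst`; scenarios that prescribe `Vt` instead
back-compute the driving pressure. Mechanical power defaults to the elastic
term only,

$$MP = 0.098 \cdot RR \cdot V_t \cdot (PEEP + DP/2) \quad \mathrm{[J/min]},$$

which is exactly linear in RR and PEEP and quasi-quadratic in DP (because
`Vt` itself scales with DP). An optional constant-flow resistive term
`0.098·RR·Vt·Raw·(Vt/Tinsp)` can be added; it is off by default so the
reported power isolates the elastic load, and it is the only place the
inspiratory time (hence the I:E ratio) enters — consistent with the small
observed effect of I:E on power. Alveolar PO2 comes from the alveolar gas
equation `FiO2·(Pb − PH2O) − PaCO2/RQ` floored at 1 mmHg; alveolar
ventilation is `RR·max(0, Vt − Vd)`, with dead space defaulting to
2.2 mL/kg ideal body weight when a scenario does not set it.

## The membrane oxygenator

The device model is a lumped single pass. Oxygen: the outlet PO2 moves a
fraction `membrane_o2_efficiency` of the way from the inlet PO2 to the
sweep-gas PO2 `sweep_fio2·(Pb − PH2O)`. Carbon dioxide: the sweep gas
leaves equilibrated to the inlet blood PCO2 scaled by
`membrane_co2_efficiency`, giving a gas-side capacity
`sweep·1000·eff·PCO2/(Pb − PH2O)` mL/min, capped by the blood-side content
`Q·10·C_CO2`; the outlet PCO2 is re-inverted from the outlet content *at
the outlet saturation*, so each pass conserves CO2 mass exactly despite the
Haldane shift of freshly oxygenated blood. Gas volumes are treated at
barometric dry-gas conditions without STPD/BTPS correction — internal
consistency was preferred over absolute volumetric accuracy.

Both efficiencies default to 1 (a fresh membrane) and are the device
model's calibration parameters. The packaged prototypical on-ECMO fixture
carries `membrane_co2_efficiency = 0.85`, calibrated once so that the
steady-state arterial PCO2 reproduces that scenario's blood gas
(PaCO2 35 mmHg at 4.9 L/min blood flow and 3 L/min sweep); it is a
scenario-level device property, not a quantity the solver adjusts.

Recirculation is an explicit user parameter (default 0) that scales the
effective circuit flow before it is clamped at the cardiac output. With
zero recirculation this topology oxygenates more effectively than a real
cannulated patient, whose drainage re-aspirates part of the return flow;
users matching bedside saturations should raise
`recirculation_fraction` rather than the membrane efficiency.

## Circulation and the steady-state solver

The flow topology is a single venous pool: the circuit drains
`min(Q_ECMO·(1 − recirc), Q_CO)`; the post-oxygenator stream remixes with
the bypassing venous return to form pulmonary-artery blood; the native lung
splits that flow into a shunted fraction (passed through unchanged) and a
ventilated fraction equilibrated to alveolar gas; tissue exchange applies
the Fick principle (`ΔC = V̇/Q·10`). Mixing is exact in contents —
flow-weighted means — with pressures re-inverted afterwards, so mass is
conserved by construction.

The alveolar PCO2 is not an input: inside `lung_exchange()` it solves

$$Q_{CO}(1 - Q_s/Q_t)\,10\,\big(C_{pa} - C_{cap}(P_ACO_2)\big)
  = \dot V_A \cdot 1000 \cdot P_ACO_2 / (P_b - P_{H_2O}),$$

so the CO2 the perfused capillaries release equals what alveolar
ventilation carries away. Under ultraprotective settings $\dot V_A$ is
nearly zero and the equation correctly pins the capillary blood close to
pulmonary-artery PCO2 (the small residual difference reflects the Haldane
shift), leaving CO2 clearance to the circuit.

The solver is damped successive substitution on the mixed-venous
(O2, CO2) contents: damping 0.5, convergence when the largest content
change falls below 1e-4 mL/dL, capped at 10,000 iterations. Damping 0.5
keeps the iteration stable at extreme shunt/flow combinations where the
undamped map's contraction factor approaches 1; typical scenarios converge
in 50–300 iterations. Parameter sweeps warm-start each point from the
neighbouring converged venous contents (except across patient sweeps,
where hemoglobin changes the meaning of a content), which shortens sweeps
without changing any converged answer beyond the stated tolerance.

Infeasibility is detected, not papered over: if oxygen demand exceeds
deliverable oxygen (the Fick step would drive venous O2 content negative),
a typed condition aborts the iteration and the result is flagged
`infeasible` with the cause; sweep rows continue past such points. Total
shunt with no circuit flow is the canonical example.

## The HPV stimulus

The effective oxygen tension driving hypoxic pulmonary vasoconstriction is
the weighted geometric mean
$P_sO_2 = P_AO_2^{0.62} \cdot P_vO_2^{0.38}$ — the classical Marshall
weighting of alveolar and mixed-venous tensions, with the exponents exposed
as parameters. It is bounded by its two inputs, strictly increasing in
each, and homogeneous of degree 1. The scenario runner feeds it the
alveolar PO2 at the converged arterial PCO2 and the pulmonary-artery PO2
(i.e. the venous tension *after* ECMO mixing), which is how circuit flow
relieves vasoconstriction in this model. Note that the commonly cited
healthy reference stimulus of ~19 mmHg is not reproduced by this default
weighting at healthy tensions; the weights are calibration parameters, and
the module makes no claim about absolute pulmonary-artery pressures.
Shunt enters only through the achievable venous tension computed by the
circulation, never through the stimulus formula itself.

## Packaged scenarios and what they emulate

* `protective_preecmo` — severe ARDS on protective ventilation
  (PEEP 18, Vt 360 mL at Cst 18, RR 35, FiO2 1.0) before cannulation. Two
  fixture values are modelling choices rather than ventilator readings:
  shunt fraction 0.80, the highest at which oxygen delivery still meets a
  200 mL/min consumption without a circuit in this model, and dead space
  240 mL (Vd/Vt ≈ 0.67, typical of severe ARDS), calibrated once so the
  scenario reproduces refractory hypoxemia with severe hypercapnia
  (PaO2 ≈ 36 mmHg, PaCO2 ≈ 62–65 mmHg on FiO2 1.0).
* `ultraprotective_on_ecmo` — the same patient after cannulation
  (PEEP 14, DP 10 at Cst 14 → Vt 140 mL, RR 10; circuit 4.9 L/min, sweep
  3 L/min at FiO2 1.0). Reproduces the near-normal PaCO2; its arterial
  saturation (≈99%) exceeds a typical bedside value because the fixture
  sets recirculation to zero.
* `healthy_no_ecmo` — standard intraoperative ventilation with ~3% shunt,
  a reference point for mechanical power (≈5.9 J/min) and for the
  no-circuit degenerate path of the solver.

What passing tests on these scenarios do **not** show: the model has no
pulsatility, no regional VA/Q heterogeneity (a single shunt compartment),
no temperature or 2,3-DPG effects, no metabolic acid–base compensation, no
cardiac-output feedback, and no time-resolved transients. Agreement here is
agreement with an idealized steady-state physiology, not with any
individual patient.

## Numerical choices and degenerate inputs

* All inversions use `uniroot` on guaranteed-sign brackets; PO2 on
  (1e-4, 900] mmHg, PCO2 on (1e-6, 500] mmHg, with explicit diagnostics on
  bracket failure.
* The coupled (PO2, PCO2, pH) recovery from contents iterates the two
  one-dimensional inversions to a 1e-7 mmHg fixed point (a handful of
  passes).
* Zero circuit blood flow is an identity pass-through; zero sweep flow
  removes no CO2; complete shunt passes pulmonary-artery blood through
  unchanged; a sweep capacity exceeding the blood-side content floors the
  outlet at PCO2 = 0.01 mmHg.
* Test problem sizes: the property suite exercises a 108-point scenario
  grid (circuit flow × shunt × hemoglobin × sweep × VO2) for mass-balance
  residuals, plus sweeps of ~11 points for the monotonicity claims — small
  enough to run routinely, large enough to cover the corners where the
  fixed point is slowest.
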