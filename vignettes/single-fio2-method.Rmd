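---
title: "Single-FiO2 shunt and low-V/Q quantification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-FiO2 shunt and low-V/Q quantification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hypoxemia in ventilated patients is conventionally summarized as *venous
admixture* (VenAd): the virtual shunt fraction of the Riley three-compartment
lung that reproduces the measured arterial oxygen content. VenAd lumps
together two mechanisms with opposite management implications — true shunt
(perfusion of unventilated lung, V/Q = 0, typically consolidated lung that
may respond to recruitment) and low-V/Q perfusion (poorly ventilated but
aerated lung, as in pulmonary vascular disease, where aggressive recruitment
is counterproductive). Multi-FiO2 methods (MIGET, ALPE, two-FiO2
model-fitting) can separate the two but require changing the inspired oxygen
fraction, risking signal distortion from absorption atelectasis and altered
hypoxic vasoconstriction.

`vqshunt` implements a *single-FiO2* approach: adding the mean alveolar PCO2
(measurable at the bedside by volumetric capnography) to the standard blood
gas / calorimetry / cardiac output data makes the inverse problem solvable
from one set of measurements at the operating FiO2. The package contains the
complete loop: a forward multi-compartment lung simulator, a scenario
generator, a simulation-trained neural-network inverter, a direct model
back-calculation inverter, and the evaluation statistics.

## The forward lung model

The lung is 21 compartments: 20 ventilated compartments whose perfusion
follows a log-normal distribution over the V/Q axis, plus a shunt compartment
(V/Q = 0) receiving a fraction `shunt` of pulmonary blood flow.

**Perfusion distribution.** The 20 compartments sit at log-equally-spaced V/Q
centers spanning `mean_vq * exp(±max(3.5 log_sd, 1.2))`. Each receives the
bin-integrated mass of the log-normal density with parameters
`mu = log(mean_vq) − log_sd²/2`, `sigma = log_sd`, renormalized; `mean_vq` is
therefore the perfusion-weighted (arithmetic) mean V/Q of the ventilated
lung. The floor of 1.2 log units on the grid half-width keeps the grid from
collapsing with the dispersion, so a nearly-degenerate distribution
(`log_sd → 0`) concentrates its mass into single bins rather than spreading
scale-invariantly. Ventilation is implied per compartment as
`v_frac ∝ q_frac × vq`; total alveolar ventilation is emergent, not an input,
and there is no dead-space compartment.

**Compartment equilibration.** Each ventilated compartment solves the
steady-state mass balance for O2 and CO2: gas-side flux
`vq × (PIO2·PAN2/PIN2 − PAO2)/0.863` (and `vq × PACO2/0.863` for CO2) equals
blood-side flux `10 × (end-capillary − mixed venous content)`, per unit
perfusion. Nitrogen closes the system: alveolar pressures sum to barometric
minus water vapor pressure (760 − 47 = 713 mmHg by default), and the
inspired-to-expired ventilation ratio `PAN2/PIN2` accounts for net gas uptake
when R ≠ 1. This N2 correction matters most in low-V/Q compartments at
moderate FiO2, where inspired ventilation can exceed expired by tens of
percent — precisely the compartments that shape the mean alveolar PCO2.

**Blood chemistry.** Oxygen saturation uses the Severinghaus curve
`S = (x³ + 150x)/(x³ + 150x + 23400)` evaluated at a virtual PO2
`x = PO2 × 26.86 / P50`, with the in-vivo P50 obtained from the standard P50
(`p50st`, an input) by multiplicative Bohr corrections
`P50 = p50st × 10^(−0.48 (pH − 7.4) + 0.06 log10(PCO2/40))`; base excess acts
through its effect on pH. O2 content is `1.34 × Hb × S + 0.003 × PO2` mL/dL.
CO2 content is a Douglas-form whole-blood equation (dissolved plus
bicarbonate, scaled by a hemoglobin/saturation factor that carries the
Haldane effect). pH follows from PCO2 and base excess through the whole-blood
Van Slyke buffer relation. All constants (Hüfner 1.34 mL/g, solubilities,
barometric pressure) are exposed in `gas_constants()`.

**Whole-lung closure.** Mixed venous content is the fixed point of: guess
venous → equilibrate all compartments → mix arterial content by
perfusion-weighted averaging (shunt contributes venous blood) → update venous
by Fick (`CvO2 = CaO2 − VO2/(10·CO)`, `CvCO2 = CaCO2 + VCO2/(10·CO)`). The
iteration is damped (0.5) with a per-component secant acceleration once two
residuals exist; convergence is declared when venous contents change by less
than 1e-6 mL/dL (typically 7–12 sweeps; pure damping alone needs hundreds).
Arterial and venous tensions are recovered by inverting the content
relations. A scenario whose venous O2 content would fall to zero is reported
infeasible, never clamped — clamping would silently corrupt training labels.

**Outputs.** The model emits the ten bedside features — FiO2, Hb, SaO2, pH,
PaO2, PaCO2, mean PACO2, cardiac output, VCO2, R — plus hidden labels. Mean
PACO2 is the expired-alveolar-ventilation-weighted mean of compartmental
PACO2, the model proxy for the Phase-3 geometric midpoint of the volumetric
capnogram (the waveform itself is out of scope). VenAd comes from the Riley
construction with the ideal compartment at the classic ideal alveolar PO2
(`PIO2 − PaCO2 (FiO2 + (1−FiO2)/R)`); low V/Q = VenAd − shunt.

## The scenario generator

`sample_inputs()` draws each of the nine model inputs independently and
uniformly inside its sampling range (shunt 7.3–36.5% of blood flow, log SD
0.36–1.83, mean V/Q 0.21–1.25, VCO2 185–223 mL/min, R 0.57–1.05, Hb 6.0–17.3
g/dL, standard P50 20.8–31.2 mmHg, base excess −6.5–4.9 mEq/L, CO 4.32–6.28
L/min). Uniform independent sampling is the simplest law consistent with
"unique combinations within pre-defined ranges"; no covariate correlation is
imposed. For each tuple `titrate_fio2()` bisects the monotone SaO2(FiO2) map
toward a per-scenario target saturation drawn uniformly in the retention band
[0.87, 0.98] — emulating the spread of titration endpoints seen clinically
and keeping SaO2 informative as an ML feature. Scenarios that cannot reach
the band anywhere in FiO2 0.21–0.99 (a few percent, mostly severe anemia with
extreme shunt) are logged and replaced by fresh draws. The default universe
is 15,236 retained records, randomized into 14,736 training and 500 test
rows.

What the generator emulates: the joint physiological diversity of gas
exchange, oxygen delivery, acid–base state and hemoglobin affinity, observed
through error-free bedside measurements. What it does not emulate:
measurement noise, biological covariation between inputs (e.g. anemia and
cardiac output), breath-by-breath variability, or capnogram waveform
artifacts. Passing tests therefore demonstrate internal consistency of the
inverse methods on noiseless data from this model family — not robustness to
real measurement error, which the sensitivity sweeps probe instead.

A caveat on the output envelope: because mean PACO2 ≡ 0.863·VCO2/VA
identically at steady state, corners of the input box with low mean V/Q and
low dispersion are severely hypoventilated and produce mean PACO2 and PaCO2
well above typical clinical ranges (up to ~200 mmHg). With ventilation
defined as `v = q × vq` this is an arithmetic necessity, not a solver
artifact; such records are retained (the only retention rule is the SaO2
band) and simply extend the hypercapnic tail of the universe.

## The neural-network inverter

A dense feed-forward regressor maps the ten z-scored features to shunt (% of
blood flow): 6 hidden ReLU layers of 128 units and a linear output — 84,097
trainable parameters — trained with RMSprop (lr 1e-3, rho 0.9) on MSE for 500
epochs. Normalization statistics come from training rows only. Defaults
follow common deep-learning practice where unstated: batch size 32, Glorot
uniform initialization, an optional 10% validation split used only for loss
monitoring, and a gentle exponential learning-rate decay (0.994 per epoch)
that removes the constant-rate jitter floor of RMSprop in the late epochs;
all are exposed in `mlp_config()`. The trainer is implemented in
RcppArmadillo inside the package and is fully deterministic given the seed.
On noiseless simulated data overfitting is not observed: held-out loss tracks
training loss throughout.

## The direct back-calculation

`recover_shunt()` inverts one bedside record without ML. Base excess is
derived from (pH, PaCO2, Hb) by the Van Slyke relation and the standard P50
from the measured (PaO2, SaO2) pair after removing the Bohr shifts, so the
record is chemically self-consistent. The solver then finds (shunt, log SD,
mean V/Q) such that the forward model at the record's FiO2 reproduces the
observed SaO2, PaCO2 and mean PACO2 — three equations, three unknowns; PaO2
and pH serve only as consistency inputs. The residual set is a design choice
exposed in code; SaO2 (not PaO2) is matched because the sensitivity behavior
of the method shows PaO2 and pH to be the least influential inputs.

Numerically this is bounded Levenberg–Marquardt with five deterministic
starts. The starts exploit two identities: total alveolar ventilation is
pinned by `VA = 0.863·VCO2/meanPACO2`, which fixes the mean-V/Q start for any
shunt guess (`mean_vq ≈ VA/(CO(1−s))`), and the record's own VenAd bounds the
shunt start. Venous-infeasible parameter regions return a penalty that slopes
back toward lower shunt. If no start meets the residual tolerance (0.05 pp
saturation / 0.05 mmHg), a Nelder–Mead polish from the best point is
followed by a final refit. On forward-generated records the procedure returns
the generating parameters to well within 0.3 percentage points of shunt.

`sensitivity_sweep()` repeats the recovery with one of the nine non-FiO2
inputs perturbed (default ±10% relative, ±2 mmHg absolute for the two PCO2
inputs, 9 points), holding the others fixed, and reports the curve and the
central-difference slope. Because the derived P50 and base excess are
re-computed from the perturbed record, the sweeps propagate measurement error
exactly as a bedside user would experience it.

## Evaluation statistics

Agreement between truth and estimate is summarized the way method-comparison
studies in this area report it: OLS of *actual on estimate* (slope, intercept,
R², slope CI from the t distribution), an error summary (mean, SD, median,
IQR, range, sample skewness, Shapiro–Wilk p) under the `actual − estimate`
sign convention (flippable), and Gaussian-kernel density overlays of the two
distributions on a shared grid with Silverman bandwidth.

## Numerical choices and problem sizes

* Compartment solves are nested safeguarded Newton iterations with
  maintained brackets; the outer CO2 balance is monotone increasing in
  PACO2, the inner O2 balance monotone decreasing in PAO2, so convergence is
  guaranteed on the bracket. Flux residuals at convergence are below 1e-6
  mL/min per unit flow.
* Content inversions (content → tension) are safeguarded Newton on strictly
  monotone maps; the blood-gas state from contents is a fixed point on
  saturation exploiting the weak Haldane coupling.
* Warm starts thread through the venous loop, the FiO2 bisection and
  repeated forward calls, making a converged forward run cost a few
  milliseconds.
* The unit test suite runs the generator at a few hundred scenarios; the
  end-to-end acceptance run uses the full 15,236-scenario universe with 500
  training epochs at batch 128 (about a quarter of an hour of CPU), and the
  heavier in-suite end-to-end check trains 200 epochs at batch 32, a budget
  at which held-out accuracy has already plateaued near its final value.

## Known limitations

* Adapted-West implementations differ in formulation details — the exact
  dissociation-curve, CO2-content and acid–base equations, the mean-PACO2
  convention, and the residual set matched by the back-calculation. This
  package's choices are the standard published equations stated above. The
  shunt / low-V/Q attribution of the direct back-calculation is sensitive to
  the mean-PACO2 formulation at one to two pp per mmHg, so a different
  (equally defensible) convention shifts the split by a few points while
  leaving VenAd and the sensitivity structure unchanged.
* In hyperoxic scenarios the Riley ideal-compartment construction can price
  dissolved oxygen in high-V/Q compartments slightly above the ideal
  compartment, making computed low V/Q marginally negative (worst case about
  −0.3 pp in the sampling envelope). This is a documented artifact of the
  construct, not solver error, and is left unclamped.
* No measurement noise, temperature correction, abnormal hemoglobin species,
  diffusion limitation or hypoxic vasoconstriction dynamics are modelled.
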