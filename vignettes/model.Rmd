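---
title: "The adcea model: structure, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The adcea model: structure, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`adcea` is a patient-level (microsimulation) cost-effectiveness model of a
hypothetical disease-modifying treatment for Alzheimer disease, evaluated
from six progressively broader analytic perspectives. This vignette is the
package's own account of the science: what is modelled, what each tunable
parameter means, what the synthetic world does and does not emulate, and
where the design was genuinely open.

## 1. Model structure

Each simulated patient enters with mild cognitive impairment (MCI) and is
advanced in monthly cycles until death or age 105. Two arms — treated and
usual care — are run in lockstep on **common random numbers**: one uniform
draw per patient, cycle and event type (discontinuation,
institutionalization, death), shared across arms. With a null treatment
effect the two arms are therefore bit-identical, and with a positive effect
every arm difference is attributable to the treatment; this is also a large
variance reduction for incremental quantities (asserted empirically in the
test suite).

Within a cycle, events are applied in a fixed, documented order:

1. progression of the clinical scales (CDR-SB, MMSE, NPI) and ageing;
2. severity restaging and the time-in-stage clock;
3. the severity stopping rule for the drug;
4. the random discontinuation draw;
5. the institutionalization draw (community patients only);
6. the mortality draw;
7. accrual of utilities, life-years and costs for end-of-cycle survivors.

No ordering is canonical for a discrete-cycle model; this one was fixed
before calibration and is used identically by the single-patient operations
(`step_progression()`, `mortality_probability()`, ...) and the vectorised
cohort engine, which share one set of internal kernels.

## 2. Disease progression and treatment

The published predictive-equation systems that drive industrial AD
simulators are not public, so progression here is a transparent
parameterisation that preserves their qualitative structure:

- **CDR-SB** (0–18, higher = worse) increases by a stage-specific constant
  annual rate: 1.0 (MCI), 1.6 (mild), 2.0 (moderate), 2.0 (severe)
  points/year. The stage dependence stands in for the switch to
  severe-stage equations that calibrated simulators make at advanced
  disease.
- **MMSE** (0–30, higher = better) is coupled linearly to the *applied*
  CDR-SB increment: 1.6 MMSE points lost per CDR-SB point gained. The
  coupling honours the "interconnected scales" structure with one visible
  constant.
- **NPI** (behaviour, ≥ 0) worsens by 0.5 points/year in MCI and 1.5 in
  dementia, untreated in both arms: the treatment is defined on cognition
  only.
- **Conversion.** MCI becomes dementia when CDR-SB first reaches 4.5
  points; from then on severity is staged solely on MMSE (mild ≥ 21,
  moderate 15–20, severe ≤ 14). The conversion rule is an open design
  point (no published criterion accompanies the staging bands); 4.5 was
  chosen as a conventional trial threshold for incident dementia and is a
  single config knob.
- **Treatment.** While on drug the CDR-SB change rate is multiplied by
  `1 − treatment_effect` (base case 0.25, i.e. a 25% slope reduction — the
  level used in pre-dementia trial design). We read the effect as constant
  while on drug rather than as a 1.5-year pulse: the 1.5-year figure is the
  trial endpoint at which such a slope reduction is measured, not a decay
  time. The drug stops permanently at moderate dementia and discontinues at
  10%/year (converted exactly to a per-cycle probability,
  `p = 1 − 0.9^(1/12)`, so that 12 cycles compound back to 10%); there is
  no residual benefit after stopping.

All scores are clamped to their scale bounds after every update. A side
effect worth knowing: once CDR-SB saturates at 18, the coupled MMSE stops
falling too. In the default calibration MMSE is already near its floor at
that point, so the saturation has no practical consequence.

## 3. Mortality and location of care

Mortality multiplies a baseline age/sex life table by a proportional hazard
in the modelled covariate set (current cognition, trailing 12-month MMSE
decline, baseline cognition):

$$p_{\text{cycle}} = 1 - (1 - q_{\text{age,sex}})^{HR/12}, \qquad
HR = e^{\beta_1 (30-\text{MMSE}) + \beta_2 \cdot \text{decline} + \beta_3 (30-\text{MMSE}_0)}$$

with β₁ = 0.03, β₂ = 0.05, β₃ = 0.01 as documented placeholders for an
unpublished registry-based equation. The decline covariate is 0 during the
first simulated year (no trailing window yet). The bundled life table is
*synthetic* — a Gompertz-type schedule (`q = A·e^{0.09(age−60)}`,
A = 0.0055 female / 0.008 male, 5-year bands 55–105) — and is labelled as
such in its filename and documentation; replace it via `read_life_table()`
for applied work.

Community → residential transition is driven by time at the current
severity level, as in registry-calibrated models:
`rate = base(stage) · exp(0.01·months_in_stage + 0.03·(age − 75)) · 1.1^[female]`
with base monthly rates 0 / 0.002 / 0.008 / 0.02 by stage. Residential care
is absorbing; mortality applies equally in both locations.

## 4. Utilities and QALYs

Patient utility is the additive EQ-5D-style regression

$$u = 0.408 + 0.010\,\text{MMSE} - 0.04\,\text{NPI}
      - 0.159\,[\text{institutionalized}] + 0.051\,[\text{lives with caregiver}]$$

clamped to [0, 1]. The printed source of this regression typesets the
coefficients with multiplication signs between terms, which is
dimensionally incoherent; the additive linear reading implemented here is
the standard form of published EQ-5D mapping regressions. This is flagged
prominently because it is an interpretation, not a transcription.

Caregiver utility is a per-patient scalar: 1.00 while the patient has MCI,
then 0.85 / 0.84 / 0.82 by patient MMSE band (21–26, 15–20, 0–14) in
community dementia. When the patient is institutionalized the caregiver
returns to the general-population utility norm for their age — bundled
defaults 0.87 (< 65), 0.84 (65–74), 0.80 (75+), overridable. The same reset
is applied after the patient's death (the source rule covers only
institutionalization; death is treated analogously rather than truncating
caregiver experience mid-horizon). Caregiver QALYs, when a perspective
includes them, are added directly to patient QALYs.

QALYs and life-years accrue 1/12 year per cycle for end-of-cycle survivors,
discounted at 3%/year as `(1+r)^{-t/12}` with `t` the cycle index; the
death cycle itself accrues nothing (no half-cycle correction — a documented
simplification that affects both arms symmetrically and cancels almost
entirely in incremental values).

## 5. Costs

Monthly costs by stage (constant 2021-era US$, no inflation indexing):

| component | MCI | mild | moderate | severe |
|---|---|---|---|---|
| patient health care | 1174 | 1377 | 1833 | 2105 |
| patient non-health care | 207 | 384 | 611 | 1025 |
| caregiver health care | 705 | 731 | 748 | 759 |
| caregiver productivity | 925 | 2044 | 3019 | 5055 |

The productivity figures embed an opportunity-cost valuation (care hours vs
work lost, whichever is higher) and are not recomputed from hours. Caregiver
components stop at institutionalization, mirroring the caregiver-utility
reset; patient non-health-care costs (which include dependent-living
accommodation) continue. No separate residential per-diem is added: the
patient columns are treated as already embedding facility costs. The drug
costs $16,000/year pro-rated per cycle while on treatment, or — in one-time
mode — its full price at cycle 0 (discount factor exactly 1) in the
treatment arm only. Because price never feeds back into dynamics, one-time
scenarios re-price stored trajectories (`as_one_time()`) rather than
re-simulate.

## 6. Perspectives and the ICER engine

The six built-in scenarios compose components as: A = patient utility +
patient health care (incl. drug); B = A + caregiver health care; C = B +
caregiver utility; D = A + patient non-health care; E = B + patient
non-health care + caregiver productivity; F = all. All six are evaluated on
**one** shared set of trajectory pairs — the engine stores per-patient
discounted aggregates (QALYs, life-years, five cost components per arm), and
a perspective is a pure, bit-reproducible post-processing of those columns.
Scenario discount rates must equal the rate the pairs were accrued at; the
engine refuses silently mismatched rates rather than re-weighting.

ICERs are reported raw in machine output and rounded to the nearest $1,000
(thin-space grouped, e.g. `$183 000`) in text reports. Dominance quadrants
are labelled (`dominant`, `dominated`, `undefined` for ΔQALY = 0 with
ΔCost ≠ 0) instead of printing a ratio.

## 7. The synthetic cohort: what it emulates, what it does not

`generate_cohort()` draws an MCI cohort with the inclusion structure of an
ADNI-like trial population: MMSE uniform over 24–30, age truncated-normal
(73, 7) on [55, 90], 45% female, baseline CDR-SB truncated-normal (1.5, 1.0)
on [0.5, 4], NPI truncated-normal (3, 3) at or above 0, and exactly one
caregiver per patient, three years younger. No baseline table was published
for the population being emulated, so these are visible, overridable
assumptions — chosen once as field-plausible values, not fitted. Truncated
normals are drawn by inverse-CDF so a zero SD degenerates cleanly and the
cohort is a deterministic function of the config.

What the generator does **not** emulate: covariate correlations (age–MMSE,
sex–caregiving), education/ethnicity structure, multiple or absent
caregivers beyond a simple presence probability, and measurement error in
the scales. A green test on this cohort therefore establishes that the
*machinery* (progression, hazards, accounting, perspective composition) is
correct and internally consistent — not that the absolute ICERs transfer to
any real population.

## 8. Verification design

- Single-patient operations and the cohort engine share kernels, so unit
  tests on the operations constrain the engine.
- An **independent cohort-Markov oracle** (plain expectation-propagation
  arithmetic, written separately in the test helpers) reproduces the
  engine's per-arm mean QALYs and costs within 3 Monte-Carlo standard
  errors at n = 20,000, on a homogeneous cohort with no random
  discontinuation, where the score trajectory is deterministic and only
  death/institutionalization times are random.
- Null-effect runs are bit-identical across arms; incremental cost then
  equals the discounted drug cost exactly.
- The conditional ICER-ordering property (A ≥ B ≥ C, D ≥ E ≥ F when
  treatment only shifts severity occupancy) is tested on a world
  constructed to satisfy its premise: disease-blind mortality and
  stage-blind institutionalization make death and care-location times
  identical across arms under common random numbers, leaving the severity
  gradient as the only cost channel.

## 9. Known limitations

- **Survival extension vs caregiver costs.** With the default mortality
  betas, slowing cognitive decline extends life (≈ +0.15 discounted
  life-years at base case). Because caregiver costs stop at death and
  institutionalization, added community survival *increases* caregiver
  health-care spending in the treated arm, so the caregiver-cost-inclusive
  perspectives (B, E) can carry ICERs above their narrower counterparts.
  Published analyses of this design report essentially zero incremental
  life-years, under which those perspectives become cost-saving instead.
  The package's acceptance test for the published table shape is left
  failing on exactly those clauses rather than re-tuning the calibration
  post hoc; the tension is an honest property of the stated parameter
  world, and either behaviour is reachable through the mortality config.
- The progression engine is deliberately linear-in-stage; it does not model
  biomarkers, heterogeneity in decline rates, or treatment-effect waning.
- One caregiver per patient, with per-patient scalar utilities; household
  structures are out of scope.
- Probabilistic sensitivity analysis and value-based price solving are out
  of scope; all reported uncertainty is Monte-Carlo error around means.
- The canonical config format is JSON (not YAML): the supported dependency
  set ships no YAML parser, and adding one for format sugar was not worth a
  dependency.
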