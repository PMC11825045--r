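---
title: "Mechanical power, safe upper limits and individualized ventilation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanical power, safe upper limits and individualized ventilation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpvent)
```

## The problem

Mechanical ventilation keeps patients with failing lungs alive, but the
energy the ventilator delivers to the respiratory system — its *mechanical
power* (MP, J/min) — can itself injure lung tissue (ventilator-induced lung
injury). `mpvent` implements a retrospective-cohort analysis pipeline for
pressure-controlled ventilation: it quantifies each admission's MP exposure,
asks whether exposure above some level separates ICU survivors from
nonsurvivors, derives hypoxemia-stratified "safe upper limits", predicts ICU
mortality from ventilation and laboratory features, and finally runs a
closed-loop what-if search that retunes ventilator settings until the
mortality model's prediction flips to survival.

Because the clinical databases such analyses draw on are access-restricted,
the package ships a synthetic cohort generator with a *known* mortality
mechanism. Every downstream stage is exercised, and its operating
characteristics quantified, against that generator.

## Exposure metrics

**Surrogate mechanical power.** In pressure-controlled ventilation the
package uses the surrogate

$$\mathrm{MP} = 0.098 \cdot TV \cdot RR \cdot (\mathrm{PEEP} + \Delta P),$$

with tidal volume $TV$ in litres, respiratory rate $RR$ in breaths/min, and
pressures in cmH2O. $\Delta P$ is the inspiratory driving pressure above
PEEP, so $\mathrm{PEEP} + \Delta P$ is the peak inspiratory pressure. A
literal product of the two pressure terms (available behind
`pressure_mode = "product"` for audit) yields values an order of magnitude
above any published cohort median and is never used by the pipeline: at
typical nonsurvivor settings (TV 0.46 L, RR 19.8, PEEP 9.1, ΔP 14.6) the sum
form gives 21.15 J/min, squarely in the reported range, while the product
form gives ≈ 192 J/min.

**Ideal body weight.** MP is normalised to the Devine ideal body weight,
$50\,(45.5) + 0.91\,(\text{height}_{cm} - 152.4)$ kg for males (females).
Devine was chosen because it reproduces the published height↔IBW
correspondences exactly (175 cm ↔ 70.57 kg; 165 ↔ 61.47; 185 ↔ 79.67).

**Time-weighted averages.** Ventilator settings are step functions — a
charted value holds until the next chart entry — so TWAs use sample-and-hold
integration over the first 24 h and 48 h of ventilation, divided by the
covered duration; trapezoidal weighting would smear deliberate step changes.
MP is computed per sample and then time-weighted. The product of the
TWAs of the inputs is *not* the TWA of MP whenever settings co-vary in time,
and the pipeline never computes it. The 48-h standard deviation of
per-sample MP (`sd48_mp`) captures exposure variability.

## Hypoxemia stratification

Admissions are stratified by the PaO2/FiO2 ratio (PFR) over the first six
hours of ventilation: nonhypoxemic (> 300), mild (200–300), moderate
([100, 200)), severe (< 100). Published range conventions overlap at the
boundaries; this package fixes 300 and 200 as belonging to *mild* and 100 to
*moderate*, which matches the printed integer ranges with an
upper-inclusive mild band. "Over the first six hours" is read as the
time-weighted mean PFR in the window; a worst-value (window-minimum) option
is exposed via `assign_hypoxemia(..., summary = "worst")` for sensitivity
analyses.

## Preprocessing

* **Inclusion**: age ≥ 18 years, ≥ 48 h of ventilation (which excludes
  patients who died or were extubated earlier), known ICU outcome. The
  per-rule exclusion tally is attached to the filtered table.
* **Plausibility cleaning**: exact duplicate samples and values outside
  per-variable bounds are removed and logged. Published analyses name the
  rule but not the bounds, so the defaults
  (`default_plausibility_bounds()`: TV 0.05–1.5 L, RR 4–60, PEEP 0–30,
  ΔP 1–60, pH 6.5–7.9, PaO2 20–600 mmHg, …) are deliberately config-visible
  decisions, not reconstructions.
* **k-NN imputation** (`k = 7`): features missing in more than 10% of rows
  are dropped and reported; remaining missing cells are filled with the mean
  of the k nearest rows, distance being the root-mean-square difference over
  mutually observed z-score-standardised features. Standardisation before
  the distance is our choice (the metric is otherwise dominated by
  large-unit features); observed cells are never altered, and with fewer
  than k candidate rows the column mean is used and flagged.

## Safe upper limits

Within each stratum (and pooled), a one-sided Mann-Whitney test asks whether
MP (or MP/IBW) is stochastically greater among nonsurvivors. Only if
$p < \alpha$ (default 0.05) is a limit returned: the survivors'
$(1-\alpha)\cdot 100$th percentile. That reading — the upper tail of the
*survivor* distribution at the significance level — is the only
order-consistent one that produces limits of the magnitude survivor medians
support; the $\alpha\cdot100$th-percentile alternative would sit below
almost every survivor. Percentiles interpolate linearly between order
statistics (`stats::quantile` type 7, configurable).

The rank test uses exact enumeration when both arms have ≤ 8 observations
and no ties, and the normal approximation with tie and continuity correction
otherwise. Because both the gate and the threshold are order statistics, a
present limit commutes with monotone transforms of the exposure — a property
the tests verify, along with exact agreement with brute-force enumeration at
small n and a Monte-Carlo check that under the null the limit appears at
rate ≈ α.

A per-kg limit converts to absolute power by plain multiplication
(`to_absolute_mp`): 0.22, 0.27 and 0.34 J/min/kg at the 70.57 kg reference
IBW give 15.53, 19.05 and 23.99 J/min.

Survival is then compared between admissions above and below each limit: a
Cox proportional-hazards fit on the group indicator with explicit,
user-supplied adjustment covariates, and Kaplan-Meier curves per group with
administrative censoring at 90 days. The covariate list is deliberately
explicit config — "noncollinear variables significantly associated with
mortality" is not a reproducible prescription, so nothing is selected
silently.

## Mortality prediction

The feature recipe is: seven mandatory ventilation features (MP, MP/IBW,
TV per kg IBW, 48-h SD of MP, PEEP, RR, ΔP); greedy removal, in column
order, of any later feature correlated above 0.9 in absolute value with an
earlier one (mandatory features are never removed — the tie-break is ours,
published recipes are silent); then the top 10 remaining features by seeded
random-forest impurity importance (permutation importance available by
config).

Six classifiers run under stratified 5-fold cross-validation with
library-default settings: logistic regression, random forest, SVM (RBF),
AdaBoost (SAMME over depth-1 stumps), XGBoost, and a stacking ensemble
(logistic meta-learner over out-of-fold base probabilities from the
logistic, forest, XGBoost and AdaBoost bases). Class imbalance is handled by
SMOTE — synthetic minority rows are convex combinations of a minority row
and one of its 5 nearest minority neighbours — applied *inside each training
fold only*; accuracy, precision, recall and AUROC are computed on the
untouched original test folds (evaluating on oversampled folds would inflate
every metric; the leak-free choice is documented rather than assumed).
Everything is deterministic per seed.

Feature attribution for the boosted-trees model uses TreeSHAP
(`importance_ranking`), whose per-row attributions sum to the margin
prediction up to single-precision accuracy; models without attribution
support fall back to flagged permutation importance.

## Individualization of ventilator settings

For a patient the frozen mortality model predicts to die, the individualizer
searches candidate settings until the prediction flips:

1. **Acidosis gate**: respiratory acidosis (PaCO2 > 45 mmHg AND pH < 7.35)
   switches the objective from *minimise MP* to *maximise minute
   ventilation* (VE). Published descriptions also mention a PaCO2 > 50
   worked example; the conjunction definition is used and both thresholds
   are config. Missing blood gases skip the patient with a note.
2. **Candidate grid**: TV 4–8 mL/kg IBW in 0.5 steps (a lung-protective
   envelope), RR 10–35. The driving pressure each TV implies follows from an
   estimated respiratory-system compliance ($TV = C\,\Delta P$, $C$ =
   current TV/ΔP by default); combinations whose ΔP leaves the safety
   bounds are infeasible rather than clipped, so $TV = C\,\Delta P$ holds
   exactly on every candidate. PEEP is never searched: its titration is
   delegated to a parallel workflow, which removes one degree of freedom.
3. **Objective constraints and ordering**: non-acidotic candidates must not
   exceed the current MP and are walked in ascending MP; acidotic candidates
   must reach the VE target (current VE plus a configurable increment,
   within 5% tolerance) and are walked in descending VE. Ties break toward
   lower MP, then lower RR.
4. **Flip loop**: each candidate's ventilation-derived features (mp, mp_ibw,
   tv_mlkg, rr, dp, ve) replace the patient's; non-ventilation covariates
   are frozen — whether a bedside implementation would refresh them is
   ambiguous, freezing is the conservative reading. The first candidate the
   model predicts to survive (probability below the 0.5 cut, configurable)
   wins; if none does, the settings are left unchanged.

Because candidates are walked best-first, the returned setting equals the
best-by-ordering flipping candidate found by exhaustive enumeration — an
oracle the tests check grid-point by grid-point, together with the
objective-compliance invariants (flipped non-acidotic patients never end
above their initial MP; flipped acidotic patients hold their VE target).
`case_study()` aggregates flips over predicted nonsurvivors; its percentage
is reported to one decimal (58 of 614 → 9.4).

## The synthetic cohort generator

`generate_cohort()` emulates the *post-extraction* analysis table of an
adult pressure-controlled-ventilation cohort — never a database schema or
waveforms:

* **Case mix**: four hypoxemia strata at probabilities (0.263, 0.315,
  0.359, 0.063); 2:1 male; heights ~ N(175, 10) clipped to 150–200 cm; ages
  ~ N(63, 16) clipped to 18–95.
* **Ventilation series**: piecewise-constant settings with Poisson setting
  changes (one expected change per 12 h — enough to make time weighting
  non-trivial), sampled hourly by default over ≥ 48 h. RR is drawn from
  13–27, PEEP 5–15, ΔP 8–20 cmH2O, with worse strata shifted toward harder
  ventilation; TV is compliance × ΔP (compliance ~ N(35, 8) mL/cmH2O),
  clipped to 0.2–0.9 L. These envelopes were set once so the generated TWA
  medians land on the published cohort values (RR ≈ 20, ΔP ≈ 14, TV ≈
  0.48 L, MP/IBW ≈ 0.31–0.35 J/min/kg).
* **Oxygenation**: each admission's PFR is held at its stratum target over
  the first six hours (so the latent stratum is recoverable by
  construction) and wanders ±8% thereafter.
* **Mortality**: death is Bernoulli with
  $\mathrm{logit}\,p = \beta_0 + \beta_{MP}\,\mathrm{MP/IBW}_{48h} +
  \beta_{age}\,\text{age} + \beta_{lact}\,\text{lactate}$, defaults
  $\beta_0 = -3.9$, $\beta_{MP} = 1.4$ per J/min/kg (≈ OR 1.02 per J/min at
  70.57 kg IBW), $\beta_{age} = 0.026$/yr, $\beta_{lact} = 0.153$ (≈ OR
  1.165). The marginal death rate is ≈ 29%. Because the mechanism is known,
  parameter-recovery tests are meaningful; `inject_mortality_threshold()`
  additionally raises the log-odds by a chosen jump exactly above a chosen
  MP/IBW level, for limit-recovery experiments.
* **Missingness** is MCAR only, applied to laboratory values and measured
  (non-setting) signals at a configurable rate (default 5%, capped at 50%).

What the generator does **not** emulate — and hence what green tests do not
demonstrate about real data: informative missingness, inter-variable lab
correlations (each lab is drawn marginally), treatment feedback (settings do
not respond to blood gases), competing risks, or admission-level clustering
by specialty. Conclusions from this package about any real cohort require
that cohort.

## Numerical choices and degenerate inputs

* TWA windows are anchored at ventilation start; an empty window yields a
  missing value and a flag, never zero.
* Exact rank tests switch to the tie-corrected normal approximation at 9+
  observations per arm or any tie.
* Logistic separation (|slope| diverging, SE > 100) is flagged and no OR is
  reported; Cox fits that fail or return non-finite coefficients are marked
  degenerate; strata without a limit are omitted from survival reports with
  a note.
* SMOTE requires ≥ 2 minority rows; with fewer neighbours than k = 5 it
  uses all available ones.
* All suite randomness (folds, oversampling, forests, boosting) is a pure
  function of the user seed.

## Problem sizes used by the test suite

The shipped tests quantify operating characteristics at sizes chosen to
give stable Monte-Carlo verdicts: type-I control of the limit gate on 2,000
null replicates at 200/arm (3 MC SE band), gate power on 500 replicates at
400/arm under a 1.0 log-odds step, OR coverage on 200 replicates of
n = 20,000, null AUROC calibration at n = 1,200 under 5-fold CV, and
individualizer soundness on a 500-admission cohort against exhaustive grid
enumeration.

## Known limitations

* The surrogate MP formula ignores flow/resistive work and inspiratory-time
  effects; it is not the full elastic-power equation, by design.
* Safe limits are survivor percentiles gated by a rank test — they are
  descriptive thresholds, not causal dose limits.
* The hazard-ratio report fits a group indicator (above/below limit);
  per-unit hazard interpretations require a different model, which the
  package deliberately does not guess.
* The individualizer is a retrospective what-if engine; it has no notion of
  bedside safety beyond its static bounds.
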