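---
title: "Reconstructing DEHP intake from surveys, questionnaires and urinary biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing DEHP intake from surveys, questionnaires and urinary biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dehpintake)
```

## Scope and problem

After the 2011 Taiwan incident, in which DEHP had been used for years as a
clouding agent in five categories of foods, exposure had to be
reconstructed retrospectively for a clinical cohort: DEHP metabolites clear
from urine within roughly a day, so biomarkers measured at clinic visits a
year later say nothing about intake during the incident. The package
reconstructs the average daily intake `AvDI` (ug per kg body weight per
day) from three imperfect sources -- agency concentration surveys,
food-frequency questionnaires (FFQ) and self-reported exposure histories --
plus urinary biomarkers for the current background component, and
propagates all quantified uncertainties as posterior draws rather than
point estimates.

## The concentration model

Each food category is fitted independently from survey records that carry
an agency (KBOH or TFDA), a status (`detected_quantified`,
`detected_censored`, `not_detected`) and, for quantified records, a
concentration in ppm. Repeated measurements of a product are merged first:
quantified values collapse to their geometric mean (concentrations are
lognormal-like, so the geometric mean is the natural location), a
quantified value dominates a censored one, and any detection dominates a
non-detection.

Three sub-models share the posterior:

* **Detection.** `logit P(not detected) = alpha + beta I(TFDA)`; `exp(beta)`
  is the TFDA/KBOH odds ratio for non-detection. The reported `p_D` is the
  baseline (KBOH) detection probability `1 - plogis(alpha)`. The published
  per-category summaries are consistent with a baseline-stratum convention
  for three of the five categories and with a pooled convention for one;
  we adopt the baseline convention uniformly because it composes cleanly
  with the agency effect.
* **Tainted-food mixture.** Detected concentrations lie in disjoint ppm
  intervals starting at the 1-ppm screen. Each bin carries a lognormal
  component truncated to the bin, and bin weights get a Dirichlet(1, ..., 1)
  prior updated by the quantified bin counts. Censored "> 1 ppm" records
  span every bin, so they are uninformative about the weights and the bin
  parameters; they inform only the detection sub-model.
* **Sub-threshold split.** The non-detected mass is split into a point mass
  at zero (`p_0`) and a uniform component on (0, 1) ppm (`p_1`) by a
  Beta(1, 1)-prior fraction. The 1-ppm screen makes this split invisible to
  the data, so its posterior equals its prior; it is carried honestly as
  prior uncertainty rather than estimated. Every draw satisfies
  `p_D + p_0 + p_1 = 1`, a convention we enforce because the published
  per-category rows do not sum exactly to one and sampling requires a
  proper partition.

Expected concentrations are derived per draw:
`E(Y) = sum_k w_k m_k` with `m_k` the truncated lognormal mean of bin `k`,
and `E(C) = p_D E(Y) + 0.5 p_1`. `E(C) <= E(Y)` holds by construction.

### Priors and numerical choices

* Priors are weakly informative: Normal(0, 10^2) on the detection logits,
  Normal(0, 10^2) on log-means, Half-Normal(0, 5) on log-SDs,
  Dirichlet(1, ..., 1) on weights, Beta(1, 1) on the sub-threshold split.
* **Bin-constrained log-means.** Under truncation, a flat location prior
  leaves an unidentified ridge (log-mean far below the bin with a huge
  log-SD mimics a log-uniform shape inside the bin). Since each component
  is meant to describe its own interval, the log-mean is constrained to the
  bin. This removes the ridge; simulation-based calibration in the test
  suite shows near-nominal credible-interval coverage with it.
* **Capped last bin.** The last bin is nominally open-ended, but with the
  weak priors an empty last bin would make prior-fallback draws of `E(Y)`
  astronomically large. It is truncated at a physical cap (default 5000
  ppm, above the incident's observed maximum of about 3000 ppm).
* **Sampler.** Random-walk Metropolis within Gibbs: separately tuned
  univariate updates for `alpha` and `beta` (the latter can be
  prior-dominated and much wider), per-bin updates in which the log-mean
  proposal scales with the current log-SD (the conditional posterior of the
  location widens with the scale -- funnel geometry), plus a joint
  stretch move along the bin's location-scale ridge with the appropriate
  Jacobian. Proposal scales adapt only during burn-in, preserving detailed
  balance afterwards. Defaults: 4 chains, 5000 burn-in, 10000 kept draws
  total; convergence is monitored by split-chain R-hat and flagged (not
  fatal) above 1.1.
* Concentrated-juice values are divided by 7 (the dilution ratio) before
  fitting; the divisor is configurable.
* Categories without quantified detections fall back to the mixture priors
  with a warning; their `E(Y)` intervals are wide by design.
* The summary table reports the posterior median of `exp(beta)`: in sparse
  strata the posterior of `beta` is heavy-tailed upward and the mean of its
  exponential is dominated by the tail.

## Background intake from urine

The three metabolite concentrations (ug/L, equivalently ng/mL) are
converted to a creatinine-normalised molar sum
`UE_sum = sum_m (conc_m / MW_m) / creatinine` (umol/g). Intake follows with
the 24-h molar excretion fraction `F_UE = 0.32` and `MW_DEHP = 390.56
g/mol`: children and adolescents use an absolute daily creatinine excretion
`CE` (g/day) from a sex- and height-indexed table, adults use
body-weight-normalised rates (23 mg/kg/day men, 18 women). Values flagged
below the detection limits (0.7, 0.3, 0.3 ng/mL) are substituted by
LOD/sqrt(2), a common convention, configurable. The packaged child CE table
is a synthetic approximation (CE proportional to height cubed, scaled to
plausible paediatric values and monotone in height) because the cited
reference table is not reproduced in the source material; users can supply
their own table.

## Dietary dose reconstruction

For each participant and category, one exposure scenario is resolved:

* a self-report, when present, takes precedence and zeroes the
  questionnaire contribution for that category (avoiding double counting);
  its concentrations come from the tainted mixture;
* otherwise the questionnaire belief drives the concentration draw -- yes:
  tainted mixture (mean `E(Y)`); unsure: overall category distribution
  (mean `E(C)`); no: zero.

Weekly-frequency categories map to midpoints 1, 4 and 7 times per week
(converted to per-day), duration categories to 3, 9 and 18 months with the
open-ended "> 2 years" class capped at 24 months; only the 9-month midpoint
is stated in the source material, the others are interval midpoints.
Missing self-report amounts and frequencies are imputed with cohort means
of the reported values (the missingness is modelled as completely at
random). Consumption amounts default to a 350-ml standard bottle for the
three drink categories, a Normal(15, 5^2) g/day amount truncated at zero
for fruit jam, and the self-reported or cohort-average dosage for
supplements; all are configurable, as the distributional table they stand
in for is not public.

The averaging time `AT` is the maximum questionnaire duration across
categories; for self-reports, durations of discontinuously consumed foods
are summed while simultaneous consumption contributes through the maximum.
The intake equation `AvDI = sum_i Y_i M_i EF_i ED_i / (AT BW_b)` uses the
unit contract ppm = mg/L (liquids) or mg/kg (solids), so ppm times ml (or
g) is micrograms.

Body weight is back-projected to the incident end by the growth-rate
coefficient `gamma = median_weight(age) / median_weight(age - lag)` from a
sex-by-age reference of medians (ages 0-18 in half-year steps, anchored to
the published values 18.3 kg and 15.3 kg for boys of 5 and 3.5 years;
`gamma = 1` for adults). Stochastic draws use Normal(gamma, (0.16 gamma)^2)
truncated below at 0.5: the unbounded normal with CV 0.16 can cross zero in
extreme draws, and weights above twice the back-projection are implausible.

The window-period variant replaces `AT` by `AT + lag` and `BW_b` by the
present weight for the dietary components only. Whether the background
component should also change is not specified in the source material; we
leave `AvDI_ENV` unchanged because it is defined from post-incident urine
and already refers to the current period. `AvDI_ALL` is the per-draw sum of
the three components, and the windowed total is draw-wise no larger than
the unwindowed one whenever the draw's `BW_b` does not exceed the present
weight.

## Reporting

Classification uses left-closed thresholds at 20, 50 and 100 ug/kg_bw/day
(a value of exactly 20 is medium), applied to the per-participant posterior
mean of `AvDI_ALL` -- a point summary is needed for a count table, the
source material does not say which, and the mean is the default with the
median available. Group comparisons use the Pearson chi-square without
continuity correction; component correlations default to Pearson on the
posterior means (the correlation type is not stated in the source
material) with Spearman available. Posterior summaries use type-7
(linear-interpolation) quantiles.

## The synthetic world

The generator's defaults state the incident world: survey sizes per
category and agency equal to the published totals (1582 records), baseline
detection probabilities and agency odds ratios equal to the published
estimates, a three-bin mixture on edges 1/10/100 ppm spanning roughly 1 to
several thousand ppm, half of detected records censored to "> 1 ppm", a
237/13/97 cohort with deterministic exclusion counts (10/0/1 missing urine,
0/1/1 negligible frequency, reproducing the 227/12/95 eligibility
arithmetic), self-report provision rates of 0.90/0.80/0.76 by age group
(matching the reported 213/237 children and 74/97 adults), and urine
panels with the published detection limits. Quantities the source material
does not state -- behaviour probabilities, amount distributions, metabolite
log-normal parameters, visit lags of 440-630 days -- were chosen once at
plausible field values and documented in `synth_config()`.

Ground truth defines the true dietary intake from the **true category-level
expected concentrations** (`E(Y)` or `E(C)` of the true mixture), not from
per-participant random product draws: the estimand is the expected intake
given the scenario, and individual product concentrations would add
irreducible noise that no estimator could remove. True amounts, frequencies
and durations are the pre-missingness values, mapped through the same
midpoint conventions the reconstruction uses, so recovery tests isolate
estimation error (survey inference, imputation, Monte Carlo) rather than
convention mismatches.

What a green test establishes, and what it does not: parameter recovery and
rank-correlation tests run in a *well-identified* synthetic world (dense
surveys of 1000 records per agency, balanced bin weights), because with the
incident-sized sparse surveys the drink-category posteriors are necessarily
prior-dominated -- that sparseness is a property of the data, not a defect
of the estimator, and no method could recover what the 1-ppm quick screen
discarded. The tests therefore establish correctness of the machinery, not
that the incident data pin down every parameter. The generator also does
not emulate recall bias, correlated questionnaire errors, or within-person
pharmacokinetic variation (a single steady-state urine draw stands for the
background).

## Limitations

* The sub-threshold split `p_1` is prior-driven by construction; its value
  matters only through a bounded `0.5 p_1` ppm term in `E(C)`.
* The supplementary bin definitions and prior choices of the original
  analysis are not public; defaults are documented and configurable, and
  the package's estimates should be compared with the published ones only
  at that level of fidelity.
* The child creatinine table and the growth-reference medians are synthetic
  approximations anchored to the published values.
* Self-report precedence zeroes a category's questionnaire contribution
  entirely; partial double counting within a category is not modelled.
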