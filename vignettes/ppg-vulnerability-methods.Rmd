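---
title: "Methods: personalized prediction of postprandial glucose excursions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized prediction of postprandial glucose excursions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the modelling approach

People with type-2 diabetes differ widely in how their blood glucose responds
to meals: the same bowl of rice can produce a large post-meal spike in one
person and barely move another. `ppgv` implements an idiographic
(one-model-per-person) pipeline that asks, for each individual separately:
*given what and when this person just ate, and which glucose-lowering agents
are active, will this meal produce a postprandial glucose (PPG) excursion
relative to their own typical response?* — and then reads the fitted model's
feature importances back as that person's *vulnerability profile*: the mix of
dietary and temporal factors that predict their excursions.

The outcome for each meal is built in three steps:

1. **2-hour incremental AUC (iAUC).** The anchor glucose $G_0$ is the CGM
   reading nearest the meal within ±20 min. The iAUC is the trapezoidal
   integral of $\max(G(t) - G_0, 0)$ over the 120 min after the meal
   (mg/dL·min). Negative increments are clipped — the positive-part
   convention standard in the glycemic-response literature. The value is
   *undefined*, never zero, when the window has fewer than 5 readings or its
   readings span less than 100 of the 120 min.
2. **Expanding personal baseline.** Meal $i$'s baseline is the mean of that
   person's iAUCs for meals $1..i-1$. The first defined meal has no baseline
   and is never labelled.
3. **Binary excursion label.** Label 1 iff iAUC strictly exceeds the
   baseline; a tie is not "higher", so it labels 0.

Each eligible participant gets two gradient-boosted-tree classifiers
(binary logistic XGBoost):

* **low-burden** — features available passively: hour of day, day of week /
  month, month, day of study, meal-slot indicator, ate-in-last-8h/24h flags,
  and the previous usable observation's label;
* **high-burden** — the same plus manually logged meal content (grams per
  food group and total, current meal and trailing 8-h/24-h sums, presence
  indicators) and medication features (per agent class: an active-window
  flag and active dose, plus trailing 8-h/24-h dose sums).

Rows are split 70/30 chronologically (first `floor(0.7 n)` rows train).
Hyperparameters are chosen by 4-fold rolling-origin cross-validation inside
the training rows: the training window is cut into five contiguous blocks,
fold $j$ fits on blocks $1..j$ and validates on block $j+1$, so validation
data always lies strictly after its fitting data. The selection metric is
mean defined-fold F1 of the positive class at threshold 0.5, matching the
headline evaluation metric; ties prefer the simplest model (fewer rounds,
then shallower trees, then larger learning rate).

Model comparison is per person: the better of the two F1s defines the best
model; participants are subgrouped by which schema won, and a paired
two-sided Wilcoxon signed-rank test (normal approximation with continuity
correction, zeros dropped, average ranks) is run within each subgroup. We
keep this subgroup-then-test procedure for fidelity to the analysis it
replicates, but print a caveat with the report: testing a difference inside
a subgroup selected on the sign of that difference is circular, so those
p-values describe effect size rather than confirm a hypothesis.

Vulnerability profiles normalize each feature's total gain in the best model
to a percentage of the summed gain, then aggregate to interpretable
categories (staples, vegetable intake, total grams intake, hour of the day,
previous PPG excursion, ...). A mean-|SHAP| profile is computed alongside:
the "mean absolute importance across data points" phrasing fits SHAP, while
gain is a global split statistic, so both are emitted rather than guessing
which was meant. Missing-indicator columns inherit their parent feature's
category, so the category map partitions every column of both schemas.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `window_min` | 120 | min | the 2-h PPG window |
| `anchor_tol_min` | 20 | min | tolerates one missed reading next to the meal |
| `min_points` / `min_coverage_min` | 5 / 100 | readings / min | rejects gap-ridden windows while tolerating one missed 15-min reading |
| `min_obs` | 20 | usable meals | supports 14 train / 6 test; exactly 20 is included |
| `train_frac` | 0.70 | — | chronological split fraction |
| `k` | 4 | folds | rolling-origin CV |
| `threshold` | 0.5 | probability | classification cut; not tuned |
| action windows | basal/intermediate (2, 24] h; bolus (0.25, 4] h; non-insulin (0, 6] h | hours | pharmacodynamic onset/offset per agent class |
| meal slots | breakfast 05–10, lunch 11–15, dinner 16–22 | clock hours | slot boundaries are not standardized; these cover Chinese mealtime conventions |

The eligibility boundary deserves a note: the flowchart wording "≤ 20
observations" conflicts with the training-requirements wording "a minimum of
20"; the split arithmetic (14 + 6) needs exactly 20, so a participant with
exactly 20 usable observations is included here.

The full tuning grid is reproduced as printed — `nrounds` {50, 100, 150},
`eta` {0, 1e-4, 1e-3, 0.01, 0.015}, `max_depth` {1, 2, 3}, `gamma` {−0.5,
0, 0.5}, `colsample_bytree` {0.5, 1, 2}, `min_child_weight` {1, 2},
`subsample` 1 — but two of those values are outside the booster's legal
domain, so the grid is sanitized before fitting: `gamma` −0.5 → 0 (must be
nonnegative) and `colsample_bytree` 2 → 1 (a column fraction), then
duplicates dropped (360 points). `eta = 0` is retained; it produces a
constant model and never wins on informative data. `fast_hyper_grid()` is a
12-point subset (informative learning rates, all depths) used for the
large simulation studies; on a 28-row training set the full sanitized grid
takes ≈ 10 s per participant-schema on one core, the fast grid well under
a second.

Boosters run single-threaded with a fixed seed and a fixed intercept
(`base_score = 0.5`), which both keeps runs byte-reproducible and makes
single-class fold fit sets legal inputs.

# What the synthetic generator emulates — and what it does not

The generator stands in for a 67-adult, ~2-week observational CGM study. A
participant's trace is

$$G(t) = b + A\sin\!\big(2\pi (h(t)-16)/24 + \pi/2\big)
        + \sum_m H_m\, s(t - t_m) + \varepsilon(t),$$

with personal baseline $b \sim U(120, 180)$ mg/dL, circadian amplitude $A$,
i.i.d. Gaussian noise, and a triangular meal pulse $s$ rising to its peak at
45 min and returning to baseline at 180 min — chosen piecewise-linear so the
2-h pulse area has a closed form (`pulse_area()`), which the iAUC oracle
tests integrate against. Pulse height is a weighted sum of standardized
exposures (grams/100 per food group; a person-specific risk-window indicator
for the hour driver), shrunk by $(1 - \text{med\_suppression})$ when any
agent from the participant's daily regimen is active at meal time under the
same action windows the feature builder uses.

Schedules emulate the observed scale: three daily slots (07:30, 12:12,
18:18) with ~36 min jitter plus an afternoon snack with probability 0.23,
giving 3.23 meals/day in expectation over 14 days; meal times are snapped to
the CGM grid, as diet entries in the source spreadsheets share the sensor's
timestamp rows. Food-group grams are lognormal, scaled to the observed
per-group daily means (staples 222 g, vegetables 155.9 g, animal foods
144.9 g, dairy 82.3 g, fruits 31 g, legumes/nuts 8.8 g, sweets 1.5 g).
Those printed group means sum to ≈ 646 g/day, which does not match the
separately printed ≈ 913 g/day total (the source total evidently includes
uncoded items); the generator keeps the per-group means and defines total
as the group sum. Optional missingness injection drops CGM readings and
blanks gram cells to exercise the coverage rules and imputation.

Scenario mixes control the planted heterogeneity: `"mixed"` (the default:
35% staples-driven, 30% timing-driven, 20% medication-masked, 15%
noise-only), homogeneous variants of each type, `"strong_mixed"` (low-noise
staples/timing drivers with bimodal servings — a strong, learnable signal),
and `"single_driver"` (one dominant category per person at ≥ 5× any other
weight). Each participant's truth (weights, noise, suppression, seed) is
stored so recovery tests can check the pipeline finds what was planted.

The generator deliberately does **not** model glucose–insulin physiology:
no ODE dynamics, no carbohydrate absorption kinetics, no insulin-dose
response curves, no inter-meal dependence beyond pulse overlap. Passing
recovery tests therefore show the *pipeline* recovers planted statistical
structure; they do not certify performance on real CGM data, where signal
strength, missingness patterns, logging error and unmodelled drivers
(sleep, stress, activity) differ.

# Numerical choices and degenerate inputs

* iAUC integration interpolates the trace linearly at the exact window
  boundaries when readings exist on both sides, so the integral always runs
  over the nominal 120 min regardless of grid phase; and the positive part
  is integrated exactly on the piecewise-linear interpolant — a segment
  crossing the anchor level contributes only its positive lobe, rather than
  clipping at the sample points first.
* Meals closer than 120 min apart both get iAUCs over their own overlapping
  windows; no de-overlapping is attempted.
* Ties: iAUC equal to baseline labels 0; equal F1s report schema `"tie"`;
  grid ties resolve to the simplest model by a documented sort.
* Undefined propagates: precision with no positive predictions, F1 with an
  undefined component, fold F1 on an all-negative validation block — all NA,
  dropped from means, never coerced to 0. If every fold of every grid point
  is undefined the participant gets a flagged majority-class fallback whose
  profile is all-zero.
* Imputation is per-participant, per-feature median computed on the training
  rows only and applied to both portions; indicator columns record exactly
  which cells were imputed; constant indicators are dropped.
* Equal-timestamp rows keep insertion order (stable sorts throughout).
* Unit auto-detection treats a CGM series with median < 30 as mmol/L
  (× 18.018); the physiologic ranges cannot overlap, and normalization is
  idempotent.

# Validation problem sizes

The test suite validates against independent oracles at these sizes, chosen
to exercise the properties well while keeping a full run on one core in the
minutes range: 1,000 noise-free meals against the closed-form pulse area
(tolerance 2%, dominated by trapezoid discretization); 1,000 random
sequences against a literal prefix-mean labelling loop (exact label match);
exact sign-enumeration of the signed-rank null (normal approximation within
0.02 on the tied n = 8 worked example and on distinct-|difference| cases at
n = 9–12 — the regime where the exact distribution's own discreteness does
not already exceed that bound; at n ≤ 8 the exact two-sided p moves in
steps larger than 0.02, so no continuous approximation can track it
uniformly there); a 30-individual strong-driver cohort for signal
recovery (median best-model F1 at least 0.15 above the always-positive
base-rate F1); and a 50-individual single-driver cohort for vulnerability
recovery (dominant category top-ranked for ≥ 70%). The recovery studies use
the fast grid.

# Known limitations

* The free-text food lexicon is a compact keyword table; coverage of real
  logs is best-effort and unmapped grams are reported, not dropped.
  Synthetic data bypasses text parsing entirely by emitting structured
  grams.
* Medication "current" intake is encoded as active-window indicators plus
  dose sums, one explicit reading of a time-varying conversion; dose-weighted
  decay curves are a plausible alternative the data cannot adjudicate.
* `prev_excursion` carries no recency cap, and when meals sit closer than
  the 2-h window the previous label is formally resolved only after the
  current meal — an inherent property of the lagged-outcome design.
* The subgroup Wilcoxon tests are descriptive (see the circularity caveat
  above).
* Cohort-level F1 summaries exclude individuals whose F1 is undefined;
  with-versus-without variants are both reported in the comparison summary.
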