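# ppgv — personalized prediction of postprandial glucose excursions

`ppgv` is an R package and analysis workflow for *idiographic* (per-person)
modelling of postprandial glucose (PPG) excursions in type-2 diabetes. It
takes one individual's continuous glucose monitor (CGM) trace plus their
meal and glucose-lowering-agent logs, and answers, for that individual:

1. **Will this meal produce a PPG excursion**, relative to the person's own
   typical response?
2. **Does manual meal/medication logging improve the prediction**, or does
   passively collected CGM + clock data suffice?
3. **Which dietary and temporal factors drive that person's vulnerability**
   to excursions?

It is aimed at researchers building personalized glycemic prediction models
or just-in-time adaptive interventions from free-living CGM studies.

## The statistic at the core

For each meal at time $t_m$, the 2-hour incremental area under the curve is

$$\mathrm{iAUC}_m = \int_{t_m}^{t_m + 120\,\mathrm{min}}
  \max\{G(t) - G_0,\, 0\}\; dt \quad [\mathrm{mg/dL \cdot min}],$$

with $G_0$ the CGM reading nearest the meal (±20 min) and the integral
evaluated by the trapezoid rule on the readings (negative increments
clipped). Meal $m$ is an **excursion** ($y_m = 1$) iff its iAUC strictly
exceeds the expanding mean of that person's previous iAUCs — a personal
rolling baseline. Each eligible person (≥ 20 usable labelled meals, both
classes present) gets two XGBoost classifiers — *low-burden* (temporal
features + previous excursion) and *high-burden* (plus meal-content and
medication features) — fit on the first 70% of their meals with a 4-fold
rolling-origin cross-validated grid search, and evaluated by F1 on the
held-out last 30%. Low vs. high burden is compared per person and within
preference subgroups by paired Wilcoxon signed-rank tests. The best model's
gain-based feature importances, normalized to percentages and aggregated
into categories, form the person's **vulnerability profile** (a mean-|SHAP|
profile is reported alongside). A seedable synthetic-cohort generator with
known per-person excursion drivers backs all validation.

## Worked example

```r
library(ppgv)

# one synthetic individual whose excursions are driven by staple grams
tr  <- synthetic_truth("demo", driver_weights = c(staples = 30, vegetables = 2),
                       circadian_amplitude = 3, noise_sd = 4,
                       bimodal_groups = "staples", seed = 7L)
rec <- generate_participant(tr, days = 14)
rec
#> <ppg_participant demo: 1344 CGM readings over 14.0 days, 44 meals, 0 medication events>

obs <- label_participant(rec)
sprintf("usable observations: %d; excursion rate: %.1f%%",
        sum(obs$usable), 100 * mean(obs$label[obs$usable]))
#> "usable observations: 43; excursion rate: 46.5%"

mat <- assemble_matrix(rec, obs, "high_burden")
fit <- fit_participant(mat, grid = fast_hyper_grid(), seed = 7L)
s   <- score(fit$test_labels, fit$test_pred)
sprintf("held-out F1: %.3f (base-rate F1: %.3f)", s$f1, base_rate_f1(fit$test_labels))
#> "held-out F1: 1.000 (base-rate F1: 0.632)"

prof <- gain_profile(fit)
round(head(sort(prof$per_category_pct, decreasing = TRUE), 3), 1)
#>       staples  animal foods  basal insulin
#>           100             0              0
```

The person's 13 held-out meals are all classified correctly (F1 = 1.000
versus 0.632 for the always-positive baseline), and the vulnerability
profile concentrates 100% of the model's gain on the staples category — the
driver that was planted.

Full-cohort analyses live in `analysis/01_simulate.R` …
`analysis/05_profile.R`: simulate a 67-person study-scale cohort, label and
filter it, fit both models per person, compare burden levels (subgroup
Wilcoxon tests), and derive vulnerability profiles with cohort
heterogeneity summaries. Each script prints what it found and writes its
tables under `results/`. `run_pipeline(ppg_config(...))` performs the same
end to end. Real ShanghaiT2DM-style spreadsheets can be ingested with
`read_shanghai_participant()` / `input_mode = "shanghai_dir"`.

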