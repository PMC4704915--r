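# stratikit

Tools for **risk-stratified patient management**: deciding which
chronic-disease patients to enroll in which management program — case
management, disease management, supported self-care, wellness promotion —
when programs differ in cost, benefit and capacity, and enrollment
decisions must come from predictive models built on electronic health
records. The package is demonstrated end to end on asthma and is aimed at
biostatisticians and health-services researchers who want the full
pipeline — data, models, explanations, thresholds, simulated outcomes —
reproducible from a single seed.

## What is inside

* **Synthetic cohort generator** (`generate_cohort()`): seeded,
  ground-truth-known EHR-like tables (patients, physicians, encounters
  with ICD-9-style codes, medication dispensings, 21 environmental
  monitoring series, per-encounter costs) with a pyramid-shaped cost
  distribution, rare acute-care events, planted risk patterns and
  per-physician effects on the event log-odds.
* **Cohort and features** (`identify_asthma()`, `build_feature_matrix()`):
  the asthma cohort definition (493.xx diagnosis or two qualifying
  dispensings within 365 days), next-year outcome labels, and three
  feature families — patient, physician practice profile (log panel
  counts, leave-one-out panel outcome means, match features) and
  environmental (nearest-station yearly summaries).
* **Risk and cost models** (`train_and_cv()`, `evaluate_holdout()`):
  stratified 10-fold CV on the training years plus a held-out final year;
  AUC / R² with the mean absolute prediction error; synthetic minority
  oversampling inside training folds; backward elimination at a 0.02
  tolerance; feature merging for cost models
  (`reduce_features()`); feature-family comparison at an absolute 0.10
  decision threshold (`compare_feature_families()`).
* **Rule-based explanation** (`mine_rules()`, `explain_patient()`): class
  association rules for the high-risk class, where support is the
  fraction of all patients satisfying the rule *and* high-risk and
  confidence is the high-risk fraction among satisfiers; sub-rule
  dominance pruning; actionable-first ranking; an inverted rule index; an
  intervention registry attaching tailored interventions to rules.
* **Threshold optimization** (`optimize_thresholds()`): walk risk
  percentiles from highest to lowest and give each one the management
  level minimizing the expected cost change
  `delta = c_i - avg_n_e * p * c_e` among levels with remaining capacity,
  with an exhaustive-search oracle and sensitivity sweeps.
* **Outcome simulation** (`simulate_policy()`, `compare_policies()`): the
  enrolled-patient cost formula `h + c_i - n_e * p * c_e`, aggregate
  costs / admissions / ED visits, 5-level sensitivity grids over program
  cost, benefit and clinician uptake, attribute-combination tables, a
  minimum-accuracy search, paired one-sided t tests on log cost and
  McNemar tests on admissions and ED visits.
* **Power calculations** (`paired_t_sample_size()`, `f_test_r2_power()`,
  `correlated_auc_sample_size()`): the three design-stage calculations of
  the evaluation protocol.

## Worked example

```r
library(stratikit)

params <- cohort_params(n_patients = 2000, n_physicians = 40,
                        n_years = 4, seed = 42)
bundle <- generate_cohort(params)
bundle
#> <cohort_bundle>
#>   2000 patients, 40 physicians, years 2005-2008
#>   20721 encounters, 28250 dispensings, 4032 env rows
#>   events: 732 across 8000 patient-years (rate 0.064)

fm <- build_feature_matrix(bundle)
model <- train_and_cv(fm, model_spec("logistic"), n_folds = 10, seed = 42)
model
#> <risk_model> learner logistic, outcome high_risk (binary)
#>   68 features, trained on years 2005-2006
#> <eval_report> AUC = 0.7127 (10-fold CV, n = 2860)
#>   per fold: 0.704 0.785 0.684 0.621 0.749 0.620 0.763 0.775 0.701 0.728
evaluate_holdout(model, fm)
#> <eval_report> AUC = 0.7199 (0-fold CV, n = 1430)
```

The cross-validated AUC (0.71) and its holdout confirmation (0.72) say the
planted structure — prior utilization, physician effects, medication
ratios — is learnable but noisy, as intended for a rare outcome.

```r
traj  <- holdout_trajectories(fm, model)
c_e   <- sum(traj$h[traj$n_e > 0]) / sum(traj$n_e)   # avg cost of one event
stats <- compute_percentile_stats(traj$pred, traj$n_e, traj$n_e * c_e)
levels <- list(
  management_level("case management",     5000, 0.40, capacity = 15),
  management_level("disease management",  1500, 0.25, capacity = 58),
  management_level("supported self-care",  300, 0.10, capacity = 215)
)
policy <- optimize_thresholds(levels, stats, c_e = c_e)
policy
#> <strat_policy>
#>   bins: 100, total expected cost change: -71104.75
#>   level changes after bins: 3, 4, 6, 7, 12, 13, 39, 40
#>   disease management: 45 patients
#>   none: 1326 patients
#>   supported self-care: 59 patients

simulate_policy(traj, policy, c_e = c_e)
#> <policy_outcome>
#>   total cost: 6432182 (baseline 6503287, change -71105)
#>   admissions: 36.7 (baseline 41), ED visits: 98.5 (baseline 107)
```

The optimizer declines case management here — at this cohort's event cost
even the top percentile's expected benefit does not cover $5000 per
patient — and instead fills the cheaper strata where
`delta = c_i - avg_n_e * p * c_e` is negative, cutting expected cost by
$71k and admissions by ~10% without violating any capacity. A rule
explains who the high-risk patients are:

```r
d <- as.data.frame(fm)[, c("prior_inpatient", "prior_ed", "prior_events",
                           "controller_ratio", "high_risk")]
rank_rules(mine_rules(d, min_support = 0.01, min_confidence = 0.7))
#> <rule_set> 1 rules
#> <rule> prior_inpatient=1 => high risk  (supp 0.024, conf 0.810)

paired_t_sample_size(effect = 0.1, alpha = 0.05, power = 0.90)
#> [1] 857
```

The mined rule recovers the generator's planted pattern (a prior-year
inpatient stay carries 0.8 event probability) at its true confidence, and
the design-stage sample size for comparing two policies' log costs at a
0.1 SD effect is 857 pairs.

A command-line wrapper over the same functions is installed at
`inst/cli/stratify-kit.R` (`simulate-cohort`, `features`, `train`,
`mine-rules`, `explain`, `optimize-thresholds`, `power`).

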