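---
title: "Methods: risk-stratified patient management with stratikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-stratified patient management with stratikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Chronic-disease management programs form a hierarchy — case management,
disease management, supported self-care, wellness promotion — in which more
intensive programs help more but cost more and have hard capacity limits
(case management often costs over $5000 per patient per year and enrolls
only 1–3% of a population). Because health-care costs are pyramid-shaped
(on the order of 80% of costs concentrated in 20% of patients), the value
of a program depends entirely on *who* is enrolled. `stratikit` implements
a full pipeline for making those enrollment decisions from EHR-style data,
demonstrated on asthma:

1. a seeded **synthetic cohort generator** with known ground truth,
2. **cohort, outcome and feature construction** (patient, physician
   practice-profile and environmental feature families),
3. **risk and cost models** under a fixed accuracy protocol,
4. **class association rules** that explain individual high-risk
   predictions and carry tailored interventions,
5. a **threshold optimizer** that assigns risk percentiles to management
   levels to minimize expected total future cost under capacities, and
6. an **outcome simulator** with sensitivity grids and the design-stage
   **power calculations** for evaluating such a deployment.

## The synthetic cohort generator

No public data set carries linked patient, physician, encounter,
dispensing and environmental-monitoring tables, so every downstream stage
is exercised on cohorts from `generate_cohort()`, whose ground truth
(per patient-year event probabilities, counts and costs) is recorded in a
separate truth table so pipelines can be run blind.

The event model is deliberately simple and fully known. For an asthma
patient in year $t$ the probability of an acute-care event (inpatient
stay, urgent-care or emergency visit with a primary asthma diagnosis) is

$$\operatorname{logit} p_{it} = \operatorname{logit}(\text{base rate}) + b_{\phi(i)},$$

where $b_{\phi(i)} \sim N(0, \sigma_{\text{phys}}^2)$ is the primary
physician's additive effect on the log-odds — the simplest mechanism that
makes physician-profile features informative *by construction*. Planted
patterns then either multiply the odds or override the probability
outright for patient-years satisfying a stated condition; the default
plants the clinically canonical pattern "an inpatient stay last year
raises next-year event probability to 0.8".

Default study conditions and the reasoning behind them:

* `base_event_rate = 0.05` per patient-year — acute asthma events are
  rare; 5% keeps the high-risk class a genuine minority while leaving
  enough positives to model.
* `physician_effect_sd = 0.8` — a moderate spread (odds ratios of ~2
  between physicians one SD apart), large enough to matter, small enough
  not to dominate patient history.
* `cost_body = (meanlog 7.0, sdlog 1.5)` — a lognormal cost body whose
  top quintile carries roughly three quarters of body costs; adding
  per-event costs (lognormal around `event_unit_cost_mean = 6000`)
  reproduces the cost pyramid (the generator's tests assert the top 20% of
  patients carry at least 60% of total cost at $n \ge 10{,}000$).
* `n_years = 11` — ten training years plus one holdout year, matching the
  accuracy protocol below.
* 21 environmental series (air quality, weather, pollen, respiratory-virus
  activity) as monthly seasonal means plus noise, with per-station offsets
  so that readings genuinely differ across monitoring stations.
* ~40 attributes rather than the several hundred a production EDW would
  carry: the attribute-group machinery treats groups generically, so the
  attribute count is a scale parameter, not a structural one.
* missingness is injected completely at random (`missing_rate = 0.02`) on
  soft demographic fields; informative missingness is out of scope.
* geography is a unit square with Euclidean distance standing in for
  travel distance; dates are (year, month) pairs.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: coded-vocabulary drift, informative
missingness, correlated comorbidity structure, referral networks,
patient churn between physicians, and any dependence structure among the
environmental series beyond seasonality. Results on synthetic cohorts
validate the *machinery*, not clinical effect sizes.

## Cohort, outcomes, features

A patient enters the asthma cohort with at least one 493.xx diagnosis code
or at least two asthma-medication dispensings (inhaled steroids,
beta-agonists, leukotriene modifiers, other inhaled anti-inflammatories —
oral steroids excluded) within any 365-day span. With month-resolution
dates the span check uses a 30-day-month approximation; two dispensings
400 days apart therefore do not qualify, matching the definition's intent.
Cohort membership is monotone: adding records never removes a patient.

Rows are patient-years. Features for index year $t$ use data up to and
including year $t$; outcomes come from year $t{+}1$ only (the binary
acute-care label, summed reliever + oral-steroid refills, total cost).
A permutation test in the suite verifies no feature changes when all
outcome-year data are shuffled.

Physician practice-profile features follow three conventions worth
stating:

* **Log panel counts** are `log(1 + count / normalizer)` with
  `normalizer = 1` by default, i.e. plain log counts; panel-fraction
  variants are obtained by passing the panel size as the normalizer.
* **Leave-one-out panel means.** The mean index-year event indicator and
  cost over the physician's asthma patients always exclude the index
  patient, so a patient's own outcome can never leak into their features.
* **Fallback at `min_panel = 5`.** A physician with fewer than five other
  asthma patients gets the population mean instead of a noisy panel mean.
  Five is a judgment call (no principled value exists); it trades variance
  against coverage and is exposed as an argument.

Environmental features are the yearly mean and maximum of each variable's
monthly series at the station nearest the patient's home.

## Risk and cost models

The protocol is fixed: stratified 10-fold cross-validation on the
training years, one evaluation on the held-out final year, AUC for the
binary outcome, $R^2$ plus the mean absolute prediction error (Cumming's
prediction measure) for continuous outcomes. The learner registry
(logistic regression, decision tree, random forest, gradient boosting,
k-nearest-neighbor, linear and ridge regression) holds standard,
well-understood algorithms; selection among them is empirical per data
set, by CV metric.

* **Rebalancing** is synthetic minority oversampling: new minority points
  are interpolations toward one of five nearest minority neighbors. It is
  applied only to the training portion inside each fold — never to held-out
  rows.
* **Backward elimination** greedily removes the feature whose removal
  degrades the CV metric least while total degradation stays within 0.02
  of the full model, re-using fold seeds so candidate metrics are
  comparable; ties break by feature name.
* **Feature merging** (for cost models): the `n_keep` features with the
  largest absolute association with the target (Pearson correlation for
  numeric features, the correlation ratio for categorical ones) stay
  separate; the rest are clustered by average-linkage agglomeration on
  $1-|\text{cor}|$ into `n_groups` clusters, each replaced by the mean of
  its standardized members. None of these three metrics is canonical; all
  are the simplest members of their families and are isolated behind the
  function boundary.
* **Family comparison**: "better by 10% or more" is read as an *absolute*
  difference of 0.10 in AUC or $R^2$, consistent with the power
  statements that speak of "a difference of 0.1 in AUC"; a relative mode
  sits behind a flag.

## Explaining high-risk predictions with class association rules

A rule is a conjunction of feature–value items implying the high-risk
class. Two definitions anchor everything:

* **support** = fraction of *all* patients who satisfy the left side *and*
  are high-risk;
* **confidence** = among patients satisfying the left side, the fraction
  who are high-risk.

Because the support numerator counts co-occurrence with the high-risk
label, it is anti-monotone in the item set, so the miner grows candidate
itemsets level-wise over items present in high-risk rows only — a pure
efficiency device that cannot change the result (the suite asserts
equality with exhaustive enumeration on 50 seeded matrices). Confidence is
not anti-monotone and is always computed against the full matrix at the
end. Defaults: minimum support 1%, minimum confidence 70%, at most 4 items
per rule.

Numeric features are discretized at quartiles into half-open intervals
$[l, u)$; users can override with clinical cut-points or restrict a
feature to its "high" or "low" range through the constraints argument
(value constraints also keep rules clinically directional). Redundancy
pruning drops a rule exactly when a strict sub-rule with at least its
confidence exists — the simplest member of the cited pruning family, and
pluggable. Display order is a deterministic total order: actionable rules
first, then confidence (desc), support (desc), length (asc), and the
canonical sorted item string as a final tie-break. Matching a patient uses
an inverted item → rules index whose results are asserted equal to a
linear scan. The clinician-review step is modeled as an allow/deny list,
not automated; the support/confidence threshold adjustment loop is left to
the caller (it is a sweep, not a search).

A patient's explanation is the top-3 matched rules by default; a patient
may match none ("zero or more rules" is the contract), and no attempt is
made to hide rules dominated by a displayed sub-rule — the ranked list is
shown as-is.

## Optimal thresholds for risk strata

For a risk percentile with average event count `avg_n_e`, enrolling an
average patient into a program with per-patient cost $c_i$ and avoided
fraction $p$ changes their expected future cost by

$$\Delta = c_i - \overline{n_e} \cdot p \cdot c_e,$$

with $c_e$ the average cost of one event. The optimizer walks percentiles
from highest to lowest risk and picks, among programs with remaining
capacity, the one with the smallest $\Delta$. Design choices:

* An implicit **"no program" level** ($c_i = 0$, $p = 0$, unlimited) makes
  $\Delta = 0$ the universal comparator and guarantees feasibility.
* **100 equal-count bins** by default ("percentile" granularity); any bin
  count works.
* **Ties go to the less intensive program** (cheaper, then lower $p$) to
  conserve scarce capacity.
* The monotone-gradient **early stop** (once every program has shown
  $\Delta > 0$ with untouched capacity, the remaining bins default to "no
  program") is optional and asserted equal to the unpruned run on
  monotone instances.
* Stratifying by predicted **cost** instead of event risk needs only the
  ranking variable swapped; the delta formula is unchanged.

Per-bin choices are independent when no capacity binds, so the greedy
assignment is globally optimal there; with binding capacities it is a
heuristic. Both facts are asserted against an exhaustive-enumeration
oracle on small instances (≤6 bins × ≤4 levels), and the suite keeps the
comparison honest in both regimes rather than hiding the heuristic gap.

## Simulating policy outcomes

A patient who would incur cost $h$ and $n_e$ events without enrollment is
simulated, if enrolled, at cost $h + c_i - n_e\,p\,c_e$ with expected
events $n_e (1-p)$. Two modes exist: **expectation** (the formulas,
deterministic — used by default and by most tests) and **stochastic**
(binomial thinning of events and Bernoulli uptake draws — used when
sampling behavior is itself under test). Corner cases the formulas leave
open:

* A negative simulated cost (possible when $n_e p c_e > h + c_i$) is
  floored at zero and counted in `n_floored`.
* The log transform for cost comparisons is $\log(\text{cost}+1)$ so
  zero-cost patients are admissible; an offset of 0 recovers the plain log.
* McNemar tests dichotomize admissions and ED visits as any-vs-none; the
  event-count alternative is not implemented.
* Uptake $u < 1$ scales the enrollment effect in expectation mode and
  becomes a Bernoulli draw in stochastic mode.

The heuristic comparator encodes the conventional pyramid: top 1% of
predicted risk to case management, next 4% to disease management, next
15% to supported self-care, rest unmanaged — fully overridable. The
minimum-accuracy search blends the calibrated (true-probability) predictor
with uniform noise, bisects the blend weight to the point where the
policy's simulated total cost equals baseline, and reports the AUC there.
Intervention effects attached to rules reuse the same $(c_i, p)$
machinery through the registry.

## Power calculations

Three design-stage calculations are implemented, no more:

* `paired_t_sample_size()` uses the normal-approximation paired design
  $n = \lceil (z_{1-\alpha}+z_{\text{power}})^2/d^2 \rceil$, which returns
  exactly 857 pairs at $\alpha = .05$ one-sided, 90% power, $d = 0.1$ SD —
  the protocol's design size, asserted in the suite.
* `f_test_r2_power()` uses the noncentral-F formulation with
  $f^2 = \Delta R^2 / (1 - R^2_{\text{base}} - \Delta R^2)$ and
  $\lambda = f^2 (u + v + 1)$, checked against a Monte-Carlo oracle.
* `correlated_auc_sample_size()` uses the Hanley–McNeil
  exponential-approximation variance for each AUC and
  $\mathrm{Var}(A_1-A_2) = V_1 + V_2 - 2 r \sqrt{V_1 V_2}$, two-sided,
  equal classes, also Monte-Carlo checked (paired DeLong test on binormal
  scores).

The protocol's companion figures of 245 patients (F test) and 137 per
class (AUC comparison) are *not* hard-coded as expected outputs: they
depend on a baseline $R^2$, a baseline AUC pair and an $f^2$ convention
that are not fully specified, so the functions expose every assumption as
an input instead of freezing one reconstruction.

## Problem sizes and numerical conventions

The test suite and the acceptance script run entirely on generated data at
sizes chosen to make Monte-Carlo bands tight where a probability is being
checked and small everywhere else: planted-pattern recovery on 8,000 to
10,000-patient cohorts, physician-signal detection on twenty 1,200-patient
replicates, optimizer-oracle comparisons on 100 small instances,
miner-oracle equality on 50 matrices of up to 12 binary features, and 200
replicates of the 857-pair power simulation. Stochastic assertions use
3-standard-deviation bands around the designed value. All randomized steps
take explicit seeds; a bundle is byte-identical under a repeated seed.

## Known limitations

* The generator's attribute dependence structure is a modeling choice;
  nothing in it was fit to real data.
* Single undesirable-event type, single-period optimization; no
  discounting, no inter-period dynamics, no movement between strata.
* Greedy threshold optimization is optimal only when capacities do not
  bind; the oracle comparison quantifies (but does not remove) the gap.
* Statistical significance of individual rules is not assessed; rules are
  screened by support/confidence and dominance only.
* Exact parity with any particular legacy machine-learning toolkit's
  algorithms is a non-goal; the registry holds standard R implementations.
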