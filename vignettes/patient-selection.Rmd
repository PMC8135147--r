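---
title: "Explainable patient selection: models, choices, and limitations"
author: "paibrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable patient selection: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methodology: the two
models it chains together, the parameters that matter and why their
defaults are what they are, what the synthetic trial generator does and
does not emulate, the numerical conventions that make results
bit-reproducible, and the limitations we know about.

## 1. The problem and the two-stage model

A two-arm placebo-controlled trial measures a symptom total score weekly
for six weeks. Some patients benefit from the drug far more than from
placebo; most analyses only report the average contrast. The pipeline
here asks: *which baseline profile identifies the patients who benefit,
and can the answer be stated as rules a clinician can audit?*

**Stage 1 (counterfactual scoring).** An elastic-net regression predicts
the week-6 total from baseline features, the randomized arm, and
arm-by-feature interactions. Because the arm enters as data, the fitted
equation can be evaluated under *both* arms for every patient; the
difference (treatment minus placebo prediction) is the Personalized
Advantage Index (PAI). It is a function of covariates only — by
construction it does not depend on the arm the patient actually received
(a property the test suite asserts). Thresholding the PAI yields
`treatment_indicated` / `rest_indicated` labels. The model is deliberately
fit on *all* rows: its job is to manufacture the best available labels for
the next stage, not to estimate out-of-sample error (see §6 for the cost
of this choice).

**Stage 2 (rule-list classification).** A Bayesian Rule List is an
ordered sequence of conjunctive rules ending in a default ("else")
clause; the first rule whose antecedent a patient satisfies assigns the
class probabilities. The posterior combines a structural prior — a
truncated Poisson on list length (mean `lambda`) and on each rule's
cardinality (mean `eta`), with antecedents drawn uniformly from the mined
pool of the right cardinality — with a Dirichlet–multinomial marginal
likelihood of the labels captured per rule. We sample lists by
Metropolis–Hastings (insert / remove / swap moves with the proposal
asymmetry corrected) and report the maximum-a-posteriori sampled list.

The two stages are assessed with stratified k-fold cross-validation of
the classifier against the PAI labels, and with Cohen's d between arms —
computed on the *actual* week-6 scores — for the full sample versus the
selected subgroup.

## 2. Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `alpha_grid` | 0.001, 0.01, 0.1, 1, 10 | penalty strength | decade-spaced grid spanning near-OLS to near-constant fits |
| `l1_ratio_grid` | 0.1, 0.5, 0.9 | lasso share of the penalty | ridge-leaning to lasso-leaning mixes |
| `inner_cv_folds` | 5 | folds | conventional; selection by pooled CV mean squared error |
| threshold `step` | 0.5 | score points | thresholds scanned 0, −0.5, −1, … |
| `target_fraction` | 0.5 | fraction | a balanced two-class set for the classifier |
| `max_rule_length` | 3 | predicates/rule | rules longer than 3 conjuncts stop being clinician-readable |
| `eta`, `lambda` | 2, 2 | expected cardinality / list length | favors short lists of short rules |
| `dirichlet_alpha` | (1, 1) | pseudo-counts | uniform prior over the two classes |
| `min_support`, `max_support` | 0.10, 0.90 | fraction of rows | antecedents below the floor are noise; above the ceiling they are satisfied by nearly everyone and carry no class information |
| `max_antecedents` | 2000 | pool size | deterministic cap keeping per-fold mining tractable |
| `mcmc_iterations`, `n_chains` | 10 000, 3 | iterations | comfortable for a single fit; see §5 for the reduced evaluation budgets |
| `burn_in`, `thin` | 0.5, 10 | — | standard MH housekeeping |
| `n_boot` | 1000 | resamples | percentile CIs on rule probabilities |

## 3. What the synthetic generator emulates

`simulate_trial()` reproduces the *schema and effect structure* of a
6-week two-arm antipsychotic trial, not any real trial's marginal
distributions:

* two arms (113 / 120 patients by default, typical arm sizes for a
  multi-arm antipsychotic registration trial);
* 30 ordinal items scored 1–7, generated by discretizing a latent
  per-patient severity factor plus item noise (factor loading 0.3). This
  yields positive inter-item correlation and a controllable marginal
  `P(item >= 3) = 0.30`;
* a planted responsive subgroup defined by `item_22 >= 3 OR item_27 >= 3`
  (the two "general psychopathology"-type items that rule lists should
  rediscover), prevalence ≈ 47%;
* week-6 mean change: `-placebo_change` for everyone, plus an extra
  drug-arm reduction of `effect_in_subgroup` (12 points) inside the
  subgroup and `effect_outside_subgroup` (3 points) outside it; weekly
  values interpolate linearly with noise;
* dropout (30% by default) with a uniform last-observed week in 1–5 and
  LOCF imputation downstream; an optional mode makes dropout probability
  increase with poor response.

Auxiliary scales (two sleep VAS scores, social performance, quality of
life) and demographics are generated independent of outcome: they are
model inputs but should not appear in discovered rules.

Two honest caveats about realism. First, Cohen's d is computed on raw
week-6 totals, whose pooled SD is dominated by the between-patient
baseline spread (≈ 20 points); with clinically plausible point effects
the defaults therefore produce full-sample d around 0.2–0.4 and subgroup
d about twice that — the same *structure* as a strongly positive trial,
at smaller absolute d. Second, items are exchangeable by construction
(equal loadings), whereas real symptom scales have factor structure;
passing tests on this generator demonstrates that the pipeline recovers a
planted threshold subgroup under correlated ordinal noise, *not* that it
would recover the true responder phenotype in any particular real trial.

## 4. Numerical choices and conventions

* **Arm coding** treatment = 1, placebo = 0, so the arm coefficient is
  directly the predicted drug–placebo contrast at zero covariates; any
  affine recoding is equivalent.
* **Standardization.** Features are standardized internally before
  penalization (penalties are scale-sensitive); coefficients are reported
  on the original scale. The coordinate-descent convergence threshold is
  exposed (`convergence_thresh`, default 1e-10); the analytic-recovery
  test tightens it to 1e-20, where fitted PAI scores match the generating
  contrast to better than 1e-6 relative error.
* **Grid-search criterion.** The selection statistic is pooled k-fold
  mean squared prediction error; ties break toward the first grid pair in
  row order — the standard criterion for a penalized-regression grid
  search.
* **Threshold tie-break.** Among thresholds whose indicated fraction is
  equally close to the target, the largest (least negative) wins. If all
  scores are positive the function warns and returns threshold 0 with an
  empty indicated class.
* **Adjusted R²** uses p = the total number of design columns
  (features + arm + interactions).
* **Mining.** Level-wise enumeration with the support window, skipping
  conjunctions that repeat a feature with the same operator (the
  collapsed shorter antecedent is already present); interval
  conjunctions (`>=` with `<=`) are kept. If the pool exceeds
  `max_antecedents` the level being built is truncated to the
  highest-support antecedents in stable order — deterministic, and at
  desk scale it retains all single predicates.
* **MAP tie-break.** Equal log posteriors resolve to the list sampled
  first. Label argmax ties resolve to `treatment_indicated`.
* **Bootstrap convention.** A rule capturing no rows in a resample
  contributes the Dirichlet prior mean for that resample; a one-row
  dataset collapses the interval to a point.
* **Degenerate inputs** raise errors rather than guesses: constant
  outcomes, missing week-6 values before LOCF, missing features at
  prediction time, single-class training folds, `n_repeats < 2`.
* **Determinism.** Every sampler and fold assignment takes an explicit
  seed; chains run sequentially from one seeded stream; two pipeline runs
  with the same configuration write byte-identical reports (timestamps
  are quarantined in the manifest).

## 5. Evaluation design and problem sizes

Cross-validation is stratified by PAI label; each patient is tested
exactly once, and pooled test metrics are computed over the union of
held-out predictions. In the repeated-subgrouping test the PAI labels are
computed once and held fixed; each of the 100 repeats re-runs the fold
split and the sampler with a fresh seed, labels every patient with their
out-of-fold rule list, and contributes one subgroup Cohen's d. Subgroup
membership always uses the *test-fold* label, never an in-sample one, so
the classifier stage adds no leakage of its own. AUC uses the rule's
posterior probability of `treatment_indicated` with a fixed direction
(never auto-flipped).

The package's standard desk-scale budgets, used by the test suite and the
acceptance script: 1500 iterations × 1 chain with a 300-antecedent pool
inside the 100-repeat distribution; 2500 × 2 for single final models;
5000 × 2 for reported cross-validation runs; 50 000 × 3 when checking the
sampler against the exhaustively enumerated posterior on pools of ≤ 6
antecedents (total-variation distance < 0.05). These sizes were chosen as
the smallest at which the enumeration check and the rule-recovery
experiment are stable.

## 6. Known limitations

* **In-sample optimism of the PAI stage.** Because the label-generating
  regression is fit on all rows, patients are selected partly on their own
  realized noise. Under a homogeneous-effect null generator the selected
  subgroup's d exceeds the full-sample d by a small systematic margin
  (≈ +0.1 in our 20-seed null experiments — the corresponding null-safety
  test in the suite documents this by failing); with random labels
  replacing PAI labels the excess vanishes, so the bias is attributable
  entirely to the in-sample counterfactual labeling. Consequence: the
  repeated-subgrouping t-test is evidence of *consistent* selection, not
  an unbiased estimate of the subgroup's true effect; out-of-sample PAI
  validation would remove the bias at the cost of noisier labels.
* **LOCF attenuates effects.** Dropouts carry only the part of the
  benefit accrued before their last visit, shrinking both full-sample and
  subgroup d. LOCF is the convention such trials themselves use for the
  primary endpoint; the attenuation is a feature of the emulation, not a
  bug.
* **Linear counterfactuals.** The elastic net approximates a threshold
  subgroup with linear interactions; with strongly correlated items the
  credit can spread to proxies (including the baseline total, which is
  kept as a predictor by default and can be excluded via
  `include_baseline_total = FALSE`).
* **Complement phrasing of recovered rules.** On ordinal items
  `item >= 3` and `item <= 2` cut at the same boundary; the MAP list
  frequently phrases a planted rule in complement form for the rest
  class. `rule_recovers_cutpoint()` treats both as the same discovery.
* **Binary classes only.** Multi-treatment indication lists are out of
  scope.

## 7. A minimal session

```{r}
library(paibrl)

trial  <- locf_impute(simulate_trial(trial_config(seed = 1)))
pai    <- compute_pai(trial)
labels <- pai_labels(pai)

hyper <- brl_hyper(mcmc_iterations = 5000, n_chains = 2,
                   max_antecedents = 300, seed = 1)
cv    <- kfold_cv(trial, labels, hyper, k = 5, seed = 1)
final <- final_model(trial, labels, hyper, n_boot = 500)
eff   <- effect_improvement_test(trial, labels,
                                 brl_hyper(mcmc_iterations = 1500,
                                           n_chains = 1,
                                           max_antecedents = 300),
                                 n_repeats = 100, seed = 42)
print(final)
print(eff)
```
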