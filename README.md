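# paibrl — explainable patient selection for two-arm randomized trials

Heterogeneity of treatment response is the norm in psychiatry: in a
placebo-controlled trial some patients respond well to the drug, others no
better than to placebo, and a strong placebo response further dilutes the
measured treatment effect. `paibrl` implements an explainable two-stage
pipeline for finding a *treatment-indicated* subgroup — patients predicted
to do meaningfully better on drug than on placebo — from the trial's own
baseline data, in a form a clinician can read: an ordered list of
if–then–else rules with explicit symptom cutoffs.

It is aimed at biostatisticians and clinical-trial methodologists who want
to (re)analyze a completed two-arm trial with a symptom-scale endpoint
(e.g. a PANSS-style 30-item ordinal scale summed to a total score), or to
prototype such an analysis on simulated trials before requesting access to
restricted patient-level data.

## The method

**Stage 1 — Personalized Advantage Index (PAI).** An elastic-net linear
regression models the week-6 total symptom score from baseline features
`x` (age, sex, 30 ordinal items, baseline total, four auxiliary scale
scores), the randomized arm `a ∈ {0 = placebo, 1 = treatment}`, and all
arm-by-feature interactions:

    ŷ(x, a) = β₀ + βᵀx + γ a + δᵀ(a·x)
    minimize  (1/2n) Σᵢ (yᵢ − ŷᵢ)² + α [ ℓ‖w‖₁ + (1−ℓ)/2 ‖w‖₂² ]

with the penalty strength `α` and mixing weight `ℓ` chosen by 5-fold
cross-validated prediction error over the grid α ∈ {0.001, 0.01, 0.1, 1,
10}, ℓ ∈ {0.1, 0.5, 0.9}. Each patient's PAI score is the counterfactual
contrast obtained by evaluating the fitted equation under both arms:

    PAI(x) = ŷ(x, a = 1) − ŷ(x, a = 0) = γ + δᵀx

Negative scores mean a lower (better) predicted score on drug. A threshold
scanned in −0.5 steps from 0 splits the sample into treatment-indicated
(PAI ≤ threshold) and rest-indicated classes, targeting a ~50/50 split.

**Stage 2 — Bayesian Rule Lists (BRL).** A rule-list classifier is trained
on the PAI labels: candidate predicates (`item ≥ c`, `item ≤ c`, quartile
cuts for continuous features) are mined into conjunctive antecedents, and a
Metropolis–Hastings sampler explores ordered rule lists `d = (r₁, …, rₘ)`
under the posterior

    p(d | data) ∝ p(d | λ, η) · Π_rules B(n_ind + α₁, n_rest + α₂) / B(α₁, α₂)

where the prior puts truncated-Poisson(λ = 2) mass on list length and
truncated-Poisson(η = 2) mass on rule cardinality (max 3 predicates per
rule), and the likelihood is the Dirichlet–multinomial marginal of the
labels captured by each rule (first match wins; a default rule catches the
rest). The maximum-a-posteriori sampled list is reported with posterior
class probabilities and bootstrap confidence intervals.

**Evaluation.** Stratified 5-fold cross-validation (accuracy / AUC / F1
against the PAI labels), Cohen's d between arms (pooled-SD convention,
`d = (mean_placebo − mean_treatment)/s_pooled`, positive = drug better) for
the full sample and for the selected subgroup, a 100-repeat subgroup-d
distribution with a two-sided one-sample t-test against the full-sample d,
and a labeling-consistency histogram across the fold rule lists.

**Synthetic trials.** Real patient-level trial data of this kind are
access-restricted, so the package ships a generator with the same schema:
two arms, 30 correlated ordinal items discretized from a latent severity
factor, a planted rule-defined subgroup (`item_22 ≥ 3 OR item_27 ≥ 3` by
default) that carries the drug benefit, linear weekly trajectories, and
dropout handled by last-observation-carried-forward (LOCF).

## Worked example

```r
library(paibrl)

trial  <- locf_impute(simulate_trial(trial_config(seed = 1)))
pai    <- compute_pai(trial)
print(pai)
labels <- pai_labels(pai)
hyper  <- brl_hyper(mcmc_iterations = 5000, n_chains = 2,
                    max_antecedents = 300, seed = 1)
final  <- final_model(trial, labels, hyper, n_boot = 500)
print(final)
```

Output:

```
<pai_fit> elastic net, n = 233
  selected alpha = 1, l1_ratio = 0.1
  R^2 = 0.852 (adjusted 0.781), 57 nonzero coefficients
<pai_threshold> -5.5 -> 114 treatment-indicated / 119 rest-indicated (fraction 0.489)
If item_07 >= 4 then rest_indicated (0.78, CI 0.66-0.88)
else if item_22 >= 4 then treatment_indicated (0.95, CI 0.93-0.97)
else if item_14 >= 4 then treatment_indicated (0.88, CI 0.77-0.96)
else if item_07 >= 2 then rest_indicated (0.70, CI 0.61-0.78)
else treatment_indicated (0.69, CI 0.56-0.80)
[log posterior -155.92 on training data]
in-sample: accuracy 0.764, AUC 0.796, F1 0.734
```

Reading this: the elastic net explains 85% of the week-6 variance on this
simulated trial; the threshold −5.5 labels patients whose predicted score
on drug beats placebo by at least 5.5 points as treatment-indicated
(114 of 233, near the 50% target). The final rule list then explains those
labels with symptom cutoffs — here it keys on item 22, one of the two
items that define the planted responsive subgroup. Cross-validation and
the treatment-effect comparison follow the same pattern:

```r
cv  <- kfold_cv(trial, labels, hyper, k = 5, seed = 1)
eff <- effect_improvement_test(trial, labels,
                               brl_hyper(mcmc_iterations = 1500,
                                         n_chains = 1,
                                         max_antecedents = 300),
                               n_repeats = 100, seed = 42)
```

`eff` holds the full-sample Cohen's d, the 100-repeat distribution of
subgroup d's, and the t-test of their difference. A whole run —
simulation, PAI, BRL, evaluation, artifacts on disk — is one call:
`run_pipeline(pipeline_config())`. A thin command-line wrapper with
`simulate` / `pai` / `brl` / `evaluate` / `run-all` subcommands is
installed at `inst/cli/paibrl.R`.

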