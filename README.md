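# memprec

Mixture modelling of memory precision and retrieval success in
continuous-report (delayed-estimation) memory tasks, with the statistical
machinery used around it in two-group and two-timepoint (longitudinal aging)
study designs.

## The model

In a continuous-report task a participant reproduces a studied feature (for
example an object's location) on a continuous wheel, yielding a signed
angular error θ ∈ (−180°, 180°] per trial. Errors are modelled as a
two-component circular mixture

p(θ) = pT · f_vM(θ; μ = 0, κ) + (1 − pT) / 360,

where f_vM is the von Mises density centred on the target. The mixture
weight **pT** is retrieval success — the probability the memory was accessed
at all — and the concentration **κ** (interchangeable with the circular
standard deviation via the Bessel-function ratio I₁(κ)/I₀(κ)) is memory
precision: the fidelity of a successfully retrieved memory. `memprec`
provides:

- exact conversion between circular SD and κ (`sd_to_k()`, `k_to_sd()`);
- multi-start maximum-likelihood and random-walk Metropolis Bayesian fitting
  (`fit_mixture_mle()`, `fit_mixture_bayes()`), a no-guessing single-parameter
  alternative and AIC model comparison (`fit_no_guessing()`,
  `compare_models()`);
- a semi-parametric fallback for when subject-level fits fail: a group-level
  fit yields a guessing threshold (the |error| where a response becomes more
  likely a guess than a noisy retrieval), and subject estimates derive from
  counts and spread within it (`guessing_threshold()`,
  `semiparametric_estimates()`, `semiparametric_analysis()`);
- subject-label permutation inference on group-level parameters
  (`permutation_group_test()`);
- Jeffreys–Zellner–Siow t-test Bayes factors and stretched-beta Pearson
  correlation Bayes factors (`jzs_ttest_bf()`, `pearson_bf()`), plus rank
  tests (`rank_tests()`);
- lifestyle-questionnaire scoring and item-level change tests
  (`score_leq()`, `item_change_tests()`);
- synthetic-data generators for task displays, two-group trial data, and
  two-timepoint cohorts with lifestyle and covariate structure
  (`generate_displays()`, `generate_two_group_trials()`,
  `generate_cohort()`, `generate_lifestyle_items()`);
- orchestration of the two study shapes with 3-SD outlier exclusion,
  reference-sample z-scoring and full subject accounting
  (`run_experiment1()`, `run_change_analysis()`).

## Worked example

```r
library(memprec)

set.seed(1)
errs <- simulate_errors(10000, pT = 0.73, kappa = 13.87)
fit <- fit_mixture_mle(errs)
fit
#> <mixture_fit> method: mle
#>   pT = 0.7241  kappa = 13.834  (SD = 15.70 deg)
#>   loglik = -50208.271  n = 10000  converged: TRUE
```

A simulated population in which 73% of trials are successful retrievals with
concentration 13.87 is recovered to well within sampling error: the fitted
retrieval success is 0.724 and the fitted concentration 13.83,
corresponding to a circular SD of about 15.7° for retrieved memories.

```r
pearson_bf(0.082, n = 54)
#> <bayes_factor> pearson_correlation  BF10 = 0.2011  BF01 = 4.973  (stretched beta, width 1)
```

A sample correlation of 0.082 over 54 pairs yields BF01 ≈ 5: the data are
about five times more likely under the null than under a uniform prior on
the population correlation — moderate evidence for no association.

```r
trials <- generate_two_group_trials(n_subjects = 20, trials_per_subject = 75,
                                    pT = c(0.9, 0.3), kappa = 14, seed = 2)
permutation_group_test(trials, B = 999)
#> <permutation_result> groups: group1 vs group2  B = 999
#>   pT     observed diff = -0.5954  z = -6.286  p = 0.0010
#>   kappa  observed diff = +0.8345  z = +0.428  p = 0.6960
```

Groups simulated with very different retrieval success but identical
precision: the permutation p-value for pT sits at its attainable floor
1/(B+1) while the precision difference is indistinguishable from label
noise.

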