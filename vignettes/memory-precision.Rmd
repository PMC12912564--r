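---
title: "Separating retrieval success from memory precision: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating retrieval success from memory precision: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memprec)
```

## The measurement problem

In continuous-report memory tasks a participant reproduces a studied
feature — typically an object's angular location or colour — on a continuous
wheel. The signed angular error on each trial mixes two qualitatively
different failure modes: a retrieved memory reproduced with limited fidelity
(small, roughly bell-shaped errors) and an outright retrieval failure
followed by a guess (errors uniform over the circle). A single summary such
as mean absolute error confounds the two. `memprec` implements the standard
two-component mixture that separates them, and the inferential machinery
needed to compare the resulting parameters across groups and timepoints.

## The mixture model

Signed errors $\theta \in (-180°, 180°]$ are modelled as

$$p(\theta) = p_T \, f_{vM}(\theta;\, 0, \kappa) \;+\; (1 - p_T)\,/\,360,$$

with $f_{vM}$ the von Mises density centred on the target. $p_T$ is
*retrieval success*, the probability a memory is accessed at all; $\kappa$
is *memory precision*, the concentration of errors when it is. The
equivalent circular standard deviation is
$\mathrm{SD} = \sqrt{-2 \ln\!\big(I_1(\kappa)/I_0(\kappa)\big)}$ (radians),
and `sd_to_k()` / `k_to_sd()` convert between the two scales.

Conventions that matter downstream:

- **Degrees at every interface, radians internally.** All densities are
  per-degree (the uniform component is $1/360$), so log-likelihoods are
  comparable across estimators and modules.
- **The $+180°$ boundary belongs to the positive side**: `wrap_error(0, 180)`
  is $+180$. Some convention has to be fixed for the closed interval; this
  one is applied and tested consistently.
- **Bessel ratios are computed with exponentially scaled Bessel functions**
  so concentrations up to the documented cap of 700 do not overflow.
  `sd_to_k()` inverts the SD formula by bracketed root finding on
  $\log\kappa$ (the map is strictly monotone) rather than by the series
  approximation some toolboxes use — exactness was preferred over speed at
  this scale, and the round trip is tested to below $10^{-6}$ degrees over
  $\kappa \in [10^{-3}, 500]$.

## Fitting

`fit_mixture_mle()` is the default estimator: bounded L-BFGS-B with an
analytic gradient, multi-started from a $5 \times 5$ grid over
$p_T \in [0.1, 0.9]$ and $\kappa \in [0.5, 128]$ (log-spaced), with
$\kappa$ constrained to $[10^{-3}, 700]$ and $p_T$ to $[0, 1]$. Multi-start
MLE was chosen as the default because it is deterministic given the data —
every downstream permutation and bootstrap stage stays exactly reproducible
under a seed. The optimiser is validated against a brute-force
$101 \times 101$ grid on every test sample (it must reach the grid maximum
to within $10^{-6}$).

`fit_mixture_bayes()` mirrors the Bayesian fitting tradition of
analogue-report toolboxes: random-walk Metropolis on $(p_T, \log\kappa)$
with a uniform prior on $p_T$ and a weakly informative
$\log\kappa \sim N(\log 10, 1.5^2)$ prior (spanning roughly
$\kappa \in [0.5, 200]$ at two prior SDs). Proposals adapt toward 30%
acceptance during burn-in and are frozen afterwards. Convergence is judged
by split-chain $\widehat R$ over two chains; a fit with any
$\widehat R > 1.05$ is flagged non-converged, the package's operational
definition of "the model failed to converge" — subjects so flagged are
excluded by the pipeline with a logged reason. Because the toolbox priors
used in practice are not standardised, these priors are documented as this
package's choice, and the posterior mean is checked against the MLE at
large $n$ in the test suite.

`fit_no_guessing()` fixes $p_T = 1$, the single-parameter alternative in
which no guessing occurred. `compare_models()` compares the two by AIC
($2k - 2\ell$); the models are nested, so the mixture's log-likelihood can
never be lower, and a $\Delta\mathrm{AIC} > 2$ is read as decisive, the
same convention used for model selection elsewhere in this literature. On
data simulated with genuine guessing mass ($p_T = 0.6$, $n = 2000$) the
two-parameter model is reliably preferred.

## The semi-parametric fallback

When subject-level fits are unreliable, a more robust route fits the
mixture once to the pooled group data and derives a *guessing threshold*:
the $|\theta|$ at which the posterior responsibility of the target
component equals $0.5$, i.e. where
$p_T f_{vM}(\theta) = (1 - p_T)/360$. In closed form,
$\cos\theta_c = 1 + \big[\ln\frac{1-p_T}{p_T} + \ln I_0^{e}(\kappa)\big]/\kappa$
(with $I_0^e$ the scaled Bessel function); if the von Mises component
dominates everywhere the threshold saturates at 180°. The responsibility-0.5
rule is the standard interpretation of a model-derived guessing cutoff and
is stated here as this package's definition rather than a reproduction of
any particular toolbox's internals.

Subject-level retrieval success is then the proportion of responses within
the cutoff, and precision is minus the SD of the within-cutoff errors
(sign-flipped so that higher values mean greater precision). The spread is
the *linear* sample SD ($n-1$ denominator by default, switchable to the
population form): inside a narrow cutoff the circular and linear SDs differ
negligibly. These estimates are deliberately biased — uniform guesses that
land inside the cutoff inflate retrieval by approximately
$(1 - p_T)\,\theta_c/180$, an identity asserted in the tests at
$n = 10^5$ — but they are monotone in the truth: across simulated subjects
the Spearman correlation with true $p_T$ exceeds 0.8 at 75 trials per
subject.

## Permutation inference on group-level parameters

Group-level parameters have no subject-level sampling distribution, so
group differences are tested by permutation: subject-to-group labels are
shuffled (trials travel with their subject — trials within a subject are
not exchangeable, subjects are), the model is refit to each permuted
group's pooled trials, and the observed difference is referred to the
permuted ones. Choices, each tested:

- **Two-tailed via absolute differences**, since the null distribution of
  the difference is symmetric.
- **Add-one correction**: $p = (\#\{|d_{perm}| \ge |d_{obs}|\} + 1)/(B+1)$,
  so $p$ is never zero and ties count conservatively against rejection.
- **z-scores standardise by the permutation distribution**'s mean and SD.
- **Permutation refits use the MLE** with a warm-started three-point
  multistart (the two observed group optima plus one grid fallback). On
  these well-conditioned pooled fits this reaches the same optimum as the
  full grid at a tenth of the cost; the observed fits themselves always use
  the full multistart.

Calibration is verified empirically: over 200 null simulations (two groups
of 20 subjects × 75 trials drawn from the same population, $B = 200$), the
type-I error rate at $\alpha = 0.05$ must lie in $[0.02, 0.09]$ for both
parameters. The add-one correction makes the attainable rate slightly
conservative ($\approx 0.0498$ at $B = 200$).

## Bayes factors

Two families are provided, both two-sided to match standard reporting:

- **JZS t-test Bayes factors** (`jzs_ttest_bf()`): Cauchy prior with scale
  $r = 0.707$ on the standardised effect (the JASP default), computed by
  adaptive quadrature over the Zellner $g$ parameter. The test suite checks
  the result against an independent quadrature route — the marginal of the
  noncentral-$t$ likelihood over the Cauchy prior — to four significant
  figures.
- **Stretched-beta correlation Bayes factors** (`pearson_bf()`): the
  analytic expression depending only on $(n, r)$, with a
  Beta$(1/w, 1/w)$ prior stretched to $(-1, 1)$; the default width
  $w = 1$ is the uniform prior. The Gauss hypergeometric term is evaluated
  by power series with an Euler-integral fallback where the series
  converges slowly. Four published BF$_{01}$ values (4.98, 5.94, 3.26,
  5.61) recompute from their $(r, n)$ summaries within 2%, and a strong
  correlation ($r = 0.86$, $n = 59$) yields BF$_{10} > 1000$.

`rank_tests()` wraps the Mann-Whitney and Wilcoxon signed-rank tests, with
the all-tied paired case flagged degenerate rather than silently tested.

## The synthetic-data generator

No raw data ship with the package; the generators define the study
conditions every stage is tested under.

- `generate_displays()` emulates the encoding displays: 29 scenes × 3
  objects by default, positions uniform on $[0, 360)$ rejection-sampled
  until all pairwise circular separations are ≥ 62.04° (the overlap
  constraint), each target paired with a similar lure — 174 objects in
  total. Infeasible configurations (e.g. 6 objects at 62.04°) are refused
  by a pigeonhole check, and feasible-but-unsatisfiable ones fail loudly
  after 10,000 attempts.
- `generate_two_group_trials()` and `generate_cohort()` draw per-subject
  true parameters — logit-normal $p_T$ (SD 0.6 on the logit scale around a
  population mean of 0.67) and log-normal $\kappa$ (SD 0.4 around 15.63) —
  and simulate trials through `simulate_errors()` (Best-Fisher von Mises
  sampling). The population means are the published group-level estimates;
  the spreads are this package's choice of realistic between-subject
  heterogeneity, since subject-level distributions are not recoverable from
  group summaries.
- The cohort generator couples lifestyle to memory change through a single
  target correlation: the standardised true memory change is
  $r \cdot z_{\text{lifestyle decline}} + \sqrt{1-r^2}\,\varepsilon$, so
  the true-parameter-scale correlation equals the configured $r$ (estimation
  noise attenuates it in fitted values — a real feature of such designs).
  Typical and pandemic lifestyle sum scores are bivariate normal with means
  33.37 and 28.90, SDs 7.39 and 7.53 and correlation 0.86. Attrition is
  missing-completely-at-random by default.
- `generate_lifestyle_items()` produces 0–5 Likert frequency responses for
  17 activity items, with pandemic responses shifted down per item
  (social, vigorous-physical and leaving-home activities most; home-based
  cognitive activities least) and clipped to the scale.

What the generators do *not* emulate: response biases (e.g. repulsion from
display neighbours), swap/misbinding errors to non-target items, practice
effects, non-random attrition (a performance-dependent option exists but is
off by default), and ordinal measurement error in the questionnaires.
Passing tests therefore show that the estimators recover the truth under
the stated mixture model, not that real data satisfy it.

## Pipelines and data hygiene

`run_experiment1()` reproduces the two-group comparison: subject-level mean
absolute error and semi-parametric estimates, group-level fits with
nonparametric bootstrap percentile CIs (1,000 resamples over subjects by
default — the CI method is this package's choice), the permutation test,
and rank tests with JZS Bayes factors. `run_change_analysis()` reproduces
the two-timepoint core: per-subject fits at each timepoint, z-scoring
against the full T1 sample (the reference-study convention), T1-minus-T2
difference scores for memory and typical-minus-pandemic for lifestyle (both
oriented as decline), correlation tables with stretched-beta Bayes factors,
the paired typical-vs-pandemic test, and subgroup correlations (family
history of dementia; a median split on a configurable risk score, default
the depression score) at a Bonferroni-adjusted $\alpha = 0.01$.

Hygiene rules applied throughout:

- **Outliers**: a subject-level outcome more than 3 SD from the group mean
  is excluded, computed in a single pass (not iteratively), independently
  per outcome — so a subject can be excluded from the precision analysis
  but retained for retrieval success.
- **Full accounting**: every subject in the input ends in the results table
  or in the exclusion log with a reason (non-convergence, missing
  timepoint, outlier).
- **Reproducibility**: reports are bit-for-bit reproducible given the input
  and seed.

## Problem sizes in the test suite

The routine suite exercises parameter recovery at 10,000 trials, oracle
equivalence on 50 samples of up to 500 trials against a $101\times101$
grid, permutation calibration over 200 null simulations at $B = 200$ with
20 subjects × 75 trials per group, bootstrap CI coverage over 20 seeds at
100 resamples, and semiparametric validity over 60 subjects × 75 trials —
sizes chosen so the full suite runs in minutes on a single core while
keeping Monte-Carlo error well below every asserted tolerance.

## Known limitations

- The mixture assumes the von Mises component is centred on the target; a
  systematic response bias would be absorbed into (and inflate) the SD.
- No swap/misbinding component is modelled; designs with confusable
  non-targets need a third component this package deliberately omits.
- The semi-parametric estimates are biased by construction and should be
  compared only within an analysis, never across thresholds.
- The Bayesian fit's priors are defaults, not a reconstruction of any
  specific toolbox; sensitivity to the $\kappa$ prior grows as trial counts
  shrink.
- Mixed-effects model selection, marginal-effect contrasts and influence
  diagnostics for the longitudinal analysis are out of scope; the pipeline
  stops at difference-score correlations and paired tests.
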