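---
title: "Methods: questionnaire-based MSKP risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: questionnaire-based MSKP risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

painrisk builds a screening-oriented risk model for chronic musculoskeletal
pain (MSKP) in adolescents from self-reported survey data. This vignette is
the package's account of the underlying methods: the severity index, the
synthetic cohort generator, the two-step feature selection, the
cross-validated ensemble and its risk stratification, and the places where
the design was genuinely open and a choice had to be made.

## The MSKP severity index

Respondents report a 0-10 visual-analogue pain intensity for four body
regions (neck, shoulders, middle back, lower back). Each intensity is banded
into a severity rating: 0 for no pain, 1 for intensities 1-3, 2 for 4-7, and
3 for intensities above 7. The index is the sum of the four ratings, so it
ranges 0-12, and an index of 4 or more defines a positive case of intense
chronic pain. Because a single region contributes at most 3 points, a
positive case necessarily reports significant pain in at least two regions —
the index cannot be triggered by one painful site alone. The no-pain rating
of 0 is forced by the semantics of "absence of pain" (an intensity of 0
contributes nothing).

Instrument scores feeding the model are deliberately simple: the 22-item
mobile-dependency test total (0-88, a plain sum), six continuous
sleep-disturbance factor scores, activity frequencies with a five-level
weekly-MET categorization, household-chore flags and sociodemographics.
Records missing any scored item are dropped (complete-case rule) and listed
in an exclusion report; psychometric structure below the instrument totals
(factor loadings, measurement error) is out of scope, because only totals
and factor scores enter the model.

One scale ambiguity deserves a note: the sleep instrument is nominally
administered on a days-per-week basis, but the factor-score ranges carried
here (0-4, 0-3.2, 0-3.0 for the modelled factors) follow the ranges the
model actually consumes. The factors are treated as continuous scores
throughout; dichotomized "reports the problem" rates are only used to shape
the generator's marginals.

## The synthetic cohort generator

No respondent-level survey data are available, so every downstream stage is
exercised on synthetic cohorts whose statistical structure matches what the
analysis assumes. The generator is first-class, tested code, not a fixture.

**Correlated blocks via a Gaussian copula.** Sleep factors, activity
frequencies and chore flags each form a positively correlated block. A
block is drawn from an exchangeable latent normal and pushed through each
variable's marginal inverse CDF. The latent correlation is corrected as
`r = 2 sin(pi * rho / 6)` so that `rho` is the latent Spearman correlation;
for continuous marginals (the sleep factors, scaled Beta distributions) the
rank correlation transfers exactly, while discretized marginals (1-5
activity frequencies, binary chores) attenuate it through ties — the
contract is exact on the continuous block and documented as approximate on
the discrete ones. Defaults are 0.45 (sleep), 0.40 (activity), 0.30
(chores); they sit deliberately below the 0.5 screening threshold so that a
block's members are correlated yet individually screenable, which is the
regime the survey's correlation map displays.

**Categoricals.** Age group and school transport are drawn as single
categorical variables and one-hot encoded downstream, which automatically
produces the negative within-group indicator correlations a single-draw
categorical must have.

**Marginals.** Sex (53.8% girls), age (discretized normal, mean 13.9,
SD 2.0), mobile-dependency total (truncated discretized normal, mean 25.1,
SD 16, split into 22 items that sum exactly to the total) and per-factor
sleep reporting rates follow the surveyed distribution summary. Girls are
generated with slightly lower activity latents (except dance) and slightly
higher chore latents; the direction is what the survey reports, the
magnitudes (0.25 and 0.2 latent shifts) are invented and labelled as such.

**Outcome model and effect sizes.** Outcome status is drawn from a logistic
model over thirteen features. The published per-feature odds ratios come
from a heavily L1-shrunken ensemble, so they understate the data-generating
effects: used verbatim they produce a population AUC near 0.53, which
contradicts the discrimination the fitted model demonstrably achieves
(AUC ~0.8). The generator therefore uses the published effect pattern
(signs and relative magnitudes) under a single multiplier, `effect_scale`,
fixed once at 16 by a one-off Monte-Carlo check so that the simulated
model's discrimination lands in the reported working range; the package's
tests assert the cross-validated AUC falls in 0.70-0.90. The multiplier is
a study condition, not a tuning knob, and is not revisited.

**Intercept calibration.** The intercept is set by root-finding on the
Monte-Carlo prevalence curve (the mean inverse-logit of intercept plus
linear predictor over 100 000 respondents drawn with a fixed internal
seed) so the positive fraction hits the target prevalence of 22.6%. An
unreachable target raises an error reporting the achievable range.

**Pain-intensity synthesis.** The model governs positivity, not per-region
intensity, so intensities are synthesized afterwards, consistent with the
drawn status: four regions are drawn from independent discrete
presence/intensity distributions and rejection-sampled until the resulting
index is >= 4 for positives and < 4 for negatives. Positives draw from an
elevated pain profile, which keeps the rejection cheap; the conditional law
given the index constraint is what downstream scoring sees.

**What the generator does not emulate.** Item-level psychometrics,
nonlinear or interaction effects, informative missingness (blanked items
are planted uniformly at random), and any geographic or seasonal structure.
Passing tests therefore certify the pipeline's statistical machinery, not
the epidemiology of any particular real cohort.

## First selection step: correlation screening

All predictors are one-hot encoded and standardized (z-scores; constant
columns are left at zero and flagged rather than divided by zero). The
reference level of every one-hot group is dropped as the logistic baseline.
Features are then clustered by average linkage on the distance
`1 - |Spearman rho|` and the tree is cut at height `1 - threshold`
(default threshold 0.5, exposed in the configuration). Within every
multi-feature cluster exactly one representative survives: the feature with
the largest absolute Spearman correlation with the outcome, ties broken
alphabetically. The original analysis screened by expert reading of the
correlation dendrogram; an automatic pipeline needs a deterministic rule,
and this one is stated in the documentation as a departure from that
judgement call. Screening is deterministic given the matrix and threshold,
and raising the threshold can only grow the kept set.

## Second selection step: cross-validated Lasso

The Lasso-logistic objective is the penalized log-likelihood
`l(beta) - lambda * sum(|beta_j|)` with an unpenalized intercept; `lambda`
penalizes the *total* log-likelihood, so the glmnet backend receives
`lambda / n` (its penalty is per observation). The working penalty of 10
on this scale corresponds to a glmnet penalty of about 0.015-0.022 at the
sample sizes involved. The default grid is log-spaced over 0.01-100 and
contains 10; a one-point grid reproduces a fixed a-priori penalty for users
who want that reading.

The plan is a 20-times repeated stratified 3-fold — 60 train/test splits,
each preserving the sample prevalence to within one respondent per class.
Every fold-model is scored by the AUC of the ROC curve on its held-out
fold, computed as the Mann-Whitney rank statistic with ties counting one
half (equivalent to brute-force pair counting, which the tests verify).

Two penalty-selection rules are provided because the AUC-penalty profile is
nearly flat at n = 680 and the outright maximizer is unstable from seed to
seed. The selection stage defaults to the one-standard-error rule (the
strongest penalty within one SE of the best mean AUC), which lands on the
sparse, stable ensembles the next step needs; the definitive-model stage
defaults to the plain best-mean-AUC rule, since its features are already
fixed and sparsity is no longer at stake.

Retention uses the median-nonzero rule: a feature survives only if its
coefficient distribution over the 60 fold-models has a nonzero median —
equivalently, a per-SD odds-ratio median different from 1. A feature zeroed
by the Lasso in more than half the folds is discarded. With correlated
predictor blocks this rule has a known limitation, discussed under
*Limitations*.

## The definitive model and risk stratification

The definitive workflow splits the cohort 60/20/20 (training /
risk-definition / risk-evaluation), stratified so each part preserves the
overall prevalence. Standardization statistics, the penalty and all
fold-models come from the training part alone; the risk-evaluation part
never influences training, standardization, penalty choice or cut
placement, and the workflow object records the index sets so this is
asserted structurally in the tests.

The model score of a respondent is the arithmetic mean of the predicted
probabilities of the 60 fold-models (the definitive model is the frozen
ensemble, not a refit on pooled data). Tertile cuts of the score on the
risk-definition set define three bands; each band's expected risk is the
positive fraction observed within it on that set. Band membership uses
left-closed, right-open intervals, and the cuts are right-continuous
empirical quantiles (the order statistic at `floor(n p) + 1`), the
combination under which the three bands are balanced to within one
respondent up to ties. The held-out evaluation reports observed band
prevalences next to the expected ones — an empty band is reported as
undefined, never as zero — plus the overall AUC.

## Effect statistics

Coefficients of standardized predictors are log odds ratios per SD;
`exp(beta)` is the per-SD OR. The maximum OR over a variable's observed
range is `exp(beta * range / SD)` on the raw scale, and per-feature
confidence intervals come from the 60 fold-models: a normal approximation
on the log-OR scale using the across-fold mean and SD, at the
Bonferroni-corrected level `1 - 0.10 / k` for `k` simultaneous intervals
(an empirical-quantile variant is available and switchable in
configuration; normal-theory is the default because the fold distributions
are approximately log-normal and 60 values give thin tails for extreme
quantiles). Prevalence is reported with the Wilson score interval — among
the common binomial intervals it is the one that reproduces the published
22.6% [19.7%, 25.9%] from 154/680 at one-decimal rounding, stays inside
[0, 1], and behaves at the boundaries; the zero-count lower bound is
exactly 0.

## Numerical choices and degenerate inputs

- glmnet convergence threshold 1e-9 to 1e-10 with a warm-start path ending
  exactly at the requested penalty; at `lambda = 0` the result matches an
  independent Newton-Raphson MLE to 1e-4.
- Median-nonzero tolerance 1e-8 on the coefficient scale.
- Ties: average ranks in every Spearman computation; one-half in the AUC;
  alphabetical tie-breaks for screening representatives; the stronger
  penalty on exact AUC ties in the grid.
- Constant columns: flagged and zeroed in standardization, correlation
  defined as 0 in the Spearman matrix, refused with an error in
  maximum-OR computations.
- Degenerate band inputs (fewer than three distinct scores) and
  single-class outcomes are errors, not silent results.

## Problem sizes in the test suite

The suite exercises prevalence calibration at n = 50 000, rank-correlation
recovery at n = 10 000, effect recovery by unpenalized refit at n = 50 000
(where the Monte-Carlo standard error of the weakest binary effects is
comfortably inside the 20% acceptance band), oracle comparisons at
n <= 2000, and the full selection-plus-stratification pipeline at the
survey's own n = 680 over 20 seeds.

## Limitations

With positively correlated blocks in which only some members carry direct
effects, zero-effect block members acquire substantial *marginal*
association (a sleep factor correlated 0.45 with three true risk factors
can out-signal a weak true feature such as pet-care responsibility). No
penalty level separates such proxies from weak direct effects at n = 680,
so the selection stage can keep a correlated proxy and drop a weak true
feature; the package's acceptance tests record this honestly rather than
masking it. Consequently the selected feature list should be read as a set
of *predictive* markers, not causal factors — which is also how the
underlying survey analysis frames its own findings. Probability
recalibration of ensemble scores is deliberately out of scope; the tertile
machinery consumes raw averaged probabilities.
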