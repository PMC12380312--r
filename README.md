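# painrisk

Questionnaire-based risk modelling of chronic musculoskeletal pain (MSKP)
in adolescents, for biostatisticians and school-health researchers who want
a reproducible, testable version of the survey-to-risk-score workflow:
instrument scoring, two-step feature selection, a cross-validated
Lasso-logistic ensemble, and tertile risk stratification with held-out
evaluation.

## The method in brief

**Outcome.** Each respondent reports a 0–10 pain intensity for four body
regions (neck, shoulders, middle back, lower back). Intensities are banded
into severity ratings r ∈ {0, 1, 2, 3} (0; 1–3; 4–7; >7) and summed into
the MSKP index

    index = Σ_regions r ∈ [0, 12],   positive case ⇔ index ≥ 4,

so positivity requires significant pain in at least two regions.

**Model.** After one-hot encoding and standardization, features are screened
by average-linkage clustering on 1 − |Spearman ρ| (one representative per
correlated cluster), then selected by a Lasso-regularized logistic
regression, objective ℓ(β) − λ·Σ|β_j|, fitted under a 20× repeated
stratified 3-fold plan (60 fold-models) with the penalty chosen by held-out
ROC AUC; a feature survives only if its coefficient distribution across the
60 folds has a nonzero median. The definitive model is the frozen ensemble:
a respondent's score is the mean predicted probability over the 60
fold-models. Tertiles of that score on a risk-definition subset define
low/medium/high bands, each carrying its observed positive fraction as the
expected risk; a disjoint risk-evaluation subset measures how well those
expectations transfer. Effect sizes are reported as odds ratios per SD,
maximum odds ratios over each variable's range exp(β·range/SD) with
Bonferroni-corrected 90% CIs across folds, and prevalence with a Wilson 95%
interval.

Because no respondent-level data are published, the package ships a
Gaussian-copula synthetic cohort generator that reproduces the survey's
statistical structure (marginals, correlated sleep/activity/chore blocks,
one-hot categorical groups, a calibrated logistic outcome, and pain
intensities consistent with outcome status). See
`vignettes/risk-model-methods.Rmd` for the full methods account.

## Worked example

```r
library(painrisk)

cohort <- generate_cohort(cohort_spec(n_respondents = 680, seed = 1))
scored <- score_cohort(cohort)
prevalence_ci(sum(scored$mskp_positive), nrow(scored))
#> # A tibble: 1 × 3
#>   point   low  high
#>   <dbl> <dbl> <dbl>
#> 1 0.241 0.211 0.275

res <- run_pipeline(outdir = "mskp_run")
glance(res$model)
#> # A tibble: 1 × 7
#>       n n_train best_lambda train_cv_auc evaluation_auc lower_cut upper_cut
#>   <int>   <int>       <dbl>        <dbl>          <dbl>     <dbl>     <dbl>
#> 1   680     408       0.316        0.796          0.822    0.0929     0.271

res$model$evaluation
#> <band_evaluation> AUC 0.822
#> # A tibble: 3 × 5
#>   band       n positives expected observed
#>   <fct>  <int>     <int>    <dbl>    <dbl>
#> 1 low       52         3   0.0444   0.0577
#> 2 medium    37         7   0.133    0.189
#> 3 high      47        23   0.543    0.489
```

Reading the output: the simulated cohort's MSKP prevalence is 24.1%
[21.1%, 27.5%]; the definitive ensemble discriminates positives from
negatives with a held-out AUC of 0.822; and the tertile bands defined on
the risk-definition subset (score cuts 0.093 and 0.271) transfer to the
held-out evaluation subset with observed risks of 5.8%, 18.9% and 48.9% —
the high band concentrates roughly twice the overall prevalence. The run
directory (`mskp_run/`) contains every artifact as CSV/JSON plus a Markdown
report; `autoplot(res$selection)` and `autoplot(res$model$evaluation)` draw
the odds-ratio distributions and the expected-versus-observed band
comparison.

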