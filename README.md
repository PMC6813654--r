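# reosig

Rank-based gene-pair signatures for predicting chemotherapy response from
tumor transcriptomes.

## The problem

Quantitative expression signatures (risk scores summing normalized expression
values) transfer poorly between laboratories: absolute values shift with
platform, batch and specimen quality, and median-anchored scores cannot
classify a single patient without a reference cohort. `reosig` implements the
qualitative alternative used for predicting response to platinum–taxane
adjuvant chemotherapy in high-grade serous ovarian cancer: signatures built
from **within-sample relative expression orderings** (REOs).

For an oriented gene pair (a, b), the only information used is whether
`E_a > E_b` *inside* one sample — invariant to any strictly increasing
per-sample transformation and computable for one patient in isolation. A
**gene-pair signature** (GPS) is a set of k oriented pairs with a
strict-majority vote:

    responder  ⇔  #{ pairs with E_a > E_b }  >  k / 2

The published four-pair ovarian-cancer signature ships as `four_gps()`
(FUS>THBS2, GUCY2C>RCVRN, PCSK6>ZNF365, PASK>DNAJB14): a sample is predicted
to respond iff more than two of the four favorable orderings hold.

The package covers:

* **Discovery** (`run_discovery()`): 60-month follow-up truncation → pooled
  *t*-test screen between pathological CR/non-CR groups (p < 0.05) →
  univariate Cox screen on expression (p < 0.05) → Cox on each pair's REO
  indicator with Benjamini–Hochberg control (FDR < 0.05), oriented so the
  favorable pattern has HR < 1 → greedy forward selection maximizing
  Harrell's C-index of the majority vote.
* **Classification** (`vote_classify()`, `four_gps()`), plus the
  median-anchored point-score comparator (`quant_score_classify()`) whose
  cohort-dependence the tests demonstrate.
* **Validation** (`validate_signature()`, `response_crosstab()`,
  `subgroup_survival()`, `cross_cohort_comparison()`): Kaplan–Meier curves,
  log-rank test, univariate and covariate-adjusted Cox models (covariates
  screened at univariate p < 0.2), C-index, Fisher's exact confusion-matrix
  test.
* **Survival kernel**: `cox_fit()` (Efron ties, Wald CIs),
  `concordance_index()`, `km_estimate()`, `logrank_test()`, `bh_fdr()`,
  `fisher_exact_2x2()`, `chi_square_independence()`, `two_sample_t_test()`.
* **Synthetic cohorts** (`generate_cohort()`): seeded cohorts with a latent
  responder state, planted oriented pairs, exponential proportional-hazards
  survival, uniform censoring and noisy response labels, plus batch-effect
  and degradation operators for robustness experiments.

## Worked example

Generate a cohort under the reference study conditions (300 patients, 150
genes, 4 planted pairs, non-responder hazard ratio 3), discover a signature,
and validate it:

```r
library(reosig)

cohort <- generate_cohort(generator_config(seed = 7))
disc   <- run_discovery(cohort$expression, cohort$clinical)
disc
#> Signature discovery run
#>   stage counts:
#>     genes              150
#>     de_genes           12
#>     prognostic_genes   9
#>     candidate_pairs    36
#>     prognostic_pairs   11
#>     signature_pairs    8
#> Gene-pair signature: 8 pair(s), strict-majority vote (responder iff > 4 favorable)
#>   G0072>G0122
#>   G0072>G0015
#>   ...
#>   training C-index: 0.638

report <- validate_signature(cohort$expression, cohort$clinical, disc$signature)
report
#> Validation report: n = 300 (responders 139, non-responders 161)
#>   log-rank: chi-square = 52.156, p = 5.13e-13
#>   univariate Cox (non-responder vs responder): HR = 3.01 (95% CI 2.20-4.11), p = 4.62e-12
#>   C-index = 0.638
#>   multivariate Cox (n_used = 300), adjusted for: stage_ord, grade_3; signature HR = 3.01, p = 4.58e-12
```

Reading the numbers: the 12 genes passing the differential-expression screen
shrink to 9 prognostic genes and 36 candidate pairs, of which 11 survive FDR
control; forward selection keeps 8 (here including all four planted pairs).
Predicted non-responders recur three times faster than predicted responders
(HR ≈ 3, the generator's configured value), and the C-index of 0.64 sits at
the information ceiling set by a latent two-state risk model with that hazard
ratio — a reminder that a *correct* binary signature on such data cannot
reach C = 1.

Classifying a single new sample requires no cohort:

```r
vote_classify(cohort$expression[, 1, drop = FALSE], disc$signature)
#>   sample_id vote_count         label
#> 1     S0001          1 non_responder
```

A thin command-line front end over the same functions lives in
`inst/cli/reosig.R` (`simulate`, `discover`, `classify`, `validate`).

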