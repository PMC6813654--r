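---
title: "Qualitative gene-pair signatures: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative gene-pair signatures: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosig)
```

## The problem and the modelling idea

Quantitative transcriptional risk scores are fragile in clinical use: absolute
expression values shift with laboratory, platform, specimen storage and
amplification protocol, and median-anchored scores cannot classify one patient
without a reference cohort. `reosig` implements the qualitative alternative: a
signature made of **relative expression orderings** (REOs). For an oriented
gene pair $(a, b)$ the only information used is the within-sample indicator

$$ I_{ab}(s) = \mathbf{1}\{E_a(s) > E_b(s)\}, $$

which is invariant to *any* strictly increasing transformation applied to
sample $s$ and needs no other sample to evaluate. A signature is an ordered
set of $k$ such pairs with a strict-majority rule: sample $s$ is predicted a
**responder** (to platinum–taxane adjuvant chemotherapy, in the motivating
application to high-grade serous ovarian cancer) iff more than $k/2$ of its
pairs show the favorable ordering. The shipped four-pair signature
(`four_gps()`: FUS>THBS2, GUCY2C>RCVRN, PCSK6>ZNF365, PASK>DNAJB14) therefore
calls a responder iff at least three of the four orderings hold.

## The discovery pipeline

`run_discovery()` chains four stages, each with a strict threshold
(`p < alpha`, never `<=`):

1. **Follow-up truncation.** Recurrence-free survival (RFS) is truncated at 60
   months: records followed strictly beyond the horizon are censored at it.
   All later survival analyses see the truncated outcome.
2. **Differential expression.** Pooled-variance two-sample *t*-tests between
   pathological complete-response (CR) and non-CR samples; default
   `de_alpha = 0.05`. This stage (and the next) intentionally uses
   quantitative values — only the pair stages are rank-based.
3. **Prognostic genes.** Univariate Cox proportional-hazards fits of each DE
   gene's continuous expression on RFS; default `cox_alpha = 0.05`.
4. **Prognostic pairs and forward selection.** All $\binom{m}{2}$ pairs of
   surviving genes are formed; each pair's REO indicator enters a univariate
   Cox model; pairs are oriented so the favorable pattern has hazard ratio
   below 1, Benjamini–Hochberg adjusted over all tested pairs, and kept at
   `pair_fdr = 0.05`. Greedy forward selection then grows a set from every
   surviving pair as seed, at each step adding the pair that most increases
   Harrell's C-index of the strict-majority vote, stopping when no addition
   strictly increases it, and returns the seed-grown set with the largest
   final C-index.

Any stage that leaves no survivors raises a condition of class
`reosig_stage_error` naming the stage, so callers can distinguish "no signal"
from a crash.

### Tie-breaking and the strict-increase rule

Three choices in forward selection were genuinely open and are fixed as
follows, for reproducibility:

* candidate additions whose C-index agrees within $10^{-12}$ are ordered by
  smallest pair-level adjusted *q*, then lexicographic pair name;
* among seed-grown final sets: largest C-index, then fewest pairs, then
  lexicographic names;
* "until the C-index did not increase" is read as *strict* increase required
  to continue, so every recorded growth path is strictly increasing.

The strict reading has a consequence worth knowing. The vote of an even-sized
set is conservative (a 2-pair signature calls responder only when *both*
orderings are favorable), and when single pairs are already accurate proxies
of the underlying risk state, the step from one to two pairs often does not
improve the concordance index at all — the population-level gain of voting
only materializes at three or more pairs. Growth through that plateau happens
only via sampling fluctuation, so on cohorts with near-noiseless planted
pairs, forward selection frequently halts at one or two pairs or takes in
moderately informative bystander pairs. The acceptance script reports the
resulting planted-pair recovery fraction; it is an honest property of this
search rule, not of the voting model. A non-strict reading would grow through
plateaus but makes the trace non-monotone and the stopping rule ill-defined
under exact ties, so it was rejected.

## The statistical kernel

All survival machinery is exposed directly (`cox_fit`, `km_estimate`,
`logrank_test`, `concordance_index`, `bh_fdr`, `two_sample_t_test`,
`fisher_exact_2x2`, `chi_square_independence`) with these conventions:

* **Cox fits** maximize the partial likelihood with **Efron** tie handling;
  Wald standard errors, p-values and 95% CIs $\exp(\beta \pm 1.96\,se)$.
  Constant covariates are an error; monotone-likelihood fits are returned
  flagged `converged = FALSE` and excluded from screens with a warning.
* **Harrell's C**: a pair $(i, j)$ is comparable iff $t_i \ne t_j$ and the
  earlier subject had an event; concordant iff that subject has strictly
  higher risk; tied risk scores contribute 0.5. With a binary risk score this
  convention bounds C below 1 unless within-group event times are tied —
  relevant when reading "perfect" toy examples.
* **Fisher's exact test** is two-sided by the minimum-likelihood convention
  (sum of hypergeometric probabilities not exceeding the observed table's,
  with $10^{-7}$ relative tolerance).
* The ***t*-test** defaults to pooled variance (classical Student), switchable
  to Welch via `var_equal = FALSE`; zero pooled variance is a "degenerate
  gene" error, and screening functions skip such genes with a warning rather
  than failing the run.
* **Validation reports** (`validate_signature()`) code covariates as: age
  dichotomized at 60 years, stage ordinal II/III/IV as 2/3/4, grade 3 vs 2,
  residual tumor ≥11 mm vs 0–10 mm. Covariates pass into the multivariate
  Cox model when their univariate Wald p is strictly below 0.2; the
  multivariate fit is complete-case with `n_used` reported. An empty
  predicted group marks the group statistics not-computable instead of
  erroring.

## The synthetic-cohort generator

`generate_cohort()` produces the statistical structure the pipeline assumes,
fully determined by a seed. Defaults describe the reference study conditions:
300 patients, 150 genes, 4 planted pairs, ordering-flip probability
`reo_error = 0.05`, responder prevalence 0.5, exponential survival with
baseline hazard 0.02/month and hazard ratio 3 for latent non-responders,
uniform censoring on (0, 80) months (roughly one-third censored after
truncation), and a 10% CR/non-CR misreporting rate.

Construction of a planted pair $(a, b)$: a shared per-sample midpoint
$m \sim N(\mu_{ab} + h\,(z - \tfrac12),\, 1)$, where $z$ is the latent
responder state and $h = 2$ (log2-like units), and a signed gap $d$ with
$|d| \sim$ folded $N(1, \sigma)$ ($\sigma$ = `noise_sd`, default 0.5), sign
positive for responders and flipped independently with probability
`reo_error`; then $a = m + d/2$, $b = m - d/2$. The state shift $h$ makes
each planted gene individually differentially expressed and prognostic — as
it must be to survive the quantitative screens — while cancelling in every
cross-gene difference, so only the oriented within-pair gap tracks the state
cleanly. Background genes are i.i.d. normal with per-gene means uniform on
[4, 12] and unit spread. Clinical covariates are drawn from fixed marginals
independent of the latent state.

Perturbation operators model the two failure modes the REO construction is
designed against: `apply_monotone_distortion()` (per-sample affine, power or
softplus-composite transforms — batch effects) and `degrade_samples()`
(additive noise plus floor-dropout — specimen-quality loss). Monotone
distortion provably leaves every REO indicator unchanged; degradation does
not, and `robustness_experiment()` quantifies the label concordance of the
vote and of the median-anchored comparator under both.

What the generator does **not** emulate: gene–gene correlation beyond the
planted construct, count-based RNA-seq noise (negative binomial), probe- or
platform-specific effects, informative censoring, covariates correlated with
risk. Passing parameter-recovery tests on these cohorts therefore shows the
pipeline recovers the structure it assumes — not that it would perform
identically on real tumor cohorts.

## Numerical and interface choices

* Linear-scale input (e.g. FPKM) is transformed as $\log_2(x + 1)$ by
  default; the offset avoids $-\infty$ at zero and is user-settable. Whether
  zero-expression genes should instead be filtered is left to the caller.
* An expression tie $E_a = E_b$ counts as *not favorable* (indicator 0); ties
  have measure zero in continuous data.
* Gene identifiers are opaque case-sensitive strings; probe-level input is
  collapsed by averaging, with probes mapping to zero or multiple genes
  dropped.
* A missing signature gene is an error, not an abstention.
* Signatures serialize to JSON with fixed key order; predictions to TSV.
* Problem sizes in the test-suite simulations (cohorts of 100–1000 samples,
  20–150 genes, 20–500 replicates depending on the property) were chosen as
  the smallest at which the checked quantities are stable; the acceptance
  script uses the reference conditions above, with held-out evaluation done
  on seeded 50/50 splits (`split_cohort()`).

## Known limitations

* The forward-selection plateau discussed above: with highly accurate
  individual pairs the returned signature may be smaller than the planted
  truth, and bystander pairs sharing genes with true pairs can enter it.
* The comparator's shipped behavior needs a user-supplied gene list with
  per-gene directions and threshold; it exists to demonstrate
  cohort-dependence, not as a validated risk score.
* No time-varying covariates, stratified Cox, or competing risks; Efron is
  the only tie-handling offered.
* The pipeline assumes one expression matrix already on a common gene
  universe; use `intersect_gene_universe()` and `collapse_probes()` upstream
  when combining platforms.
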