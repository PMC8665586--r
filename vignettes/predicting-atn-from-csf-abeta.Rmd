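---
title: "Predicting tau pathology and neurodegeneration from CSF amyloid-beta isoforms"
author: "abatn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tau pathology and neurodegeneration from CSF amyloid-beta isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`abatn` re-implements, as tested R code, a study design in which CSF
amyloid-beta isoform levels in cognitively unimpaired (CU) adults are
used to predict two downstream Alzheimer-pathology labels: tau
positivity (T+, p-tau181 > 19.2 pg/mL) and neurodegeneration
positivity (N+, t-tau > 242 pg/mL).  Because the cohort data behind
such studies are access-restricted, the package is built around a
calibrated synthetic-cohort generator; all claims the test suite makes
are claims about that generator plus the methods, not about any real
cohort.  This vignette documents the models, the tunable parameters,
the numerical choices, and the limitations.

## The synthetic cohort model

### Isoforms

Concentrations are strictly positive and visibly right-skewed in this
kind of assay data, so each biomarker group (T−, T+, N−, N+) gets a
trivariate lognormal on (Aβ1-38, Aβ1-40, Aβ1-42).  The published
group summary statistics are stored in `default_group_params()` and
converted by `calibrate_lognormal()`:

* per isoform, exact lognormal moment matching:
  $\sigma^2 = \log(1 + \mathrm{CV}^2)$,
  $\mu = \log(\text{mean}) - \sigma^2/2$;
* per isoform pair, the log-correlation is solved from the published
  ratio's log-variance through
  $\mathrm{Var}(\log X - \log Y) = \sigma_x^2 + \sigma_y^2 - 2\rho\sigma_x\sigma_y$.

A lognormal was chosen over a truncated Gaussian because it makes the
three ratio features (42/40, 42/38, 40/38) analytically tractable:
ratios of jointly lognormal variables are again lognormal.  Ratios are
always *computed from the sampled isoforms*, never sampled separately,
so the six biomarker features stay algebraically coherent.

Two numerical guards apply.  If the published moments imply
$|\rho| > 1$ (they can: the table is real data, not a lognormal), the
correlation is clamped to $\pm 0.999$ with a warning; and if the
pairwise-assembled covariance is not positive definite, its
off-diagonals are shrunk toward zero (again with a warning) until it
is.  Neither guard triggers for the default group parameters.

One fidelity limit is worth stating precisely: the published table
carries more moments (3 isoform means + 3 SDs + 3 ratio means + 3
ratio SDs) than a trivariate lognormal has parameters (9).  We match
the isoform moments exactly and the ratio *log-variances* exactly; the
arithmetic ratio means are then implied, and land within about 3% of
the published values (worst case: the T+ 42/40 ratio).  The test
suite asserts a 4% band for the implied ratio moments and exactness
for what is matched exactly.

### Labels, demographics, proteomics

The configured outcome's tau marker is drawn from a lognormal
*truncated to the correct side of its threshold* (inverse-CDF
truncation around a log-offset of ±0.25 at log-SD 0.35), so
`label == (marker > threshold)` holds exactly by construction rather
than approximately; the other tau marker is drawn untruncated from a
group-shifted lognormal and its label computed from the value.  The
tau marginals are deliberately *not* fidelity targets — they are label
carriers.  Age and education are group-conditional Gaussians, sex and
APOE ε4 group-conditional Bernoullis; the stored group values imply an
age shift of ≈3.4 years and an APOE enrichment for the positive
groups, and essentially no sex/education signal, matching the
published group table.  Default prevalence is 0.31 for T (from the
published test-set stratification, 74 positives of 238 predictions)
and 43/110 for N (from the published group sizes); both are free
parameters.

`generate_proteomics()` emulates a targeted MRM panel: 567 peptides ×
cohort subjects, log-scale Gaussian abundances with unit within-group
SD, `n_differential = 30` peptides shifted upward by
`effect_size = 1.5` SD in labelled positives, missing-at-random cells
at `missing_rate = 0.05`, plus a block of `n_low_detect = 247`
peptides whose observed fraction is forced to at most 10% — so the
detectability filter retains exactly 320 of 567, the published panel
split.  The effect size and contrast sizes (55 vs 21) reflect the
published proteomics sub-study; with them the moderated-t arm should
(and in tests does) reach sensitivity ≥ 0.8 at observed FDR ≤ 0.10.
The generator also emits a GMT annotation whose single non-null term
is exactly the planted set, for enrichment-recovery experiments.

What the generator does *not* emulate: assay noise structure,
longitudinal visits, batch effects, missing-not-at-random patterns,
and real covariance between demographics and isoforms.  A green test
suite therefore shows the *methods* behave correctly under the stated
conditions, not that any particular AUC would be attained on real
cohort data.

## The model search

`build_features()` produces the canonical ten predictors in a fixed
order (`ab38, ab40, ab42, r4240, r4238, r4038, age, education, sex,
apoe4`); sex is 1 = female and APOE is carrier status (at least one ε4
allele), documented constants where the underlying study is silent.
`enumerate_subsets()` walks all $2^{10}-1 = 1023$ non-empty subsets in
ascending-bitmask order; the bitmask doubles as a stable subset index.

For each subset, `nested_cv_select()` tunes nine classifier families
by nested cross-validation: a 2-fold inner loop scores every (family,
grid point) by rank-based AUC, and a 5-fold outer loop refits each
outer fold's inner winner and scores it on the held-out outer fold,
giving five outer AUCs.  Subsets are ranked by `auc_mean - auc_sd`.
The hyperparameter grids (`default_algorithms("full")`) follow the
published table; `"reduced"` keeps one sensible candidate per family
for fast runs (and smaller ensemble sizes, chosen once as the
package's smoke-test scale).  Points worth calling out:

* **Selection protocol.**  Hyperparameters are selected per outer fold
  (for honest error estimation) *and* once on the full search data by
  the same inner-CV rule (for the final refit); the underlying study
  is ambiguous between these, so both are computed and reported
  together in the `subset_result`.
* **Scaling** is a per-family concern: logistic, k-NN and SVC see
  features standardised with training-fold statistics only;
  tree/boosting families see raw features.
* **SVC C grid.**  The published non-linear-kernel C values
  (−4 … 3) are read as powers of ten, since a non-positive cost is
  invalid; the linear kernel uses the raw positive grid.
* **Backends.**  Ridge logistic uses glmnet with
  $\lambda = 1/(nC)$; naive Bayes and SVC use e1071; trees use rpart;
  random forest uses ranger.  Both the gradient-boosting and XGBoost
  families are backed by xgboost, each with its own grid (R has no
  separate canonical gradient-boosting engine in this package's
  dependency set).  k-NN (Minkowski p ∈ {1, 2}, probability votes)
  and AdaBoost (SAMME over depth-1 rpart stumps) are implemented in
  the package.
* **Scores.**  Families without native probabilities (SVC, AdaBoost)
  contribute their continuous decision values — the AUC is rank-based,
  so calibration is irrelevant; confusion counts threshold
  probabilities at 0.5 and decision values at 0.
* **Ties** between candidates are broken by fixed family order, then
  grid order; **failing grid points** are skipped and logged, never
  fatal; **seeding** flows from one master seed through derived
  per-component streams (hold-out split, folds, stochastic learners),
  making whole reports byte-reproducible.
* **Per-subset independence.**  Fold assignments depend only on the
  configuration seed, so a subset's result never depends on which
  other subsets were searched; `run_search()` is resumable by subset
  index for the same reason.

`fit_atn()` wraps the whole procedure in a classic modelling
interface: a stratified 25% hold-out is split off *before* any search
(`test_fraction` configurable; the underlying study does not state its
test-set size, so this is a documented default), the search runs on
the remainder, and `evaluate_winner()` refits the top subset's model
on all search data and scores the untouched test set — any subject-id
overlap is a hard "leakage" error.  `stratify_predictions()` then
partitions test subjects into TP/FP/TN/FN for the downstream
proteomics contrasts.

## Univariate statistics

`mann_whitney()` returns the U statistic with midrank ties, an exact
two-sided p by enumeration when $n_1 + n_2 \le 12$ and tie-free, and
otherwise the tie- and continuity-corrected normal approximation (at
$n_1 = n_2 = 6$ the two agree to within about 0.015; the corrected
approximation's worst-case error is slightly above 0.01 at this size).
`U/(n_1 n_0)` is identically the empirical AUC used by the search — a
shared oracle the tests exploit.  `binormal_auc()` is the closed form
$\Phi(\Delta\mu/\sqrt{\sigma_+^2+\sigma_-^2})$; it is *signed*
(below 0.5 when positives score lower), with direction correction
`max(v, 1-v)` applied where a fitted one-feature logistic model would
learn the direction.  Welch t and Fisher exact back the descriptive
cohort table; a zero-margin 2×2 table returns p = 1 by convention.

## Differential expression and enrichment

`moderated_t()` is a from-scratch empirical-Bayes two-group moderated
t.  Per peptide, group means and the pooled residual variance $s^2$
(df $d$) come from pairwise-complete observations — no imputation,
the simplest defensible treatment of the panel's missingness;
peptides with fewer than two observations per group are skipped and
counted.  The scaled inverse-chi-square prior $(d_0, s_0^2)$ is
estimated by moment matching of $\log s^2$ using digamma/trigamma
inversion (Newton's method on the trigamma function); the posterior
variance $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ yields
$t = \Delta\bar x / (\tilde s\sqrt{1/n_1 + 1/n_2})$ on $d_0 + d$ df.
In the $d_0 \to 0$ limit this is the ordinary pooled t; as
$d_0 \to \infty$ all peptides share $s_0^2$.  On complete data the
implementation agrees with limma's to machine precision (a test, not
a dependency).  The FDR procedure is Benjamini-Hochberg (`bh_adjust`,
a validated interface over the standard step-up), with the DEP flag at
adjusted p < 0.05.  A max-|t|-per-protein roll-up is provided as an
optional extension; the core analysis is peptide-level.

`ora()` computes the upper-tail hypergeometric overlap p per GMT term,
BH-adjusted across terms.  The universe is the *detectable measured
panel* (peptides surviving the >10% filter), not the genome — the
panel defines what could have been called — and is an explicit
argument.  `term_network()` connects significant terms by the Jaccard
coefficient of their overlap-member sets, with node weight
$-\log_{10}(\text{adjusted } p)$.  Ranked GSEA is deliberately not
implemented; the analysed design is over-representation of a DEP list.

## The pipeline

`run_all(run_config())` chains simulate → describe → search (T and N)
→ evaluate → stratify → differential expression (group contrast plus
TP/FP and TN/FN contrasts when the strata are large enough) →
enrichment, with one master seed, one YAML-configurable parameter set,
per-stage artifact files and a `summary.json`.  A stage failure stops
with the stage name; completed artifacts persist.  Running with no
configuration reproduces the calibrated synthetic study at reduced
grids; `full_grids: true` restores the full published grids.  There is
deliberately no shell entry point: the package's users work in R, and
the exported stage functions plus this orchestration are the
interface.

## Problem sizes and test design

The suite builds everything from code at test time.  Cohort-level
checks use n = 318 (the study scale) and a 100 000-subject draw for
law-of-large-numbers calibration checks; search-level checks use 2-3
feature catalogues at n ≈ 80-120 with the reduced roster, which
exercises every code path of the 1023-subset machinery at a fraction
of its cost; leak-freedom is established by 50 permuted-label runs of
the full search-plus-test pipeline; proteomics error control uses 50
seeds of the 567 × 76 panel at the published contrast sizes.  These
sizes are the package's chosen desk scale for routine verification.

## Known limitations

* The generator's group-conditional independence between isoforms and
  demographics is a simplification; real cohorts correlate age with
  biomarker levels within groups.
* The implied ratio means deviate from the published ones by up to
  ~3% (overdetermination, discussed above).
* Flagship multivariate test-set AUCs reported for the real cohort
  (≈0.93) are not reproduction targets: they depend on restricted
  data.  The package's substitutes are property-based — calibrated
  single-feature AUC recovery, chance-level behaviour under permuted
  labels, and separable-signal sanity checks.
* The moderated-t model fits no covariates (mirroring the analysed
  design) and the prior fit is the plain, non-robust moment matcher.
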