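---
title: "Structural connectome-based predictive modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural connectome-based predictive modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In patients with diffuse gliomas after multimodal therapy, cognitive
deficits are thought to arise from damage to white-matter connections
between distributed cortical networks rather than from single lesioned
regions. `structcpm` models this relationship with connectome-based
predictive modeling (CPM): per-subject structural connectivity matrices —
`N x N` tables of streamline (fiber) counts between the nodes of a
whole-cortex parcellation — are used to predict performance on a
neuropsychological battery, and the edges and nodes carrying the
prediction are mapped back onto the brain's network organization.

The package operates on three inputs: fiber-count connectivity matrices
(one per subject, symmetric, nonnegative integers, zero diagonal), a
parcellation table assigning each node a hemisphere and one of the seven
canonical resting-state networks (visual, somatomotor, dorsal attention,
ventral attention, limbic, frontal control, default mode), and a score
table for a 10-test battery spanning five cognitive domains. The default
parcellation has 100 nodes (50 per hemisphere), so a matrix has
`100 * 99 = 9900` informative off-diagonal entries — the denominator for
every "% of possible edges" figure — corresponding to 4950 unique
undirected edges.

### Directed entries versus unique edges

Connectivity matrices are symmetric, so entries `(i, j)` and `(j, i)`
are statistically identical. Internally every computation runs once per
unique edge (upper triangle, `i < j`, row-major flat order); all
*reported* edge counts are directed-entry units (unique counts times 2),
the convention under which the per-test count tables of this literature
are written (their counts are always even and their percentages use
`N(N-1)`). `edge_universe()`, `edge_index()`, `vectorize_edges()` and
`unvectorize_edges()` fix these coordinates; they are stable across
versions. Node ids are 1-based in files and interfaces.

## The CPM protocol

For a test with score vector `y` over `n` subjects and edge matrix `X`
(`n x p` unique-edge fiber counts):

1. **Edge screening.** Each edge is related to the score by tie-aware
   Spearman correlation (Pearson correlation of mid-ranks). Mid-ranks
   are mandatory because fiber counts contain many tied zeros. Two-sided
   p-values use the t-approximation on `n - 2` degrees of freedom —
   standard practice at `n` near 120 — and edges with `p < alpha`
   (default `alpha = 0.001`) are selected. Signs are defined relative to
   *performance*: for time-scored tests (Trail-making A/B, where lower is
   better) the raw correlation sign is flipped, so a "positively
   associated" edge always means more fibers, better performance.
2. **Summary connectivity values.** Per subject, the fiber counts of the
   selected positive and negative edge sets are summed separately.
3. **Linear model.** Ordinary least squares of the score on the positive
   summary value, optionally with confounding covariates. Models from
   negatively associated edges are only reported descriptively
   (`negative_edge_map()`); final predictive models use positive edges
   exclusively, where the bulk of the signal sits (98% of screened edges
   in the motivating data).
4. **Leave-one-out cross-validation and permutation test.** Each subject
   is predicted from a model whose *entire* pipeline — screening,
   summing, fitting — is re-run on the remaining `n - 1` subjects, so no
   information about the left-out subject reaches feature selection (a
   property asserted by test). Predictive power is the Pearson
   correlation between out-of-fold predictions and observed scores, plus
   the RMSE. Its significance comes from a permutation test: the score
   vector is shuffled `n_perm = 100` times and the complete
   cross-validation is re-run per shuffle. The p-value uses the add-one
   convention `p = (1 + #[r_perm >= r_obs]) / (1 + n_perm)`, whose
   smallest value at 100 iterations is `1/101` — the conventional 0.01
   floor at 2-decimal reporting.

### Brain mapping

Edges selected in at least 90% of the cross-validation folds (inclusive
threshold) of a model passing the permutation test (`p < 0.05`) are
*validated predictive edges*; a failing model yields an empty map
flagged "CV not passed". Validated edges are classified as
within-network (both endpoints share a network label, hemisphere
ignored) or between-network. A node's degree is the number of unique
validated edges incident to it; summed over nodes this equals twice the
unique edge count. Criticality thresholds come from the nonzero-degree
distribution: critical nodes have degree at least
`floor(mean + 1 * SD)`, highly critical `floor(mean + 2 * SD)` (sample
SD). Flooring to integers reflects how such cutoffs are quoted in
practice — a nonzero mean of 5.4 and SD of 5.2 yield the conventional
"degree >= 10". Both multipliers are configurable.

### Covariate models

Demographic, clinical and tumor-related covariates are screened
nonparametrically, the statistic family being a pure function of the
covariate class: Spearman for continuous/ordinal (age, ISCED education,
interval since treatment, intervention counts, lesion volumes per lesion
type), Mann-Whitney U for binary (sex, IDH status, grade 3 vs 4,
recurrence), Kruskal-Wallis for multi-level categorical (tumor
location). Normal/chi-square approximations with tie correction are used
(exact enumeration appears only in the test suite's oracles). When every
score is tied the Kruskal-Wallis statistic is reported as 0 by
convention. `compare_families()` fits full-cohort (not cross-validated)
OLS models per family — pure connectivity, demographic (age +
education), tumor-related (recurrence + lesion volumes + location), and
the combined families — and compares per-test R-squared vectors with
paired t-tests. Keeping these as full-sample fits, with cross-validation
confined to `loocv_predict()`, mirrors how the two kinds of numbers are
reported in this literature.

### Normative deficit classification

A patient has a clinically relevant deficit on a test when the score is
strictly worse, in performance terms, than the control mean minus 1.5
control SDs: below `mean - 1.5 SD` for higher-is-better tests, above
`mean + 1.5 SD` for time-scored tests. Boundary equality is non-deficit
(ties are not addressed in the source conventions; strict inequality is
the conservative reading). Under normal scores, controls classified
against their own norms show a deficit rate near `pnorm(-1.5)`, about
6.7% — a calibration asserted by test.

## The synthetic cohort generator

No patient-level data are distributed with analyses of this kind, so
`generate_cohort()` produces cohorts with the statistical structure the
analysis assumes, with full recorded ground truth:

* **Counts.** Each unique edge's fiber count is negative binomial
  (Poisson-gamma; `dispersion` is the NB size, default 8). Baseline
  means depend on the edge class — intra-network 160, intra-hemisphere
  (different networks) 80, inter-hemispheric 25 fibers by default — with
  a mean-preserving lognormal spread across edges
  (`edge_log_sd = 1`). The class ordering reproduces the block structure
  of real fiber-count matrices (intra-hemispheric above
  inter-hemispheric connectivity), and the between-edge spread produces
  the long right tail of tractography counts (medians of tens of fibers,
  maxima in the thousands).
* **Lesions.** Patients are assigned a lesion side (`45% L / 45% R /
  10% none` by default). Every edge incident to an ipsilesional node is
  scaled by `1 - lesion_loss` (default 0.175) and re-rounded, so the
  median ipsilesional nodal fiber sum sits near 82.5% of the
  contralesional one — the 15-20% nodal fiber loss regime reported for
  treated glioma cohorts.
* **Scores.** Seven of the ten tests carry a planted effect: a disjoint
  set of `n_planted = 30` edges whose negative binomial means are scaled
  by a per-subject, per-test lognormal latent ability factor
  (`ability_sdlog = 0.45`). The score is linear in the *realized* fiber
  counts: `score = intercept + sum(w * fiber) + beta_age * age +
  beta_edu * education + noise`, sign-flipped into native units for
  time-scored tests. The weight `w` is calibrated so the connectivity
  term attains a target variance share of `r2_connectivity = 0.40` *in
  the patient cohort* (the cohort whose model R-squared the analysis
  reports; full-sample R-squared values of 0.35-0.45 are the regime of
  interest). Centering uses the *control* summary mean, so patients —
  whose ability factor is reduced by `ability_deficit = 0.30` and whose
  planted edges are additionally depressed by lesions — fall below
  controls without any hand-placed offset. Age and education carry
  variance shares of 0.06 and 0.04 (age hurting, education helping
  performance). The three remaining tests are covariate-plus-noise only,
  with a fixed 0.45 SD patient shift so they still show impairment.
  With `noise_sd = 0` the scores reproduce the recorded linear model
  exactly, which the tests exploit as a closed-form oracle.
* **Controls.** Control scores follow the same score model with no
  lesion and no ability deficit; their fiber draws enter through the
  planted-edge sums only. Control age/education are drawn from the same
  marginals (a matched-cohort design).

What the generator does **not** emulate: anatomical geometry and tract
shapes, spatially contiguous lesions (loss is hemisphere-wide and
multiplicative), correlations *between* test scores beyond shared
covariates (each test has an independent latent ability), metabolic
imaging signal, and longitudinal change. Passing tests therefore
demonstrate that the pipeline recovers planted effects under the assumed
statistical structure — not that it would behave identically on real
tractography, where edge noise is spatially correlated and effects are
not exactly linear.

## Numerical and performance choices

* Screening inside cross-validation is fully vectorized. The edge table
  is radix-sorted once per test; each fold's mid-ranks are derived by
  run-length arithmetic over the precomputed sort (dropping a subject
  shifts within-column rank positions; tie groups are unchanged). Edge
  ranks *must* be recomputed per fold — they change when a subject is
  dropped — but no re-sorting is needed. The observed scores and all
  permuted score vectors are screened simultaneously against each fold's
  rank matrix via one matrix product, and selection uses the equivalent
  threshold `|rho| > rho_crit(alpha, n)` rather than materializing
  per-edge p-values. A full leave-one-out run with 100 permutations on a
  121 x 4950 cohort takes on the order of 15 seconds on one CPU; the
  complete 10-test pipeline runs in a few minutes.
* Strictness conventions: edge selection is `p < alpha` (equivalently
  `|rho| > rho_crit`); the fold threshold is inclusive (`>= 0.90`, "at
  least 90%"); the permutation gate is `p < 0.05`; deficit thresholds
  use strict inequality.
* Constant edges (zero rank variance, e.g. all-zero fiber counts) have
  undefined correlations and are never selected. Folds whose screening
  selects no edge degrade to an intercept (plus covariates) prediction;
  they are counted (`n_empty_folds`) rather than aborting the run.
* A cross-validated prediction vector that is exactly constant has an
  undefined correlation with the observed scores; its `r` is reported
  as 0 (no predictive ability).
* Under null (shuffled) scores the cross-validated `r` is slightly
  *negatively* biased — a known artifact of per-fold feature selection —
  so null checks bound positive skill rather than `|r|`.
* Matrices are required to be exactly symmetric on input; tractography
  outputs with asymmetric counts must be symmetrized upstream, since no
  single symmetrization rule is canonical. Nonzero diagonals are zeroed
  with a warning. Missing scores drop subjects pairwise per test.
* Display rounding follows the field's table conventions — r to 3
  decimals, permutation p to 2 (making 0.01 the reportable floor at 100
  iterations), percentages to 1 — while all stored values keep full
  precision.
* All randomness flows from explicit integer seeds; per-test permutation
  streams inside `run_pipeline()` are derived deterministically from the
  root seed, so identical inputs and seed give bit-identical outputs.

## Problem sizes used by the test suite

Unit tests run on a 30-node parcellation with 60 patients, where a
leave-one-out pass takes well under a second. Study-scale properties —
the 15-20% lesion regime, the permutation-test floor, type-I edge
selection rates under permuted scores (about `alpha * 4950` selections
per permutation), parameter recovery over 20 seeded replicates (mean
Jaccard overlap between screened and planted edges at least 0.5,
cross-validated r positive and inside its expected 0.35-0.85 band in
every replicate), and the full 10-test pipeline with 100 permutations —
run on the default 121-patient, 100-node configuration.

## Known limitations

* The Spearman t-approximation is mildly liberal in the extreme tail at
  modest n; at `alpha = 0.001` and `n = 121` the realized per-edge
  selection rate under the null is statistically indistinguishable from
  nominal in our checks, but exact permutation p-values are not
  offered.
* Negative-edge models are reported descriptively only; there is no
  cross-validated negative-edge predictor.
* Only leave-one-out cross-validation is implemented (no k-fold or
  split-half variants), and only linear prediction models.
* The deficit table's percent-deviation column is the percent deviation
  of the patient group *mean* from the control mean (a mean-of-group
  ratio), one of several possible conventions.
* `run_pipeline()` is single-threaded by design; results are independent
  of any outer parallelization.
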