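---
title: "Drugs as classifiers: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drugs as classifiers: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models fitted, the parameters that matter and their defaults, what the
synthetic data do and do not emulate, and the choices made where more than
one defensible design existed. The companion scripts under `analysis/`
show the pipeline applied end to end.

## The model family

Every stage uses the same engine: a generalized linear model relating a
linear combination of predictors to the response through an inverse link,

* binary cell state (healthy = 0, cancer = 1): Bernoulli family,
  `P(y = 1 | x) = logistic(β₀ + x'β)`;
* continuous chemosensitivity, in −log(GI50) units (larger = more
  sensitive): Gaussian family with identity link.

To prevent overfitting, the fit minimizes a penalized mean negative
log-likelihood, `(1/n)·NLL + λ·P(β)`, with `P(β) = Σ|β_k|` (L1) or
`½Σβ_k²` (L2); the intercept is never penalized. L2 is the default for the
single-cell classifier, where many of the ~45 curated markers plausibly
carry some signal and shrinkage (not selection) is wanted; L1 is used for
drug-response models, where a genome-scale predictor set is expected to be
almost entirely irrelevant per drug and sparsity is the point. Penalized
fits are solved by coordinate descent via `glmnet` behind the package's
own interface; unpenalized two-feature pair models use iteratively
reweighted least squares (`glm.fit`).

### Standardization

Predictors are z-scored on each training split before fitting, and the
centering/scale constants are stored in the model and re-applied at
prediction. This has two consequences worth stating. First, ranking genes
"by magnitude of fit parameter" is only meaningful on a common scale, and
all rankings here use standardized-scale weights. Second, predictions are
invariant to affine rescalings of any input column (a unit change never
changes a classification). Zero-variance columns get scale 1, so their
centered values are identically zero and any penalty drives their weight
to exactly zero.

### Choosing λ

The candidate grid is 50 logarithmically spaced values from λ_max down to
`1e-4·λ_max`, where λ_max is the smallest strength that zeroes every
weight, computed from the standardized training data as
`max|X'(y − ȳ)|/n`; ridge has no finite zero-crossing, so its grid top is
inflated 1000-fold. The selected value minimizes the mean held-out
*deviance* — the GLM-native loss; misclassification rate would discard
calibration information — over 10 stratified folds, with fold assignment a
deterministic function of the seed. Two caveats are built in rather than
discovered: cross-validated deviance needs at least 4 folds (below that
the package raises a configuration error), and learning-curve fits on
fewer than 4 cells per class use a fixed fallback of `1e-2·λ_max` because
inner CV on a handful of points selects noise. With only one cell per
class, where coordinate-descent software cannot run at all, the penalized
objective is minimized directly by L-BFGS; this covers the smallest
training sets the cell-count curves visit.

## Part I: classification of single cells

`nested_cv_scores()` implements two nested levels of 10-fold
cross-validation: the outer level estimates generalization (every cell is
scored exactly once, by a model that never saw it), the inner level
selects λ within each outer training split only. Outer folds are
stratified by class — plain random folds can strand a class entirely, and
stratification is the standard reading of "10-fold CV" on labeled data.

ROC curves sweep thresholds over the unique score values; the AUC is the
trapezoidal integral, which with midrank handling of ties equals the
Mann–Whitney statistic `P(score⁺ > score⁻) + ½P(tie)`. The test suite
pins this equivalence to 1e-12 against an exhaustive pairwise oracle.

Chance levels come from a *shuffle control*: each of 100 permutations
re-runs the entire nested-CV scoring on permuted labels, so the null
distribution reflects everything the pipeline does, not just the final
AUC computation. The gene-count and cell-count curves use a cheaper
display null (permuting labels against the already-computed out-of-fold
scores) since re-running the full control per curve point would multiply
cost ~20-fold for a line whose only role is visual reference; the rigorous
control remains a separate, tested operation.

Two leakage-sensitive choices deserve note. The gene-count curve re-ranks
genes *inside each outer training fold* and refits per gene count k; an
alternative reading — masking weights of one full-data fit — would leak
test information into the ranking. And the cell-count curves draw
class-balanced training subsets (equal cells per class) with evaluation
always on the strictly held-out remainder, 100 random draws per size, with
percentile-bootstrap CIs (1000 resamples) over the per-draw AUCs.

## Part II: drug-response models

`fit_drug_model()` fits the Gaussian/L1 model per drug, dropping lines
with missing sensitivity for that drug only. Accuracy is leave-one-out R²:
each line predicted by a model trained on the other lines, with λ
re-selected inside every training set, and `R² = 1 − SSE/SST` over the
held-out predictions (negative values are possible and meaningful — the
model predicted worse than the mean). A `relambda = FALSE` fast path
reuses one panel-wide λ; it is cheaper but lets the selection see each
held-out line, and is off by default. Held-out predictions are computed in
a canonical line order (sorted ids), making the LOOCV results invariant to
how the panel's rows happen to be sorted.

The two-gene heatmap is deliberately descriptive: the two genes are the
largest-|weight| pair from a fit on *all* data (not cross-validated), and
the surface interpolates the *observed* sensitivities — linear barycentric
interpolation on a Delaunay triangulation inside the convex hull of the
observed points, nearest-observation fill outside. Interpolation (not
smoothing) means the surface passes exactly through every measurement.
The triangulation is built in the package (Bowyer–Watson); inputs with
fewer than 3 non-collinear points are rejected. Near-cocircular point sets
can make the triangulation ambiguous in degenerate configurations;
expression measurements in general position are unaffected.

## Part III: drug-pair search

A drug enters the compound classifier as a feature vector: its measured
sensitivity column, or its Part II model's predictions from expression
(`source = "predicted"`, the default for the search, since tying drug
behavior to markers is what makes the pair interpretable; `measured` is
available and is what the analysis scripts use when the interest is purely
in the achievable discrimination). With only two features, the pair model
is an *unpenalized* logistic GLM. Each pair is evaluated over 100 rounds
of stratified 90/10 subsampling; single-drug baselines are computed on the
identical splits, so "pair beats singles" is never an artifact of split
luck. Degenerate single-class test splits are redrawn (capped at 1000,
with the count reported); with stratified draws they essentially never
occur. Per-pair randomness is seeded by a hash of the unordered drug ids,
making the search symmetric in its arguments and reproducible
pair-by-pair.

Searching 74 drugs means 2701 pairs, and picking the maximum inflates the
winner's AUC above 0.5 even on pure noise. The package follows the
demonstration analysis in applying *no* multiple-comparison correction by
default, but exposes both the correction (`multiplicity_adjust()`,
Benjamini–Hochberg over per-pair permutation p-values) and the honest
yardstick for the winner (`pair_search_null_max()`, the permutation null
of the *maximum* pair AUC).

## The synthetic data

The generators produce the minimal structure the analyses assume, with
ground truth for recovery tests.

* `simulate_single_cells()`: log-scale expression, Gaussian within
  populations (per-gene baselines uniform on 4–8, within-class SD 1), a
  random subset of informative genes mean-shifted between populations by
  `effect_size` pooled SDs with random sign, and optional dropout to an
  assay floor of 0 mimicking a detection limit. Defaults (45 genes,
  90 + 90 cells, 10 informative genes, effect size 2) mirror a small
  curated single-cell PCR panel in which classification is demanding but
  feasible.
* `simulate_panel()`: 45 lines × 500 genes × 74 drugs by default — the
  gene count is a desk-scale stand-in for a genome-wide array; the line
  and drug counts mirror a real drug screen. Two latent factors `u`, `v`
  per line; subtype = `u > 0`; two designated genes carry the latents
  exactly and a 10-gene block loads partially on `u`, so the subtype axis
  is distributed across genes and ordinary drugs (sparse 5-gene signals,
  weights ±U(0.5, 1.5), noise SD 0.3) capture it only partially. The
  planted complementary pair reads `u + v` and `u − v`: each alone is a
  noisy subtype readout, their sum recovers `u` — a construction that
  guarantees a pair better than either single drug.

What passing tests on these data show — and what they do not: the
pipeline recovers planted structure (informative genes, sparse drug
supports, the complementary pair), its null calibration is correct, and
its CV machinery does not leak. They do not show that real single-cell
PCR data (zero-inflated, Ct-censored, non-Gaussian) or microarray panels
(correlated probe structure, batch effects) are this well behaved, nor
that any particular real drug is predictable from expression. One planted
interaction is worth knowing when testing: drugs whose random support
lands in the correlated subtype block have collinear predictors, so
*exact* support identification is ill-posed for them even without noise —
prediction accuracy is unaffected, but weight mass spreads across the
correlated genes.

## Numerical choices and degenerate inputs

* Penalized solutions are fit along a short warm-start path ending at the
  requested λ (single-λ coordinate descent is less reliable); convergence
  threshold 1e-10 for fits, 1e-7 inside CV.
* Separable data with λ = 0 terminate by iteration cap rather than
  diverging; predicted probabilities are clamped to
  [1e-12, 1 − 1e-12].
* Feature ranking breaks |weight| ties by input column order; zero-weight
  features sort last.
* Gene-count restrictions keep the retained genes in original column
  order, so k = (all genes) reproduces the unrestricted fit exactly —
  used as an internal consistency check in the tests.
* Bootstrap CIs are percentile intervals of the mean, 1000 resamples by
  default; a frozen-seed simulation in the tests checks ~94% coverage of
  a true mean at n = 40.
* Single-class label vectors, non-binary responses, non-finite values,
  ragged or non-numeric input files, and zero-variance responses all fail
  fast with located error messages rather than propagating.

## Problem sizes

The shipped analyses and tests run at the sizes stated above (180 cells ×
45 genes; 45 lines × 500 genes × 74 drugs; 100 permutations, 100
subsampling rounds, 100-seed recovery experiments with reduced panels
where a full-size repetition would add runtime without adding
information). These sizes were chosen as the smallest at which each
qualitative claim is stable across seeds; all of them are parameters, and
nothing in the implementation assumes them.

## Known limitations

* The expression model is Gaussian-on-log-scale; count-based single-cell
  models (negative binomial, library-size normalization) are out of scope.
* Only linear, non-interacting models are fitted; the pair framework
  assumes drugs act independently, so statistical complementarity — not
  pharmacological synergy — is what the search finds.
* Elastic-net mixing of the two penalties is deliberately not exposed;
  each stage uses the penalty suited to its predictor regime.
* The two-gene heatmap's gene choice is descriptive (all-data fit); treat
  it as visualization, not as a validated two-marker model.
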