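# chemoclass

An ideal cancer drug is a classifier: it should kill a cell if and only if
the cell is cancerous, deciding on the basis of measurable molecular
markers. `chemoclass` implements that framing as a three-part statistical
pipeline over gene-expression data:

1. **Defining the objective** — how well can cancerous and healthy single
   cells be discriminated from expression of a small marker panel? An
   L2-regularized logistic GLM is scored by ROC/AUC under nested 10-fold
   cross-validation (inner folds select the penalty strength λ, outer folds
   estimate generalization), with shuffle controls and learning curves over
   both the number of genes and the number of training cells.
2. **Characterizing the tools** — how much of a real drug's behavior do
   markers explain? Each drug's chemosensitivity across a cell-line panel,
   y = −log(GI50), is modeled as a sparse linear function of expression,
   `y = x'β + ε` with an L1 penalty `λ·Σ|β_k|`, scored by leave-one-out
   cross-validated R², plus two-gene sensitivity heatmaps.
3. **Optimizing treatment** — which *pair* of drugs, used together as a
   two-feature compound classifier `P(aggressive) = logistic(w₀ + w₁x_A +
   w₂x_B)`, separates two cell populations better than either drug alone?
   All D·(D−1)/2 pairs are evaluated with an unpenalized logistic GLM over
   100 rounds of stratified 90/10 subsampling, with bootstrap CIs.

Because the datasets this analysis style targets (single-cell PCR panels,
cell-line drug screens) are often not redistributable, the package ships
synthetic-data generators that reproduce their statistical structure — two
overlapping cell populations differing in a sparse gene subset, and a
drug-response panel with sparse linear gene signals, a latent subtype axis,
and an optionally planted complementary drug pair — so the whole pipeline
is testable end to end with known ground truth.

It is intended for computational biologists exploring classifier-based
views of drug action, and as a tested reference implementation of the
nested-CV / shuffle-control / subsampling machinery these analyses need.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data (`Rscript analysis/01_simulate_data.R`, then stages 02–05). A
condensed session:

```r
library(chemoclass)

# Part I: 45 genes, 90 healthy + 90 tumor cells, 10 informative genes
# shifted by 2 pooled SDs, 5% dropout
sim <- simulate_single_cells(effect_size = 2, dropout_rate = 0.05,
                             seed = 20140923)
scores <- nested_cv_scores(sim$data, seed = 20140924)
roc_and_auc(scores, sim$data$labels)$auc
#> [1] 0.994321
shuffle_control(sim$data, n_permutations = 100, seed = 20140924)$mean
#> [1] 0.4884296
```

An out-of-fold AUC of 0.994 against a shuffle-control chance level of
0.488 says the two populations are almost perfectly separable from the
marker panel, and that none of that separation is an artifact of the
pipeline (the permutation null sits at coin-flip level). Stage 03 shows
the same classifier trained on class-balanced subsets: mean held-out AUC
grows from 0.795 at 4 training cells to 0.991 at 80, with little gain
beyond — tens of cells are needed before marker count stops being the
bottleneck.

```r
# Part II: 45 lines x 500 genes x 74 drugs, 5-gene drug signals
panel <- simulate_panel(seed = 20140924)$panel
m <- fit_drug_model(panel, "drug_49", seed = 1)
as.numeric(m$loocv_r2)
#> [1] 0.9808004
```

A leave-one-out R² of 0.98 for this drug (each line predicted by a model
that never saw it, λ re-selected per training set) shows its response is
essentially a readout of a few genes; stage 04 finds the R²-vs-gene-count
curve reaches 90% of its plateau by about 5 genes, matching the planted
support size.

```r
# Part III: exhaustive pair search over all 2701 pairs of 74 drugs
tab <- search_pairs(panel, source = "measured", seed = 20140927)
tab$pair <- paste(tab$drug_a, tab$drug_b, sep = " + ")
tab$pair[1]
#> [1] "drug_01 + drug_02"
round(tab[1, c("pair_auc", "auc_a", "auc_b")], 3)
#>   pair_auc auc_a auc_b
#> 1    0.988 0.797 0.894
```

The winning pair is the planted complementary pair: each drug alone reads
the subtype axis only noisily (AUC 0.80 and 0.89), but their two-feature
compound classifier reaches AUC 0.99 because the second drug cancels the
latent nuisance factor the first one picks up. By default no
multiple-comparison correction is applied across pairs (use
`multiplicity_adjust(..., "benjamini_hochberg")` to opt in), and
`pair_search_null_max()` exposes the selection-inflated permutation null
the winner should be compared against.

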