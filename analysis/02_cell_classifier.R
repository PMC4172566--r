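#!/usr/bin/env Rscript
# Stage 2 — Part I: can gene expression discriminate tumor from healthy
# cells at the single-cell level?
#
# Fits the L2-regularized logistic classifier under nested 10-fold CV,
# reports the out-of-fold ROC/AUC against a 100-permutation shuffle
# control, and traces discriminability as a function of the number of genes
# considered (ranked per training fold by weight magnitude).

suppressMessages(library(chemoclass))

seed <- 20140924
data_dir <- "results/data"
out_dir <- "results/part1"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

expr <- read_matrix(file.path(data_dir, "cells_expression.tsv"))
labels <- read_labels(file.path(data_dir, "cells_labels.tsv"),
                      rownames(expr))
cells <- labeled_cell_set(expr, labels)

message("Nested 10-fold CV scoring ...")
scores <- nested_cv_scores(cells, outer_folds = 10, inner_folds = 10,
                           penalty_kind = "l2", seed = seed)
roc <- roc_and_auc(scores, cells$labels)
message(sprintf("out-of-fold AUC: %.3f", roc$auc))

write.table(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                       tpr = roc$tpr),
            file.path(out_dir, "roc_curve.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("Shuffle control (100 permutations) ...")
null <- shuffle_control(cells, n_permutations = 100, seed = seed)
message(sprintf("chance AUC: %.3f [%.3f, %.3f]",
                null$mean, null$q025, null$q975))

message("Gene-count curve ...")
curve <- gene_count_curve(cells, gene_counts = c(1:15, 20, 30, 45),
                          outer_folds = 10, inner_folds = 10,
                          penalty_kind = "l2", seed = seed)
write.table(curve, file.path(out_dir, "gene_count_curve.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
plateau <- max(curve$auc)
k_sat <- min(curve$k[curve$auc >= 0.95 * plateau])
message(sprintf("AUC reaches 95%% of its plateau (%.3f) by k = %d genes",
                plateau, k_sat))

summary <- data.frame(
  auc = roc$auc, chance_mean = null$mean, chance_q025 = null$q025,
  chance_q975 = null$q975, plateau_auc = plateau, k_saturation = k_sat)
write.table(summary, file.path(out_dir, "summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_manifest(file.path(out_dir, "manifest.json"), "classify",
               parameters = list(outer_folds = 10, inner_folds = 10,
                                 penalty = "l2", n_permutations = 100),
               seed = seed,
               inputs = file.path(data_dir,
                                  c("cells_expression.tsv",
                                    "cells_labels.tsv")))
message("Wrote ", out_dir)
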