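#!/usr/bin/env Rscript
# Stage 3 — Part I continued: more cells or more genes?
#
# Subsamples class-balanced training sets of increasing size (100 random
# draws each), evaluating the held-out AUC as a function of both the
# training-set size and the number of genes considered — the two axes a
# measurement budget trades off.

suppressMessages(library(chemoclass))

seed <- 20140925
data_dir <- "results/data"
out_dir <- "results/part1"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

expr <- read_matrix(file.path(data_dir, "cells_expression.tsv"))
labels <- read_labels(file.path(data_dir, "cells_labels.tsv"),
                      rownames(expr))
cells <- labeled_cell_set(expr, labels)

train_sizes <- c(4, 10, 20, 40, 80, 160)
message("Cell-count curves at sizes ", paste(train_sizes, collapse = ", "),
        " (100 iterations each) ...")
curve <- cell_count_curve(cells, train_sizes = train_sizes,
                          n_iterations = 100,
                          gene_counts = c(2, 5, 10, 45), seed = seed)
write.table(curve, file.path(out_dir, "cell_count_curve.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

full <- curve[curve$k == 45, ]
message("mean AUC at full gene count, by training size:")
for (i in seq_len(nrow(full))) {
  message(sprintf("  n = %3d cells: %.3f [%.3f, %.3f]",
                  full$train_size[i], full$mean_auc[i], full$ci_low[i],
                  full$ci_high[i]))
}
gain <- diff(full$mean_auc)
sat <- if (any(gain < 0.005)) {
  full$train_size[which(gain < 0.005)[1] + 1]
} else {
  max(train_sizes)
}
message("improvement becomes marginal (< 0.005 AUC per step) around n = ",
        sat, " training cells")

write_manifest(file.path(out_dir, "learning_manifest.json"), "cell-curve",
               parameters = list(train_sizes = train_sizes,
                                 n_iterations = 100,
                                 gene_counts = c(2, 5, 10, 45)),
               seed = seed,
               inputs = file.path(data_dir,
                                  c("cells_expression.tsv",
                                    "cells_labels.tsv")))
message("Wrote ", out_dir)
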