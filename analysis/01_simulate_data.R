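#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study datasets.
#
# Two datasets mirror the shapes of the real inputs the pipeline is built
# for: a single-cell expression set (45 genes, 90 healthy + 90 tumor cells,
# 10 informative genes at effect size 2 pooled SDs) and a cell-line panel
# (45 lines x 500 genes x 74 drugs, sparse 5-gene drug signals, latent
# subtype axis, one planted complementary drug pair). Everything downstream
# reads the delimited files written here.

suppressMessages(library(chemoclass))

seed <- 20140923
out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("Simulating the single-cell set (45 genes, 90 + 90 cells) ...")
sc <- simulate_single_cells(n_healthy = 90, n_tumor = 90, n_genes = 45,
                            n_informative = 10, effect_size = 2,
                            dropout_rate = 0.05, seed = seed)
write_matrix(sc$data$expression, file.path(out_dir, "cells_expression.tsv"))
write_labels(setNames(sc$data$labels, rownames(sc$data$expression)),
             file.path(out_dir, "cells_labels.tsv"))
jsonlite::write_json(sc$truth, file.path(out_dir, "cells_truth.json"),
                     auto_unbox = TRUE, digits = NA)

message("Simulating the cell-line panel (45 lines, 500 genes, 74 drugs) ...")
panel <- simulate_panel(n_lines = 45, n_genes = 500, n_drugs = 74,
                        support_size = 5, noise_sd = 0.3,
                        complementary_pair = TRUE, seed = seed + 1)
write_matrix(panel$panel$expression,
             file.path(out_dir, "panel_expression.tsv"))
write_matrix(panel$panel$sensitivity,
             file.path(out_dir, "panel_sensitivity.tsv"))
write_labels(setNames(panel$panel$subtype_labels,
                      rownames(panel$panel$expression)),
             file.path(out_dir, "panel_subtypes.tsv"))
jsonlite::write_json(
  list(planted_pair = panel$truth$planted_pair,
       latent_genes = panel$truth$latent_genes,
       noise_sd = panel$truth$noise_sd),
  file.path(out_dir, "panel_truth.json"), auto_unbox = TRUE, digits = NA)

write_manifest(file.path(out_dir, "manifest.json"), "simulate",
               parameters = list(single_cell = list(n_genes = 45,
                                                    cells = 180,
                                                    effect_size = 2,
                                                    dropout_rate = 0.05),
                                 panel = list(n_lines = 45, n_genes = 500,
                                              n_drugs = 74,
                                              support_size = 5,
                                              noise_sd = 0.3)),
               seed = seed)
message("Wrote ", out_dir)
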