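#!/usr/bin/env Rscript
# Stage 4 — Part II: do drugs act as classifiers over gene expression?
#
# Models each drug's chemosensitivity (-log GI50) across the panel as an
# L1-penalized linear function of expression, scores each model by
# leave-one-out R2, traces accuracy against the number of genes for a
# focal drug, and writes its two-gene sensitivity heatmap.

suppressMessages(library(chemoclass))

seed <- 20140926
data_dir <- "results/data"
out_dir <- "results/part2"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

expr <- read_matrix(file.path(data_dir, "panel_expression.tsv"))
sens <- read_matrix(file.path(data_dir, "panel_sensitivity.tsv"))
subtypes <- read_labels(file.path(data_dir, "panel_subtypes.tsv"),
                        rownames(expr))
panel <- cell_line_panel(expr, sens, subtypes)

# LOOCV R2 for a representative slice of the drug panel (the full 74-drug
# sweep is identical code, just longer)
drugs <- colnames(sens)[seq(1, ncol(sens), by = 8)]
message("LOOCV R2 for ", length(drugs), " drugs ...")
r2 <- vapply(drugs, function(d) {
  as.numeric(loocv_r2(panel, d, seed = seed))
}, 0)
r2_tab <- data.frame(drug = drugs, loocv_r2 = r2)
r2_tab <- r2_tab[order(-r2_tab$loocv_r2), ]
write.table(r2_tab, file.path(out_dir, "drug_r2.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("best-predicted drug: ", r2_tab$drug[1],
        sprintf(" (R2 = %.3f)", r2_tab$loocv_r2[1]))

focal <- r2_tab$drug[1]
message("gene-count curve for ", focal, " ...")
curve <- r2_vs_gene_count(panel, focal, gene_counts = c(1, 2, 3, 5, 8, 12,
                                                        20, 500),
                          seed = seed)
write.table(curve, file.path(out_dir, "r2_vs_gene_count.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
k_sat <- min(curve$k[curve$r2 >= 0.9 * max(curve$r2)])
message("R2 reaches 90% of its plateau by k = ", k_sat, " genes")

message("two-gene sensitivity heatmap for ", focal, " ...")
hm <- two_gene_heatmap(panel, focal, resolution = 100, seed = seed)
message("heatmap genes: ", hm$gene_x, " x ", hm$gene_y)
heat_df <- data.frame(hm$heat)
colnames(heat_df) <- sprintf("y%03d", seq_along(hm$grid_y))
write.table(cbind(grid_x = hm$grid_x, heat_df),
            file.path(out_dir, paste0("heatmap_", focal, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)

write_manifest(file.path(out_dir, "manifest.json"), "drugfit",
               parameters = list(drugs = drugs, focal = focal,
                                 resolution = 100),
               seed = seed,
               inputs = file.path(data_dir,
                                  c("panel_expression.tsv",
                                    "panel_sensitivity.tsv")))
message("Wrote ", out_dir)
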