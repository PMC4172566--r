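# Desk-scale panels (fewer genes/drugs than the defaults) keep the LOOCV
# loops fast; the acceptance suite runs the full-size configurations.

make_panel <- function(noise_sd = 0, n_genes = 60, n_drugs = 4, seed = 202) {
  simulate_panel(n_lines = 30, n_genes = n_genes, n_drugs = n_drugs,
                 support_size = 3, noise_sd = noise_sd,
                 complementary_pair = FALSE, seed = seed)
}

test_that("a noise-free sparse drug is recovered with high LOOCV R2", {
  sim <- make_panel(noise_sd = 0)
  drug <- colnames(sim$panel$sensitivity)[3]
  model <- fit_drug_model(sim$panel, drug, seed = 5)
  expect_s3_class(model$glm, "glm_model")
  # support recovery: nonzero weights only on the true support genes,
  # at most one false positive
  support <- rownames(sim$truth$weights)[sim$truth$weights[, drug] != 0]
  nonzero <- model$glm$feature_ids[model$glm$weights != 0]
  expect_lte(length(setdiff(nonzero, support)), 1)
  expect_setequal(intersect(nonzero, support), support)
  expect_gte(model$loocv_r2, 0.95)
})

test_that("pure-noise sensitivity is not predictable", {
  sim <- make_panel(noise_sd = 0, seed = 303)
  panel <- sim$panel
  set.seed(99)
  panel$sensitivity[, 2] <- rnorm(nrow(panel$sensitivity))
  r2 <- loocv_r2(panel, colnames(panel$sensitivity)[2], seed = 5)
  expect_lte(as.numeric(r2), 0.1)
})

test_that("drug-model fitting is deterministic and validates its inputs", {
  sim <- make_panel(noise_sd = 0.2)
  drug <- colnames(sim$panel$sensitivity)[1]
  m1 <- fit_drug_model(sim$panel, drug, seed = 7, compute_loocv = FALSE)
  m2 <- fit_drug_model(sim$panel, drug, seed = 7, compute_loocv = FALSE)
  expect_identical(m1$glm$weights, m2$glm$weights)
  expect_error(fit_drug_model(sim$panel, "no_such_drug"), "lookup error")
  few <- sim$panel
  few$sensitivity[10:30, drug] <- NA
  expect_error(fit_drug_model(few, drug), "sample-size error")
})

test_that("LOOCV R2 equals its definitional identity on the emitted predictions", {
  sim <- make_panel(noise_sd = 0.3)
  drug <- colnames(sim$panel$sensitivity)[2]
  r2 <- loocv_r2(sim$panel, drug, seed = 11)
  preds <- attr(r2, "predictions")
  y <- sim$panel$sensitivity[, drug]
  # recompute 1 - SSE/SST from the emitted per-line predictions
  expect_equal(as.numeric(r2),
               1 - sum((y - preds)^2) / sum((y - mean(y))^2))
  # invariance to line ordering
  perm <- sample(nrow(sim$panel$expression))
  panel_perm <- cell_line_panel(sim$panel$expression[perm, ],
                                sim$panel$sensitivity[perm, ],
                                sim$panel$subtype_labels[perm])
  r2p <- loocv_r2(panel_perm, drug, seed = 11)
  expect_equal(as.numeric(r2p), as.numeric(r2), tolerance = 1e-8)
  # zero-variance sensitivity is undefined
  flat <- sim$panel
  flat$sensitivity[, drug] <- 5
  expect_error(loocv_r2(flat, drug), "undefined-R2")
})

test_that("gene-count curve matches the unrestricted LOOCV at k = all genes", {
  sim <- make_panel(noise_sd = 0, n_genes = 30)
  drug <- colnames(sim$panel$sensitivity)[1]
  p <- ncol(sim$panel$expression)
  curve <- r2_vs_gene_count(sim$panel, drug, gene_counts = c(2, 4, p),
                            seed = 13, n_boot = 200)
  r2_full <- loocv_r2(sim$panel, drug, seed = 13)
  expect_equal(curve$r2[curve$k == p], as.numeric(r2_full))
  # sparse truth (3 genes): near-plateau accuracy by k = 4
  expect_gte(curve$r2[curve$k == 4], 0.9 * curve$r2[curve$k == p])
  expect_error(r2_vs_gene_count(sim$panel, drug, gene_counts = integer(0)),
               "configuration error")
  expect_error(r2_vs_gene_count(sim$panel, drug, gene_counts = 0),
               "configuration error")
})

test_that("a duplicated gene column leaves LOOCV R2 essentially unchanged", {
  sim <- make_panel(noise_sd = 0.2, n_genes = 40)
  drug <- colnames(sim$panel$sensitivity)[1]
  r2_base <- as.numeric(loocv_r2(sim$panel, drug, seed = 17))
  expr2 <- cbind(sim$panel$expression,
                 dup_gene = sim$panel$expression[, 1])
  panel2 <- cell_line_panel(expr2, sim$panel$sensitivity,
                            sim$panel$subtype_labels)
  r2_dup <- as.numeric(loocv_r2(panel2, drug, seed = 17))
  expect_lt(abs(r2_dup - r2_base), 0.05)
})

test_that("planted genes rank highly across seeds (L1 support recovery)", {
  # noise SD at 25% of the signal scale; planted support should appear
  # within the top 2 * support_size ranked genes in >= 90% of runs
  hits <- 0
  n_runs <- 25
  for (i in seq_len(n_runs)) {
    sim <- simulate_panel(n_lines = 40, n_genes = 60, n_drugs = 1,
                          support_size = 3, noise_sd = 0.25,
                          complementary_pair = FALSE, seed = 400 + i)
    drug <- colnames(sim$panel$sensitivity)[1]
    m <- fit_drug_model(sim$panel, drug, seed = i, compute_loocv = FALSE)
    support <- rownames(sim$truth$weights)[sim$truth$weights[, drug] != 0]
    top <- rank_features(m$glm)[1:6]
    if (all(support %in% top)) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.9)
})
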