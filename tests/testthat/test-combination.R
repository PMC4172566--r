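make_comp_panel <- function(seed = 501, n_lines = 45, n_drugs = 6) {
  simulate_panel(n_lines = n_lines, n_genes = 50, n_drugs = n_drugs,
                 support_size = 3, noise_sd = 0.3,
                 complementary_pair = TRUE, seed = seed)
}

test_that("drug_feature passes measured columns through and guards predicted", {
  sim <- make_comp_panel()
  drug <- colnames(sim$panel$sensitivity)[1]
  f <- drug_feature(sim$panel, drug, source = "measured")
  expect_identical(f$values, unname(sim$panel$sensitivity[, drug]))
  expect_error(drug_feature(sim$panel, drug, source = "predicted"),
               "lookup error")
  expect_error(drug_feature(sim$panel, "nope", source = "measured"),
               "lookup error")
  # predicted features from a noise-free drug track the measured column
  sim0 <- simulate_panel(n_lines = 40, n_genes = 50, n_drugs = 3,
                         support_size = 3, noise_sd = 0,
                         complementary_pair = FALSE, seed = 502)
  d0 <- colnames(sim0$panel$sensitivity)[1]
  m0 <- fit_drug_model(sim0$panel, d0, seed = 3, compute_loocv = FALSE)
  fp <- drug_feature(sim0$panel, d0, source = "predicted", model = m0)
  expect_gte(cor(fp$values, sim0$panel$sensitivity[, d0]), 0.99)
  # model for the wrong drug is rejected, not silently used
  expect_error(drug_feature(sim0$panel, colnames(sim0$panel$sensitivity)[2],
                            source = "predicted", model = m0),
               "lookup error")
})

test_that("a redundant second feature adds nothing over the first drug", {
  sim <- make_comp_panel()
  x <- drug_feature(sim$panel, "drug_01", source = "measured")
  res <- evaluate_pair(x, x, sim$panel$subtype_labels, n_rounds = 50,
                       seed = 9)
  expect_gte(res$pair_auc, res$pair_ci[["low"]] - 0.02)
  expect_lte(res$pair_auc, res$pair_ci[["high"]] + 0.02)
  expect_lt(abs(res$pair_auc - res$auc_a), 0.05)
})

test_that("complementary drugs beat either drug alone", {
  sim <- make_comp_panel(seed = 503)
  xa <- drug_feature(sim$panel, sim$truth$planted_pair[1],
                     source = "measured")
  xb <- drug_feature(sim$panel, sim$truth$planted_pair[2],
                     source = "measured")
  res <- evaluate_pair(xa, xb, sim$panel$subtype_labels, n_rounds = 100,
                       seed = 10)
  expect_gt(res$pair_auc, max(res$auc_a, res$auc_b) + 0.05)
})

test_that("permuted labels bring the pair AUC back to chance", {
  sim <- make_comp_panel(seed = 504)
  xa <- drug_feature(sim$panel, "drug_01", source = "measured")
  xb <- drug_feature(sim$panel, "drug_02", source = "measured")
  set.seed(20)
  perm <- sample(sim$panel$subtype_labels)
  res <- evaluate_pair(xa, xb, perm, n_rounds = 100, seed = 10)
  expect_gt(res$pair_auc, 0.30)
  expect_lt(res$pair_auc, 0.70)
})

test_that("search_pairs enumerates all unordered pairs and ranks the winner", {
  sim <- make_comp_panel(seed = 505, n_drugs = 6)
  tab <- search_pairs(sim$panel, source = "measured", n_rounds = 30,
                      seed = 12)
  expect_equal(nrow(tab), choose(6, 2))
  expect_true(all(diff(tab$pair_auc) <= 0))
  # the planted complementary pair wins on this construction
  expect_setequal(c(tab$drug_a[1], tab$drug_b[1]), sim$truth$planted_pair)
  # the winner's pair AUC is at least its own single-drug AUCs
  expect_gte(tab$pair_auc[1], max(tab$auc_a[1], tab$auc_b[1]))
})

test_that("search_pairs is symmetric under drug-column reversal", {
  sim <- make_comp_panel(seed = 506, n_drugs = 4)
  tab1 <- search_pairs(sim$panel, source = "measured", n_rounds = 20,
                       seed = 15)
  rev_panel <- cell_line_panel(sim$panel$expression,
                               sim$panel$sensitivity[, 4:1],
                               sim$panel$subtype_labels)
  tab2 <- search_pairs(rev_panel, source = "measured", n_rounds = 20,
                       seed = 15)
  key1 <- paste(pmin(tab1$drug_a, tab1$drug_b),
                pmax(tab1$drug_a, tab1$drug_b))
  key2 <- paste(pmin(tab2$drug_a, tab2$drug_b),
                pmax(tab2$drug_a, tab2$drug_b))
  expect_setequal(key1, key2)
  expect_equal(tab2$pair_auc[match(key1, key2)], tab1$pair_auc,
               tolerance = 1e-12)
})

test_that("the maximum pair AUC under label permutation sits above 0.5", {
  # selection over many pairs inflates the null maximum: users must compare
  # the winner against this null, not against 0.5
  sim <- simulate_panel(n_lines = 40, n_genes = 30, n_drugs = 6,
                        support_size = 3, noise_sd = 0.3,
                        complementary_pair = FALSE, seed = 507)
  nulls <- pair_search_null_max(sim$panel, source = "measured",
                                n_rounds = 15, n_perm = 10, seed = 16)
  expect_length(nulls, 10)
  expect_gt(mean(nulls), 0.5)
})

test_that("multiplicity adjustment is a faithful pass-through or exact BH", {
  tab <- data.frame(drug_a = letters[1:4], drug_b = letters[2:5],
                    pair_auc = c(0.9, 0.8, 0.7, 0.6),
                    p_value = c(0.01, 0.04, 0.20, 0.20))
  expect_identical(multiplicity_adjust(tab, "none"), tab)
  adj <- multiplicity_adjust(tab, "benjamini_hochberg")
  expect_equal(adj$q_value, oracle_bh(tab$p_value))
  # equal p-values map to that same q-value
  flat <- tab
  flat$p_value <- rep(0.07, 4)
  expect_equal(multiplicity_adjust(flat, "benjamini_hochberg")$q_value,
               rep(0.07, 4))
  # randomized BH oracle comparison
  set.seed(40)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    tabr <- data.frame(p_value = p)
    expect_equal(multiplicity_adjust(tabr, "benjamini_hochberg")$q_value,
                 oracle_bh(p))
  }
  bad <- tab
  bad$p_value <- NULL
  expect_error(multiplicity_adjust(bad, "benjamini_hochberg"),
               "state error")
})

test_that("forcing drug B's weight to zero reduces to drug A's classifier", {
  # on identical splits, the pair evaluated with the second feature zeroed
  # must give exactly the single-feature AUC
  sim <- make_comp_panel(seed = 508)
  xa <- sim$panel$sensitivity[, 1]
  xb_zero <- rep(0, length(xa))  # constant feature gets weight NA -> 0
  res <- evaluate_pair(xa, xb_zero, sim$panel$subtype_labels,
                       n_rounds = 30, seed = 21)
  expect_equal(res$pair_auc, res$auc_a, tolerance = 1e-12)
})
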