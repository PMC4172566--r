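#' Simulate a labeled two-population single-cell expression set
#'
#' Generates log-scale expression for two overlapping cell populations
#' (healthy and tumor) that differ only in a sparse subset of informative
#' genes, shifted by `effect_size` pooled standard deviations. An optional
#' dropout step replaces values by the assay floor, mimicking the detection
#' limit of single-cell PCR. The emitted set is fully determined by `seed`.
#'
#' @param n_healthy,n_tumor Cells per population (default 90 + 90).
#' @param n_genes Genes measured per cell (default 45).
#' @param n_informative Genes that differ between the populations
#'   (default 10).
#' @param effect_size Between-population mean shift of each informative
#'   gene, in pooled-SD units (default 2).
#' @param dropout_rate Probability each value is replaced by the assay
#'   floor (default 0).
#' @param noise_sd Within-population SD of log expression (default 1).
#' @param seed Integer seed.
#' @return List with `data` (a [labeled_cell_set()]) and `truth`
#'   (informative gene ids, per-gene shifts, baselines).
#' @export
simulate_single_cells <- function(n_healthy = 90L, n_tumor = 90L,
                                  n_genes = 45L, n_informative = 10L,
                                  effect_size = 2, dropout_rate = 0,
                                  noise_sd = 1, seed = 1L) {
  if (n_informative > n_genes) {
    stop("configuration error: n_informative exceeds n_genes")
  }
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop("configuration error: dropout_rate must lie in [0, 1]")
  }
  if (n_healthy < 1 || n_tumor < 1 || noise_sd < 0 || effect_size < 0) {
    stop("configuration error: invalid simulation parameters")
  }
  n <- n_healthy + n_tumor
  gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
  cell_ids <- sprintf("cell_%03d", seq_len(n))
  labels <- c(rep(0L, n_healthy), rep(1L, n_tumor))
  with_seed(seed, {
    baseline <- stats::runif(n_genes, 4, 8)
    informative <- sort(sample(n_genes, n_informative))
    shift_sign <- sample(c(-1, 1), n_informative, replace = TRUE)
    expr <- matrix(stats::rnorm(n * n_genes, sd = noise_sd), n, n_genes)
    expr <- sweep(expr, 2, baseline, "+")
    # shift informative genes in tumor cells by effect_size pooled SDs
    shift <- numeric(n_genes)
    shift[informative] <- shift_sign * effect_size * noise_sd
    expr[labels == 1, ] <- sweep(expr[labels == 1, , drop = FALSE], 2,
                                 shift, "+")
    if (dropout_rate > 0) {
      floor_value <- 0
      drop <- matrix(stats::runif(n * n_genes) < dropout_rate, n, n_genes)
      expr[drop] <- floor_value
    }
    dimnames(expr) <- list(cell_ids, gene_ids)
    list(
      data = labeled_cell_set(expr, labels),
      truth = list(informative_genes = gene_ids[informative],
                   shift = stats::setNames(shift, gene_ids),
                   baseline = stats::setNames(baseline, gene_ids),
                   effect_size = effect_size, noise_sd = noise_sd)
    )
  })
}

#' Simulate a cell-line panel with sparse linear drug-response structure
#'
#' Each line carries two latent factors `u` and `v`; the binary subtype is
#' `u > 0`. Expression is standard-normal log-scale noise, except that two
#' designated genes carry the latents exactly and a block of genes loads
#' partially on `u` (so the subtype axis is distributed across the
#' transcriptome and individual drugs capture it only partially). Each
#' drug's sensitivity (-log GI50) is a sparse linear combination of
#' `support_size` genes plus gaussian noise. When `complementary_pair` is
#' set, the first two drugs are planted to read `u + v` and `u - v`: each
#' alone is a noisy subtype readout, together they recover `u` — a pair
#' guaranteed to be more informative than either drug alone.
#'
#' @param n_lines Cell lines (default 45).
#' @param n_genes Genes (default 500; a desk-scale stand-in for a
#'   genome-wide array).
#' @param n_drugs Drugs (default 74).
#' @param support_size Genes driving each drug (default 5).
#' @param noise_sd SD of the additive sensitivity noise (default 0.3).
#' @param subtype_effect Loading of the subtype-axis gene block on `u`
#'   (default 0.5).
#' @param n_subtype_genes Genes in the subtype-axis block (default 10).
#' @param complementary_pair Plant the complementary drug pair
#'   (default `TRUE`).
#' @param seed Integer seed.
#' @return List with `panel` (a [cell_line_panel()]) and `truth` (latent
#'   factors, subtype labels, per-drug true weight vectors, the planted
#'   pair's drug ids, the latent-carrying gene ids).
#' @export
simulate_panel <- function(n_lines = 45L, n_genes = 500L, n_drugs = 74L,
                           support_size = 5L, noise_sd = 0.3,
                           subtype_effect = 0.5, n_subtype_genes = 10L,
                           complementary_pair = TRUE, seed = 1L) {
  if (support_size > n_genes) {
    stop("configuration error: support_size exceeds n_genes")
  }
  if (n_lines < 4) stop("configuration error: need at least 4 lines")
  if (n_genes < 2 + n_subtype_genes) {
    stop("configuration error: too few genes for the latent structure")
  }
  if (noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  line_ids <- sprintf("line_%02d", seq_len(n_lines))
  drug_ids <- sprintf("drug_%02d", seq_len(n_drugs))
  with_seed(seed, {
    u <- stats::rnorm(n_lines)
    v <- stats::rnorm(n_lines)
    expr <- matrix(stats::rnorm(n_lines * n_genes), n_lines, n_genes)
    # genes 1 and 2 carry the latents exactly; the next block loads on u
    expr[, 1] <- u
    expr[, 2] <- v
    block <- 2 + seq_len(n_subtype_genes)
    loading <- stats::runif(n_subtype_genes, 0.5, 1) * subtype_effect
    expr[, block] <- expr[, block] + outer(u, loading)
    dimnames(expr) <- list(line_ids, gene_ids)

    true_w <- matrix(0, n_genes, n_drugs,
                     dimnames = list(gene_ids, drug_ids))
    sens <- matrix(NA_real_, n_lines, n_drugs,
                   dimnames = list(line_ids, drug_ids))
    planted <- character(0)
    for (j in seq_len(n_drugs)) {
      if (complementary_pair && j <= 2) {
        s <- if (j == 1) 1 else -1
        true_w[1, j] <- 1   # gene_0001 = u
        true_w[2, j] <- s   # gene_0002 = v, read with opposite signs
      } else {
        supp <- sample(n_genes, support_size)
        true_w[supp, j] <- sample(c(-1, 1), support_size, replace = TRUE) *
          stats::runif(support_size, 0.5, 1.5)
      }
      sens[, j] <- drop(expr %*% true_w[, j]) +
        stats::rnorm(n_lines, sd = noise_sd)
    }
    if (complementary_pair) planted <- drug_ids[1:2]
    subtype <- as.integer(u > 0)
    if (length(unique(subtype)) < 2) {
      # pathological tiny-n draw; flip the most extreme line
      subtype[which.min(abs(u))] <- 1L - subtype[which.min(abs(u))]
    }
    list(
      panel = cell_line_panel(expr, sens, subtype),
      truth = list(u = u, v = v, subtype = subtype,
                   weights = true_w,
                   planted_pair = planted,
                   latent_genes = gene_ids[1:2],
                   subtype_genes = gene_ids[block],
                   noise_sd = noise_sd)
    )
  })
}
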