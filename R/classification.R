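#' Labeled single-cell expression set
#'
#' Bundles a cells x genes expression matrix with binary cell-state labels
#' (0 = healthy, 1 = cancer).
#'
#' @param expression Numeric matrix, cells x genes, with row (cell) and
#'   column (gene) names.
#' @param labels Binary vector, one per cell; named vectors are re-aligned
#'   to the expression row order.
#' @return An object of class `labeled_cell_set`.
#' @export
labeled_cell_set <- function(expression, labels) {
  expression <- check_matrix(expression)
  if (!is.null(names(labels)) && !is.null(rownames(expression))) {
    if (!setequal(names(labels), rownames(expression))) {
      stop("labels do not cover the expression samples")
    }
    labels <- labels[rownames(expression)]
  }
  if (length(labels) != nrow(expression)) {
    stop("labels length must equal the cell count")
  }
  check_binary(labels)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present")
  }
  structure(list(expression = expression, labels = as.integer(labels)),
            class = "labeled_cell_set")
}

#' Out-of-fold classifier scores under nested cross-validation
#'
#' Stratified outer folds estimate generalization; within each outer
#' training split the penalty strength is chosen by inner cross-validation
#' only, so no cell's score ever depends on a model that saw that cell.
#'
#' @param data A [labeled_cell_set()].
#' @param outer_folds,inner_folds Fold counts (default 10 each).
#' @param penalty_kind `"l2"` (default, appropriate when many markers may
#'   carry signal) or `"l1"`.
#' @param seed Integer seed controlling all fold assignments.
#' @param gene_subset Optional character vector restricting the design to
#'   these genes (used by the learning-curve machinery).
#' @return Numeric vector of out-of-fold probability scores, one per cell,
#'   in the input cell order; the outer fold assignment is attached as
#'   attribute `"fold"`.
#' @export
nested_cv_scores <- function(data, outer_folds = 10L, inner_folds = 10L,
                             penalty_kind = c("l2", "l1"), seed = 1L,
                             gene_subset = NULL) {
  stopifnot(inherits(data, "labeled_cell_set"))
  penalty_kind <- match.arg(penalty_kind)
  X <- data$expression
  if (!is.null(gene_subset)) X <- X[, gene_subset, drop = FALSE]
  y <- data$labels
  if (min(table(y)) < outer_folds) {
    stop("stratification error: a class has fewer cells than outer folds")
  }
  fold <- make_folds(y, outer_folds, derive_seed(seed, 1))
  scores <- numeric(length(y))
  for (f in seq_len(outer_folds)) {
    tr <- fold != f
    lam <- select_lambda_cv(X[tr, , drop = FALSE], y[tr],
                            family = "bernoulli",
                            penalty_kind = penalty_kind,
                            n_folds = inner_folds,
                            seed = derive_seed(seed, 100 + f))
    model <- fit_glm(X[tr, , drop = FALSE], y[tr], family = "bernoulli",
                     penalty = penalty_spec(penalty_kind, lam))
    scores[!tr] <- predict(model, X[!tr, , drop = FALSE])
  }
  names(scores) <- rownames(data$expression)
  attr(scores, "fold") <- fold
  scores
}

#' Shuffle control: permutation null distribution of the nested-CV AUC
#'
#' Re-runs the full nested cross-validation scoring on label-permuted data
#' for each permutation, giving the chance-level AUC distribution. A sound
#' classifier pipeline centers this null on 0.5.
#'
#' @inheritParams nested_cv_scores
#' @param n_permutations Number of label permutations (>= 20; default 100).
#' @return List with `mean`, `q025`, `q975` of the null AUCs and the full
#'   vector `aucs`.
#' @export
shuffle_control <- function(data, n_permutations = 100L, seed = 1L,
                            outer_folds = 10L, inner_folds = 10L,
                            penalty_kind = "l2") {
  stopifnot(inherits(data, "labeled_cell_set"))
  if (n_permutations < 20) {
    stop("configuration error: need at least 20 permutations")
  }
  aucs <- vapply(seq_len(n_permutations), function(p) {
    sp <- derive_seed(seed, 1000 + p)
    perm <- with_seed(sp, sample(data$labels))
    pdata <- data
    pdata$labels <- perm
    s <- nested_cv_scores(pdata, outer_folds, inner_folds, penalty_kind,
                          seed = sp)
    auc_mw(s, perm)
  }, 0)
  list(mean = mean(aucs),
       q025 = unname(stats::quantile(aucs, 0.025)),
       q975 = unname(stats::quantile(aucs, 0.975)),
       aucs = aucs)
}

# Rank genes on an outer training split: inner-CV lambda, one fit, order by
# |standardized weight|.
rank_genes_on_split <- function(X, y, inner_folds, penalty_kind, seed) {
  lam <- select_lambda_cv(X, y, family = "bernoulli",
                          penalty_kind = penalty_kind,
                          n_folds = inner_folds, seed = seed)
  model <- fit_glm(X, y, family = "bernoulli",
                   penalty = penalty_spec(penalty_kind, lam))
  rank_features(model)
}

#' Discriminability as a function of the number of genes
#'
#' For each gene count k, restricts the design to the top-k genes — ranked
#' by weight magnitude on each outer training split, so the ranking never
#' sees the held-out cells — recomputes the nested-CV out-of-fold scores,
#' and reports the AUC with a bootstrap confidence interval (resampling
#' cells) and a chance level from permuting labels against the same
#' out-of-fold scores.
#'
#' @inheritParams nested_cv_scores
#' @param max_genes Largest gene count; `gene_counts` defaults to
#'   `1:max_genes`.
#' @param gene_counts Optional explicit vector of gene counts.
#' @param n_boot Bootstrap resamples for the CI (default 1000).
#' @param n_null Label permutations for the per-k chance line (default 100).
#' @return A data.frame with columns `k`, `auc`, `ci_low`, `ci_high`,
#'   `chance_auc`.
#' @export
gene_count_curve <- function(data, max_genes = NULL, gene_counts = NULL,
                             outer_folds = 10L, inner_folds = 10L,
                             penalty_kind = "l2", seed = 1L,
                             n_boot = 1000L, n_null = 100L) {
  stopifnot(inherits(data, "labeled_cell_set"))
  p <- ncol(data$expression)
  if (is.null(gene_counts)) {
    if (is.null(max_genes)) max_genes <- p
    gene_counts <- seq_len(max_genes)
  }
  if (any(gene_counts < 1) || any(gene_counts > p)) {
    stop("configuration error: gene counts must lie in 1..", p)
  }
  gene_counts <- sort(unique(as.integer(gene_counts)))
  y <- data$labels
  X <- data$expression
  fold <- make_folds(y, outer_folds, derive_seed(seed, 1))
  scores <- matrix(NA_real_, nrow(X), length(gene_counts),
                   dimnames = list(rownames(X), gene_counts))
  for (f in seq_len(outer_folds)) {
    tr <- fold != f
    ranked <- rank_genes_on_split(X[tr, , drop = FALSE], y[tr], inner_folds,
                                  penalty_kind, derive_seed(seed, 100 + f))
    for (j in seq_along(gene_counts)) {
      k <- gene_counts[j]
      # keep original column order within the top-k so k = p reproduces the
      # unrestricted fit exactly
      keep <- colnames(X)[sort(match(ranked[seq_len(k)], colnames(X)))]
      lam <- select_lambda_cv(X[tr, keep, drop = FALSE], y[tr],
                              family = "bernoulli",
                              penalty_kind = penalty_kind,
                              n_folds = inner_folds,
                              seed = derive_seed(seed, 100 + f))
      model <- fit_glm(X[tr, keep, drop = FALSE], y[tr],
                       family = "bernoulli",
                       penalty = penalty_spec(penalty_kind, lam))
      scores[!tr, j] <- predict(model, X[!tr, keep, drop = FALSE])
    }
  }
  res <- lapply(seq_along(gene_counts), function(j) {
    s <- scores[, j]
    boot <- with_seed(derive_seed(seed, 5000 + j), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample(length(s), replace = TRUE)
        if (length(unique(y[idx])) < 2) return(NA_real_)
        auc_mw(s[idx], y[idx])
      }, 0)
    })
    null <- with_seed(derive_seed(seed, 6000 + j), {
      vapply(seq_len(n_null), function(b) auc_mw(s, sample(y)), 0)
    })
    ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    data.frame(k = gene_counts[j], auc = auc_mw(s, y),
               ci_low = ci[1], ci_high = ci[2], chance_auc = mean(null))
  })
  do.call(rbind, res)
}

#' Discriminability as a function of the number of training cells
#'
#' For each training-set size, draws `n_iterations` class-balanced random
#' training subsets, fits the penalized classifier (penalty strength by
#' inner CV on the subset where feasible), and evaluates the AUC on the
#' strictly held-out cells. Optionally repeats the evaluation restricted to
#' the top-k genes ranked within each training subset.
#'
#' @inheritParams nested_cv_scores
#' @param train_sizes Integer vector of total training-set sizes (split
#'   equally between the classes, so sizes must be even; below 4 cells per
#'   class the penalty strength uses a fixed default instead of inner CV).
#' @param n_iterations Random subsets per size (default 100).
#' @param gene_counts Optional gene counts for per-k curves; `NULL` uses
#'   all genes.
#' @return A data.frame with columns `train_size`, `k`, `mean_auc`,
#'   `ci_low`, `ci_high`, `chance_auc`, `n_iterations`.
#' @export
cell_count_curve <- function(data, train_sizes, n_iterations = 100L,
                             gene_counts = NULL, inner_folds = 10L,
                             penalty_kind = "l2", seed = 1L) {
  stopifnot(inherits(data, "labeled_cell_set"))
  X <- data$expression
  y <- data$labels
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  if (is.null(gene_counts)) gene_counts <- ncol(X)
  gene_counts <- sort(unique(as.integer(gene_counts)))
  out <- list()
  for (s in train_sizes) {
    per_class <- s %/% 2
    if (per_class < 1 || s %% 2 != 0) {
      stop("configuration error: train sizes must be even and >= 2")
    }
    if (per_class >= length(idx1) || per_class >= length(idx0)) {
      stop("configuration error: train size exceeds available cells per class")
    }
    aucs <- matrix(NA_real_, n_iterations, length(gene_counts))
    nulls <- matrix(NA_real_, n_iterations, length(gene_counts))
    for (it in seq_len(n_iterations)) {
      sit <- derive_seed(seed, s * 1000 + it)
      tr_idx <- with_seed(sit, c(sample(idx1, per_class),
                                 sample(idx0, per_class)))
      te_idx <- setdiff(seq_along(y), tr_idx)
      Xtr <- X[tr_idx, , drop = FALSE]
      ytr <- y[tr_idx]
      fit_k <- function(keep) {
        if (per_class >= 4) {
          lam <- select_lambda_cv(Xtr[, keep, drop = FALSE], ytr,
                                  family = "bernoulli",
                                  penalty_kind = penalty_kind,
                                  n_folds = min(inner_folds, per_class),
                                  seed = sit)
        } else {
          # inner CV is infeasible on a handful of cells per class; use a
          # fixed moderate point on the candidate grid instead
          std <- standardization_constants(Xtr[, keep, drop = FALSE])
          Xs <- apply_standardization(Xtr[, keep, drop = FALSE], std)
          lam <- 1e-2 * lambda_max(Xs, ytr, penalty_kind)
        }
        fit_glm(Xtr[, keep, drop = FALSE], ytr, family = "bernoulli",
                penalty = penalty_spec(penalty_kind, lam))
      }
      ranked <- if (length(gene_counts) > 1 ||
                    gene_counts[1] < ncol(X)) {
        rank_features(fit_k(colnames(X)))
      } else {
        colnames(X)
      }
      for (j in seq_along(gene_counts)) {
        k <- gene_counts[j]
        keep <- colnames(X)[sort(match(ranked[seq_len(k)], colnames(X)))]
        model <- fit_k(keep)
        sc <- predict(model, X[te_idx, keep, drop = FALSE])
        aucs[it, j] <- auc_mw(sc, y[te_idx])
        nulls[it, j] <- with_seed(derive_seed(sit, j),
                                  auc_mw(sc, sample(y[te_idx])))
      }
    }
    for (j in seq_along(gene_counts)) {
      ci <- bootstrap_ci(aucs[, j], seed = derive_seed(seed, s * 7 + j))
      out[[length(out) + 1]] <- data.frame(
        train_size = s, k = gene_counts[j], mean_auc = mean(aucs[, j]),
        ci_low = ci[["low"]], ci_high = ci[["high"]],
        chance_auc = mean(nulls[, j]), n_iterations = n_iterations)
    }
  }
  do.call(rbind, out)
}
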