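#' Cell-line drug-response panel
#'
#' Bundles a lines x genes expression matrix, a lines x drugs sensitivity
#' matrix (units -log(GI50): larger = more sensitive), and binary subtype
#' labels (1 = basal-like/aggressive, 0 = luminal/less aggressive). Rows of
#' the two matrices must describe the same cell lines in the same order.
#'
#' @param expression Numeric matrix, lines x genes.
#' @param sensitivity Numeric matrix, lines x drugs; `NA` marks a missing
#'   measurement (dropped per drug downstream).
#' @param subtype_labels Binary vector, one per line.
#' @return An object of class `cell_line_panel`.
#' @export
cell_line_panel <- function(expression, sensitivity, subtype_labels) {
  expression <- check_matrix(expression)
  if (!is.matrix(sensitivity)) sensitivity <- as.matrix(sensitivity)
  if (nrow(sensitivity) != nrow(expression)) {
    stop("expression and sensitivity must describe the same cell lines")
  }
  if (!is.null(rownames(expression)) && !is.null(rownames(sensitivity)) &&
      !identical(rownames(expression), rownames(sensitivity))) {
    stop("expression and sensitivity row (line) ids differ or are reordered")
  }
  if (length(subtype_labels) != nrow(expression)) {
    stop("subtype_labels length must equal the line count")
  }
  check_binary(subtype_labels)
  structure(list(
    expression = expression,
    sensitivity = sensitivity,
    drug_ids = colnames(sensitivity),
    subtype_labels = as.integer(subtype_labels)
  ), class = "cell_line_panel")
}

# Lines with an observed sensitivity for this drug.
drug_rows <- function(panel, drug_id) {
  if (!drug_id %in% colnames(panel$sensitivity)) {
    stop("lookup error: unknown drug '", drug_id, "'")
  }
  which(is.finite(panel$sensitivity[, drug_id]))
}

#' Fit a sparse expression model of one drug's sensitivity
#'
#' Gaussian GLM with an L1 penalty (sparsity is appropriate when few of
#' thousands of genes drive a drug's response); the penalty strength is
#' chosen by inner cross-validation. Lines missing this drug's sensitivity
#' are dropped for this drug only.
#'
#' @param panel A [cell_line_panel()].
#' @param drug_id Drug identifier (a `sensitivity` column name).
#' @param inner_folds Folds for the lambda-selection CV (default 10).
#' @param seed Integer seed.
#' @param compute_loocv Also compute the leave-one-out R2 (default `TRUE`;
#'   disable when fitting many drugs just for their weights).
#' @return An object of class `drug_model`: `drug_id`, `glm` (a
#'   `glm_model`), `lambda`, `n_lines`, and `loocv_r2` (or `NA`).
#' @export
fit_drug_model <- function(panel, drug_id, inner_folds = 10L, seed = 1L,
                           compute_loocv = TRUE) {
  stopifnot(inherits(panel, "cell_line_panel"))
  rows <- drug_rows(panel, drug_id)
  if (length(rows) < 10) {
    stop("sample-size error: fewer than 10 lines with observed sensitivity")
  }
  X <- panel$expression[rows, , drop = FALSE]
  y <- panel$sensitivity[rows, drug_id]
  lam <- select_lambda_cv(X, y, family = "gaussian", penalty_kind = "l1",
                          n_folds = inner_folds, seed = derive_seed(seed, 1))
  glm <- fit_glm(X, y, family = "gaussian", penalty = penalty_spec("l1", lam))
  r2 <- if (compute_loocv) {
    loocv_r2(panel, drug_id, inner_folds = inner_folds, seed = seed)
  } else {
    NA_real_
  }
  structure(list(drug_id = drug_id, glm = glm, lambda = lam,
                 n_lines = length(rows), loocv_r2 = r2),
            class = "drug_model")
}

# Shared LOOCV engine: held-out prediction for every line, optionally
# restricted per gene count (ranking refit within each training set).
loocv_predictions <- function(panel, drug_id, gene_counts = NULL,
                              inner_folds = 10L, seed = 1L,
                              relambda = TRUE) {
  rows <- drug_rows(panel, drug_id)
  X <- panel$expression[rows, , drop = FALSE]
  y <- panel$sensitivity[rows, drug_id]
  if (stats::sd(y) == 0) {
    stop("undefined-R2 error: sensitivity has zero variance")
  }
  # canonical line order (by id): makes the held-out predictions invariant
  # to how the panel's rows happen to be sorted
  input_order <- rownames(X)
  if (!is.null(input_order)) {
    canon <- order(input_order)
    X <- X[canon, , drop = FALSE]
    y <- y[canon]
  }
  n <- length(rows)
  p <- ncol(X)
  full_only <- is.null(gene_counts)
  if (full_only) gene_counts <- p
  gene_counts <- sort(unique(as.integer(gene_counts)))
  if (any(gene_counts < 1) || any(gene_counts > p)) {
    stop("configuration error: gene counts must lie in 1..", p)
  }
  lam_shared <- if (!relambda) {
    select_lambda_cv(X, y, family = "gaussian", penalty_kind = "l1",
                     n_folds = inner_folds, seed = derive_seed(seed, 1))
  } else {
    NULL
  }
  preds <- matrix(NA_real_, n, length(gene_counts),
                  dimnames = list(rownames(X), gene_counts))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    si <- derive_seed(seed, 200 + i)
    fit_at <- function(keep) {
      lam <- if (relambda) {
        select_lambda_cv(Xtr[, keep, drop = FALSE], ytr,
                         family = "gaussian", penalty_kind = "l1",
                         n_folds = min(inner_folds, n - 1), seed = si)
      } else {
        lam_shared
      }
      fit_glm(Xtr[, keep, drop = FALSE], ytr, family = "gaussian",
              penalty = penalty_spec("l1", lam))
    }
    full_fit <- fit_at(colnames(X))
    ranked <- rank_features(full_fit)
    for (j in seq_along(gene_counts)) {
      k <- gene_counts[j]
      if (k == p) {
        # unrestricted: reuse the ranking fit directly
        preds[i, j] <- predict(full_fit, X[i, , drop = FALSE])
      } else {
        keep <- colnames(X)[sort(match(ranked[seq_len(k)], colnames(X)))]
        m <- fit_at(keep)
        preds[i, j] <- predict(m, X[i, keep, drop = FALSE])
      }
    }
  }
  if (!is.null(input_order)) {
    back <- match(input_order, rownames(preds))
    preds <- preds[back, , drop = FALSE]
    y <- y[back]
  }
  list(predictions = preds, y = y, gene_counts = gene_counts)
}

r2_from_predictions <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("undefined-R2 error: sensitivity has zero variance")
  1 - sum((y - yhat)^2) / sst
}

#' Leave-one-out cross-validated R2 of a drug's expression model
#'
#' Each line is predicted by an L1 gaussian model trained on all other
#' lines, with the penalty strength re-selected inside every training set
#' (no leakage). `R2 = 1 - SSE/SST` over the held-out predictions; values
#' can be negative when the model predicts worse than the mean.
#'
#' @inheritParams fit_drug_model
#' @param relambda Re-select lambda within every training set (default
#'   `TRUE`). `FALSE` reuses a single panel-wide lambda — faster, but the
#'   selection then sees each held-out line.
#' @return The LOOCV R2, with the per-line held-out predictions attached as
#'   attribute `"predictions"`.
#' @export
loocv_r2 <- function(panel, drug_id, inner_folds = 10L, seed = 1L,
                     relambda = TRUE) {
  stopifnot(inherits(panel, "cell_line_panel"))
  lp <- loocv_predictions(panel, drug_id, gene_counts = NULL,
                          inner_folds = inner_folds, seed = seed,
                          relambda = relambda)
  r2 <- r2_from_predictions(lp$y, lp$predictions[, 1])
  attr(r2, "predictions") <- lp$predictions[, 1]
  r2
}

#' Prediction accuracy as a function of the number of genes
#'
#' For each gene count k, each line is predicted by a model restricted to
#' the top-k genes (ranked by weight magnitude within that line's training
#' set), and the LOOCV R2 is recomputed. The CI bootstraps cell lines
#' (resampling the held-out squared errors).
#'
#' @inheritParams loocv_r2
#' @param gene_counts Integer vector of gene counts (all >= 1).
#' @param n_boot Bootstrap resamples (default 1000).
#' @return A data.frame with columns `k`, `r2`, `ci_low`, `ci_high`.
#' @export
r2_vs_gene_count <- function(panel, drug_id, gene_counts,
                             inner_folds = 10L, seed = 1L,
                             relambda = TRUE, n_boot = 1000L) {
  stopifnot(inherits(panel, "cell_line_panel"))
  if (length(gene_counts) == 0 || any(gene_counts < 1)) {
    stop("configuration error: gene counts must be positive")
  }
  lp <- loocv_predictions(panel, drug_id, gene_counts = gene_counts,
                          inner_folds = inner_folds, seed = seed,
                          relambda = relambda)
  y <- lp$y
  res <- lapply(seq_along(lp$gene_counts), function(j) {
    yhat <- lp$predictions[, j]
    boot <- with_seed(derive_seed(seed, 9000 + j), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample(length(y), replace = TRUE)
        if (stats::var(y[idx]) == 0) return(NA_real_)
        r2_from_predictions(y[idx], yhat[idx])
      }, 0)
    })
    ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    data.frame(k = lp$gene_counts[j], r2 = r2_from_predictions(y, yhat),
               ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, res)
}

#' Two-gene drug-sensitivity heatmap
#'
#' Fits the drug's L1 model on all lines, takes the two genes with the
#' largest weight magnitudes (a descriptive, not cross-validated, choice),
#' and interpolates the observed sensitivities onto a regular grid over the
#' two genes' observed expression ranges: piecewise-linear interpolation
#' inside the convex hull of the observed points, nearest-neighbour fill
#' outside.
#'
#' @inheritParams fit_drug_model
#' @param resolution Grid points per axis (default 100).
#' @return An object of class `sensitivity_heatmap`: `gene_x`, `gene_y`,
#'   `grid_x`, `grid_y`, and the `resolution` x `resolution` matrix `heat`
#'   (rows follow `grid_x`).
#' @export
two_gene_heatmap <- function(panel, drug_id, resolution = 100L, seed = 1L) {
  stopifnot(inherits(panel, "cell_line_panel"))
  if (resolution < 2) stop("configuration error: resolution must be >= 2")
  model <- fit_drug_model(panel, drug_id, seed = seed,
                          compute_loocv = FALSE)
  top2 <- rank_features(model$glm)[1:2]
  rows <- drug_rows(panel, drug_id)
  gx <- panel$expression[rows, top2[1]]
  gy <- panel$expression[rows, top2[2]]
  z <- panel$sensitivity[rows, drug_id]
  grid_x <- seq(min(gx), max(gx), length.out = resolution)
  grid_y <- seq(min(gy), max(gy), length.out = resolution)
  heat <- interp_scattered(gx, gy, z, grid_x, grid_y)
  structure(list(gene_x = top2[1], gene_y = top2[2],
                 grid_x = grid_x, grid_y = grid_y, heat = heat),
            class = "sensitivity_heatmap")
}
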