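#' Extract a drug's feature vector for pair classification
#'
#' A drug enters the compound classifier either through its measured
#' chemosensitivity column (`source = "measured"`) or through its Part II
#' expression model applied to the panel (`source = "predicted"`); the
#' latter is how a drug's behavior is tied back to gene expression.
#'
#' @param panel A [cell_line_panel()].
#' @param drug_id Drug identifier.
#' @param source `"predicted"` (default; requires `model`) or `"measured"`.
#' @param model The drug's fitted [fit_drug_model()] result (required for
#'   `source = "predicted"`; there is no silent fallback to measured data).
#' @return An object of class `drug_feature`: `drug_id`, `values` (one per
#'   line, -log GI50 units), `source`.
#' @export
drug_feature <- function(panel, drug_id,
                         source = c("predicted", "measured"),
                         model = NULL) {
  stopifnot(inherits(panel, "cell_line_panel"))
  source <- match.arg(source)
  if (!drug_id %in% colnames(panel$sensitivity)) {
    stop("lookup error: unknown drug '", drug_id, "'")
  }
  values <- if (source == "measured") {
    panel$sensitivity[, drug_id]
  } else {
    if (is.null(model)) {
      stop("lookup error: predicted source requires a fitted drug model ",
           "for '", drug_id, "'")
    }
    if (!inherits(model, "drug_model") || model$drug_id != drug_id) {
      stop("lookup error: model does not belong to drug '", drug_id, "'")
    }
    predict(model$glm, panel$expression)
  }
  if (any(!is.finite(values))) {
    stop("data-quality error: non-finite feature values for '", drug_id, "'")
  }
  structure(list(drug_id = drug_id, values = as.numeric(values),
                 source = source),
            class = "drug_feature")
}

feature_values <- function(x) {
  if (inherits(x, "drug_feature")) x$values else as.numeric(x)
}

# One subsampling round: stratified train indices; returns NULL when the
# held-out split is single-class (caller redraws).
draw_split <- function(labels, train_fraction, seed) {
  idx1 <- which(labels == 1)
  idx0 <- which(labels == 0)
  tr <- with_seed(seed, c(
    sample(idx1, max(1, floor(train_fraction * length(idx1)))),
    sample(idx0, max(1, floor(train_fraction * length(idx0))))
  ))
  te <- setdiff(seq_along(labels), tr)
  if (length(unique(labels[te])) < 2 || length(unique(labels[tr])) < 2) {
    return(NULL)
  }
  list(train = tr, test = te)
}

# Unpenalized logistic fit + held-out AUC for a feature matrix.
split_auc <- function(F, labels, split) {
  Ftr <- F[split$train, , drop = FALSE]
  fit <- suppressWarnings(stats::glm.fit(cbind(1, Ftr), labels[split$train],
                                         family = stats::binomial()))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  eta <- drop(cbind(1, F[split$test, , drop = FALSE]) %*% co)
  auc_mw(eta, labels[split$test])
}

#' Evaluate a two-drug compound classifier
#'
#' Per round, draws a stratified random train/test split, fits an
#' unpenalized two-feature logistic GLM (overfitting is unlikely with two
#' features) on the training lines, and computes the AUC on the held-out
#' lines. Single-drug AUCs are computed on the identical splits with one
#' feature each, so the comparison is split-for-split fair. Degenerate
#' single-class held-out splits are redrawn (capped; the redraw count is
#' reported).
#'
#' @param x_a,x_b [drug_feature()] objects (or plain numeric vectors).
#' @param labels Binary population labels, one per line.
#' @param n_rounds Number of subsampling rounds (default 100).
#' @param train_fraction Fraction of each class used for training
#'   (default 0.9).
#' @param seed Integer seed.
#' @param n_perm Optional label permutations for a pair-AUC p-value
#'   (default 0 = none).
#' @param n_boot Bootstrap resamples for the round-AUC CI (default 1000).
#' @param max_redraw Cap on redraws of degenerate splits (default 1000).
#' @return An object of class `pair_search_result`: `drug_a`, `drug_b`,
#'   `pair_auc`, `pair_ci`, `auc_a`, `auc_b`, `weights` (all-data fit),
#'   `round_aucs`, `n_rounds`, `n_redrawn`, and `p_value` when requested.
#' @export
evaluate_pair <- function(x_a, x_b, labels, n_rounds = 100L,
                          train_fraction = 0.9, seed = 1L, n_perm = 0L,
                          n_boot = 1000L, max_redraw = 1000L) {
  va <- feature_values(x_a)
  vb <- feature_values(x_b)
  check_binary(labels)
  if (length(va) != length(labels) || length(vb) != length(labels)) {
    stop("feature vectors and labels must have equal length")
  }
  if (n_rounds < 1) stop("configuration error: n_rounds must be >= 1")
  F2 <- cbind(a = va, b = vb)
  run_rounds <- function(lab, seed0) {
    pa <- aa <- ab <- numeric(n_rounds)
    redrawn <- 0L
    for (r in seq_len(n_rounds)) {
      split <- NULL
      attempt <- 0L
      while (is.null(split)) {
        split <- draw_split(lab, train_fraction,
                            derive_seed(seed0, r * 1009 + attempt))
        if (is.null(split)) {
          attempt <- attempt + 1L
          redrawn <- redrawn + 1L
          if (attempt > max_redraw) {
            stop("configuration error: could not draw a two-class test split")
          }
        }
      }
      pa[r] <- split_auc(F2, lab, split)
      aa[r] <- split_auc(F2[, "a", drop = FALSE], lab, split)
      ab[r] <- split_auc(F2[, "b", drop = FALSE], lab, split)
    }
    list(pair = pa, a = aa, b = ab, redrawn = redrawn)
  }
  obs <- run_rounds(labels, seed)
  ci <- bootstrap_ci(obs$pair, n_boot = n_boot, seed = derive_seed(seed, 7))
  full <- suppressWarnings(stats::glm.fit(cbind(1, F2), labels,
                                          family = stats::binomial()))
  w <- full$coefficients
  w[is.na(w)] <- 0
  p_value <- NA_real_
  if (n_perm > 0) {
    null_max <- vapply(seq_len(n_perm), function(p) {
      perm <- with_seed(derive_seed(seed, 50000 + p), sample(labels))
      mean(run_rounds(perm, derive_seed(seed, 60000 + p))$pair)
    }, 0)
    p_value <- (1 + sum(null_max >= mean(obs$pair))) / (1 + n_perm)
  }
  structure(list(
    drug_a = if (inherits(x_a, "drug_feature")) x_a$drug_id else "a",
    drug_b = if (inherits(x_b, "drug_feature")) x_b$drug_id else "b",
    pair_auc = mean(obs$pair),
    pair_ci = c(low = unname(ci["low"]), high = unname(ci["high"])),
    auc_a = mean(obs$a),
    auc_b = mean(obs$b),
    weights = c(intercept = unname(w[1]), a = unname(w[2]),
                b = unname(w[3])),
    round_aucs = obs$pair,
    n_rounds = n_rounds,
    n_redrawn = obs$redrawn,
    p_value = p_value
  ), class = "pair_search_result")
}

# Symmetric per-pair seed: a deterministic hash of the sorted drug ids, so
# (A, B) and (B, A) are evaluated with identical randomness.
pair_seed <- function(seed, id1, id2) {
  s <- paste(sort(c(id1, id2)), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 1048573
  derive_seed(seed, h)
}

# Build the per-drug feature list for a panel.
panel_features <- function(panel, source = c("predicted", "measured"),
                           models = NULL, seed = 1L) {
  source <- match.arg(source)
  drugs <- colnames(panel$sensitivity)
  stats::setNames(lapply(drugs, function(d) {
    m <- if (source == "predicted") {
      if (!is.null(models)) {
        models[[d]]
      } else {
        fit_drug_model(panel, d, seed = derive_seed(seed, match(d, drugs)),
                       compute_loocv = FALSE)
      }
    }
    drug_feature(panel, d, source = source, model = m)
  }), drugs)
}

#' Exhaustive drug-pair search
#'
#' Evaluates every unordered drug pair (`D * (D - 1) / 2` of them) with
#' [evaluate_pair()] and returns the full table ranked by pair AUC,
#' descending. The per-pair seed is derived from the unordered pair, so the
#' result for (A, B) is identical to (B, A).
#'
#' @inheritParams evaluate_pair
#' @param panel A [cell_line_panel()].
#' @param source Feature source, `"predicted"` (default) or `"measured"`.
#' @param models Optional named list of fitted [fit_drug_model()] objects
#'   (fitted on the fly when omitted and `source = "predicted"`).
#' @return A data.frame with one row per pair — columns `drug_a`, `drug_b`,
#'   `pair_auc`, `ci_low`, `ci_high`, `auc_a`, `auc_b` — ranked by
#'   `pair_auc`; the full `pair_search_result` objects are attached as
#'   attribute `"results"`.
#' @export
search_pairs <- function(panel, source = c("predicted", "measured"),
                         n_rounds = 100L, seed = 1L, models = NULL,
                         train_fraction = 0.9, n_boot = 1000L) {
  stopifnot(inherits(panel, "cell_line_panel"))
  source <- match.arg(source)
  drugs <- colnames(panel$sensitivity)
  if (length(drugs) < 2) stop("configuration error: need at least 2 drugs")
  feats <- panel_features(panel, source, models, seed)
  labels <- panel$subtype_labels
  pairs <- utils::combn(seq_along(drugs), 2)
  results <- lapply(seq_len(ncol(pairs)), function(pidx) {
    i <- pairs[1, pidx]
    j <- pairs[2, pidx]
    evaluate_pair(feats[[i]], feats[[j]], labels, n_rounds = n_rounds,
                  train_fraction = train_fraction, n_boot = n_boot,
                  seed = pair_seed(seed, drugs[i], drugs[j]))
  })
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(drug_a = r$drug_a, drug_b = r$drug_b, pair_auc = r$pair_auc,
               ci_low = unname(r$pair_ci["low"]),
               ci_high = unname(r$pair_ci["high"]),
               auc_a = r$auc_a, auc_b = r$auc_b)
  }))
  ord <- order(-tab$pair_auc)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "results") <- results[ord]
  tab
}

#' Null distribution of the best pair AUC under label permutation
#'
#' Because the search picks the maximum over many pairs, the best pair's
#' AUC exceeds 0.5 even on pure noise (a selection effect). This exposes
#' that null: for each permutation the full pair search is re-run on
#' shuffled labels and the maximum pair AUC recorded.
#'
#' @inheritParams search_pairs
#' @param n_perm Number of label permutations (default 20).
#' @return Numeric vector of per-permutation maximum pair AUCs.
#' @export
pair_search_null_max <- function(panel, source = c("predicted", "measured"),
                                 n_rounds = 25L, n_perm = 20L, seed = 1L,
                                 models = NULL) {
  stopifnot(inherits(panel, "cell_line_panel"))
  source <- match.arg(source)
  vapply(seq_len(n_perm), function(p) {
    perm_panel <- panel
    perm_panel$subtype_labels <- with_seed(derive_seed(seed, 70000 + p),
                                           sample(panel$subtype_labels))
    max(search_pairs(perm_panel, source = source, n_rounds = n_rounds,
                     seed = derive_seed(seed, 80000 + p),
                     models = models)$pair_auc)
  }, 0)
}

#' Multiple-comparison annotation of a pair-search table
#'
#' The default (`method = "none"`) returns the table unchanged — the
#' demonstration analysis deliberately performs no correction.
#' `"benjamini_hochberg"` annotates FDR-adjusted q-values, which requires a
#' `p_value` column (per-pair permutation p-values from [evaluate_pair()]
#' with `n_perm > 0`).
#'
#' @param results A data.frame of pair results.
#' @param method `"none"` (default) or `"benjamini_hochberg"`.
#' @return The input, with a `q_value` column added for BH.
#' @export
multiplicity_adjust <- function(results,
                                method = c("none", "benjamini_hochberg")) {
  method <- match.arg(method)
  if (method == "none") return(results)
  if (is.null(results$p_value) || any(is.na(results$p_value))) {
    stop("state error: BH adjustment requires per-pair p-values")
  }
  results$q_value <- stats::p.adjust(results$p_value, method = "BH")
  results
}
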