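#' Penalty specification for a regularized GLM
#'
#' @param kind Penalty type: `"l1"` (lasso, sparsity-inducing), `"l2"`
#'   (ridge, shrinkage), or `"none"` (ordinary maximum likelihood).
#' @param strength Nonnegative penalty strength (lambda). Ignored when
#'   `kind = "none"`.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(kind = c("none", "l1", "l2"), strength = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(strength) || length(strength) != 1 || is.na(strength) ||
      strength < 0) {
    stop("penalty strength must be a nonnegative real number")
  }
  structure(list(kind = kind, strength = strength), class = "penalty_spec")
}

# Per-feature z-scoring constants; zero-variance columns get scale 1 so the
# centered column is identically zero and its weight is driven to zero by
# any penalty.
standardization_constants <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_standardization <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

# Largest lambda of the candidate grid: the L1 zero-crossing computed from
# the standardized data, inflated 1000x for ridge (which has no finite
# zero-crossing).
lambda_max <- function(Xs, y, kind) {
  z <- max(abs(crossprod(Xs, y - mean(y)))) / nrow(Xs)
  z <- max(z, 1e-8)
  if (kind == "l2") 1000 * z else z
}

# 50 log-spaced candidates from lambda_max down to 1e-4 * lambda_max.
lambda_grid <- function(Xs, y, kind, n_lambda = 50) {
  lmax <- lambda_max(Xs, y, kind)
  exp(seq(log(lmax), log(1e-4 * lmax), length.out = n_lambda))
}

# glmnet requires >= 2 columns; pad single-feature designs with a zero
# column (which always receives weight zero) and drop it afterwards.
glmnet_fit <- function(Xs, y, family, alpha, lambda) {
  padded <- ncol(Xs) == 1L
  if (padded) Xs <- cbind(Xs, `..pad..` = 0)
  fam <- if (family == "bernoulli") "binomial" else "gaussian"
  fit <- suppressWarnings(glmnet::glmnet(
    Xs, y,
    family = fam, alpha = alpha, lambda = lambda,
    standardize = FALSE, intercept = TRUE, thresh = 1e-10, maxit = 1e6
  ))
  list(fit = fit, padded = padded)
}

#' Fit a regularized generalized linear model
#'
#' Fits a GLM of the given family with an optional L1 or L2 penalty on the
#' feature weights (the intercept is never penalized). Predictors are
#' z-scored on the training data before fitting and the standardization
#' constants are stored in the model, so weights are directly comparable in
#' magnitude and prediction is scale-invariant. The penalized objective is
#' mean negative log-likelihood plus `lambda * sum(|beta|)` (L1) or
#' `lambda/2 * sum(beta^2)` (L2).
#'
#' @param X Numeric matrix, samples x features. Column names are used as
#'   feature ids when present.
#' @param y Response vector: in `{0,1}` for `family = "bernoulli"`,
#'   real-valued for `family = "gaussian"`.
#' @param family Response family.
#' @param penalty A [penalty_spec()].
#' @param seed Integer seed (kept for interface symmetry; the fit itself is
#'   deterministic given the inputs).
#' @return An object of class `glm_model` with elements `family`, `weights`
#'   (standardized scale), `intercept`, `penalty`, `penalty_strength`,
#'   `feature_ids`, `center`, `scale`.
#' @export
fit_glm <- function(X, y, family = c("bernoulli", "gaussian"),
                    penalty = penalty_spec("none"), seed = 1L) {
  family <- match.arg(family)
  X <- check_matrix(X)
  if (length(y) != nrow(X)) stop("y length must match the row count of X")
  if (any(!is.finite(y))) stop("data-quality error: non-finite response")
  if (family == "bernoulli") check_binary(y)
  if (!inherits(penalty, "penalty_spec")) {
    stop("penalty must be a penalty_spec object")
  }
  feature_ids <- colnames(X)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(X)))

  std <- standardization_constants(X)
  Xs <- apply_standardization(X, std)

  kind <- penalty$kind
  if (kind != "none" && penalty$strength == 0) kind <- "none"

  if (kind == "none") {
    # unpenalized maximum likelihood; iteration-capped IRLS handles the
    # separable case by terminating at a finite (large-margin) solution
    fam <- if (family == "bernoulli") stats::binomial() else stats::gaussian()
    fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, Xs), y,
                                           family = fam))
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    intercept <- coefs[1]
    weights <- coefs[-1]
  } else if (family == "bernoulli" && min(table(y)) < 2) {
    # glmnet needs two observations per class; tiny training sets (down to
    # one cell per class in the learning curves) fall back to direct
    # quasi-Newton minimization of the penalized objective
    co <- fit_penalized_optim(Xs, y, family, kind, penalty$strength)
    intercept <- co$intercept
    weights <- co$weights
  } else {
    alpha <- if (kind == "l1") 1 else 0
    # short warm-start sequence ending at the requested strength: glmnet is
    # more accurate along a decreasing path than at a single lambda
    lam_seq <- penalty$strength * c(32, 16, 8, 4, 2, 1)
    gf <- glmnet_fit(Xs, y, family, alpha, lam_seq)
    k <- length(lam_seq)
    weights <- as.numeric(gf$fit$beta[, k])
    if (gf$padded) weights <- weights[-length(weights)]
    intercept <- as.numeric(gf$fit$a0[k])
  }

  names(weights) <- feature_ids
  structure(list(
    family = family,
    weights = weights,
    intercept = unname(intercept),
    penalty = penalty$kind,
    penalty_strength = penalty$strength,
    feature_ids = feature_ids,
    center = stats::setNames(std$center, feature_ids),
    scale = stats::setNames(std$scale, feature_ids)
  ), class = "glm_model")
}

#' Predict from a fitted `glm_model`
#'
#' Applies the stored standardization, forms the linear predictor, and
#' passes it through the family's inverse link (logistic for bernoulli,
#' identity for gaussian).
#'
#' @param object A `glm_model`.
#' @param X Numeric matrix with the model's features. If `X` has column
#'   names they are re-aligned to the model's `feature_ids`; a mismatch is
#'   an error.
#' @param ... Unused.
#' @return Numeric score vector: probabilities strictly inside (0, 1) for
#'   bernoulli, unbounded reals for gaussian.
#' @export
predict.glm_model <- function(object, X, ...) {
  X <- check_matrix(X)
  if (!is.null(colnames(X))) {
    if (!setequal(colnames(X), object$feature_ids)) {
      stop("schema error: feature ids of X do not match the model")
    }
    X <- X[, object$feature_ids, drop = FALSE]
  } else if (ncol(X) != length(object$feature_ids)) {
    stop("schema error: X has ", ncol(X), " features; model expects ",
         length(object$feature_ids))
  }
  Xs <- apply_standardization(X, list(center = object$center,
                                      scale = object$scale))
  eta <- drop(Xs %*% object$weights) + object$intercept
  if (object$family == "bernoulli") {
    p <- stats::plogis(eta)
    pmin(pmax(p, 1e-12), 1 - 1e-12)
  } else {
    eta
  }
}

#' Rank features by weight magnitude
#'
#' Orders the model's features by decreasing absolute weight (on the
#' standardized scale, so magnitudes are comparable across features). Ties
#' are broken by original column order; zero-weight features therefore sort
#' last, among themselves in input order.
#'
#' @param model A fitted `glm_model`.
#' @return Character vector of feature ids, most important first.
#' @export
rank_features <- function(model) {
  if (!inherits(model, "glm_model") || is.null(model$weights)) {
    stop("state error: rank_features requires a fitted glm_model")
  }
  ord <- order(-abs(model$weights), seq_along(model$weights))
  model$feature_ids[ord]
}

# Direct minimization of the penalized objective (L-BFGS-B on intercept +
# weights; |beta| smoothed for L1). Only used where glmnet cannot run.
fit_penalized_optim <- function(Xs, y, family, kind, strength) {
  p <- ncol(Xs)
  obj <- function(par) {
    pen <- switch(kind,
      l1 = strength * sum(sqrt(par[-1]^2 + 1e-10)),
      l2 = strength / 2 * sum(par[-1]^2)
    )
    penalized_objective(Xs, y, par[-1], par[1], family, "none", 0) + pen
  }
  fit <- stats::optim(rep(0, p + 1), obj, method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 1e4))
  w <- fit$par[-1]
  if (kind == "l1") w[abs(w) < 1e-6] <- 0
  list(intercept = fit$par[1], weights = w)
}

# Penalized objective (mean negative log-likelihood + penalty) evaluated on
# an already-standardized design; shared by the optimizer-sanity checks.
penalized_objective <- function(Xs, y, weights, intercept, family, kind,
                                strength) {
  eta <- drop(Xs %*% weights) + intercept
  n <- nrow(Xs)
  nll <- if (family == "bernoulli") {
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) / n
  } else {
    sum((y - eta)^2) / (2 * n)
  }
  pen <- switch(kind,
    none = 0,
    l1 = strength * sum(abs(weights)),
    l2 = strength / 2 * sum(weights^2)
  )
  nll + pen
}

#' Select the penalty strength by cross-validation
#'
#' Scans a logarithmic grid of 50 candidate strengths (from the data-derived
#' `lambda_max` down to `1e-4 * lambda_max`) and returns the candidate
#' minimizing the mean held-out deviance over `n_folds` cross-validation
#' folds (stratified by class for the bernoulli family). Fold assignment is
#' a deterministic function of `seed`.
#'
#' @inheritParams fit_glm
#' @param penalty_kind `"l1"` or `"l2"`.
#' @param n_folds Number of folds (default 10).
#' @return The selected nonnegative strength.
#' @export
select_lambda_cv <- function(X, y, family = c("bernoulli", "gaussian"),
                             penalty_kind = c("l1", "l2"), n_folds = 10L,
                             seed = 1L) {
  family <- match.arg(family)
  penalty_kind <- match.arg(penalty_kind)
  X <- check_matrix(X)
  if (family == "bernoulli") {
    check_binary(y)
    if (min(table(y)) < n_folds) {
      n_folds <- min(table(y))
    }
  }
  n_folds <- min(n_folds, nrow(X))
  if (n_folds < 4) {
    # cross-validated deviance is not estimable on fewer than 4 folds
    # (and each fold's training split must retain both classes)
    stop("configuration error: too few samples per class for ", n_folds,
         "-fold lambda selection")
  }
  std <- standardization_constants(X)
  Xs <- apply_standardization(X, std)
  grid <- lambda_grid(Xs, y, penalty_kind)
  foldid <- make_folds(y, n_folds, seed, stratify = family == "bernoulli")
  alpha <- if (penalty_kind == "l1") 1 else 0
  padded <- ncol(Xs) == 1L
  if (padded) Xs <- cbind(Xs, `..pad..` = 0)
  fam <- if (family == "bernoulli") "binomial" else "gaussian"
  cv <- suppressWarnings(glmnet::cv.glmnet(
    Xs, y,
    family = fam, alpha = alpha, lambda = grid, foldid = foldid,
    standardize = FALSE, intercept = TRUE, type.measure = "deviance",
    thresh = 1e-7
  ))
  as.numeric(cv$lambda.min)
}
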