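#' ROC curve and area under the curve
#'
#' Sweeps thresholds over the unique score values (higher score = more
#' likely positive), accumulating true- and false-positive rates, and
#' integrates the curve by the trapezoidal rule. Tied scores contribute
#' half credit, so the AUC equals the Mann-Whitney U statistic divided by
#' `n1 * n0`.
#'
#' @param scores Numeric score vector (finite).
#' @param labels Binary vector in `{0,1}` (1 = positive/cancer).
#' @return An object of class `roc_result`: `thresholds`, `fpr`, `tpr`
#'   (curves from (0,0) to (1,1)), and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  check_binary(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("undefined-ROC error: both classes must be present")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  # counts per unique score value, split by class
  tp_at <- vapply(thr, function(t) sum(scores == t & labels == 1), 0)
  fp_at <- vapply(thr, function(t) sum(scores == t & labels == 0), 0)
  tpr <- c(0, cumsum(tp_at) / n1)
  fpr <- c(0, cumsum(fp_at) / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(
    thresholds = c(Inf, thr),
    fpr = fpr,
    tpr = tpr,
    auc = auc
  ), class = "roc_result")
}

# Rank-based AUC (Mann-Whitney with midranks for ties); identical to the
# trapezoidal integral of the ROC curve but O(n log n), used in resampling
# loops.
auc_mw <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- length(labels) - n1
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the per-iteration statistics with replacement `n_boot` times
#' and returns the 2.5 and 97.5 percentiles of the resampled means.
#'
#' @param x Numeric vector of per-iteration statistics (length >= 1).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(x, n_boot = 1000L, seed = 1L) {
  if (length(x) == 0) stop("empty-input error: no statistics to bootstrap")
  if (length(x) == 1) return(c(low = x, high = x))
  means <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(sample(x, length(x), replace = TRUE)), 0)
  })
  q <- stats::quantile(means, c(0.025, 0.975), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}
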