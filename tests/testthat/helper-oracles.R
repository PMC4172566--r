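# Independent brute-force oracles used to check the package's fast paths.
# These deliberately share no code with the implementation.

# Penalized objective evaluated directly from the definition:
# mean negative log-likelihood + lambda * P(beta). `Xs` is the standardized
# design the model was fitted on.
oracle_objective <- function(Xs, y, beta, intercept, family, kind, strength) {
  eta <- as.vector(Xs %*% beta) + intercept
  if (family == "bernoulli") {
    nll <- mean(log(1 + exp(eta)) - y * eta)
  } else {
    nll <- mean((y - eta)^2) / 2
  }
  pen <- if (kind == "l1") {
    strength * sum(abs(beta))
  } else if (kind == "l2") {
    strength / 2 * sum(beta^2)
  } else {
    0
  }
  nll + pen
}

# Dense grid minimization of the penalized objective for designs with at
# most 2 features (plus intercept). Returns the best objective value found.
oracle_grid_min <- function(Xs, y, family, kind, strength,
                            lim = 5, n_grid = 41) {
  g <- seq(-lim, lim, length.out = n_grid)
  p <- ncol(Xs)
  stopifnot(p <= 2)
  best <- Inf
  grid <- if (p == 2) as.matrix(expand.grid(g, g)) else matrix(g, ncol = 1)
  for (b0 in g) {
    eta <- Xs %*% t(grid) + b0
    if (family == "bernoulli") {
      nll <- colMeans(log(1 + exp(eta)) - y * eta)
    } else {
      nll <- colMeans((y - eta)^2) / 2
    }
    pen <- if (kind == "l1") {
      strength * rowSums(abs(grid))
    } else if (kind == "l2") {
      strength / 2 * rowSums(grid^2)
    } else {
      0
    }
    best <- min(best, min(nll + pen))
  }
  best
}

# AUC by exhaustive pairwise comparison (Mann-Whitney with half credit for
# ties): the probability a random positive outscores a random negative.
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg from the definition: q_i = min over j >= i (by sorted
# p) of p_(j) * m / j, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Standardize a matrix the way the package documents (z-score; sd 0 -> 1).
oracle_standardize <- function(X) {
  ctr <- colMeans(X)
  sc <- apply(X, 2, sd)
  sc[sc == 0] <- 1
  sweep(sweep(X, 2, ctr, "-"), 2, sc, "/")
}
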