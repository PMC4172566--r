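# Internal helpers: seeding, folds, RNG hygiene.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation (Lehmer-style mix, stays < 2^31 - 1).
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 99991) %% 2147483647
  as.integer(x + 1)
}

# Stratified fold assignment for a binary response; plain random folds
# otherwise. Returns an integer vector of fold ids in 1..k.
make_folds <- function(y, k, seed, stratify = TRUE) {
  n <- length(y)
  if (k < 2) stop("configuration error: need at least 2 folds")
  if (k > n) stop("configuration error: more folds than samples")
  folds <- integer(n)
  with_seed(seed, {
    if (stratify && length(unique(y)) == 2) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        if (length(idx) < k && length(idx) < 1) {
          stop("stratification error: class absent")
        }
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      folds[] <- sample(rep_len(seq_len(k), n))
    }
  })
  folds
}

check_binary <- function(y) {
  if (!all(y %in% c(0, 1))) {
    stop("invalid-response error: bernoulli family requires y in {0, 1}")
  }
  invisible(TRUE)
}

check_matrix <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) {
    stop("empty-input error: design matrix has zero rows or zero features")
  }
  if (!is.numeric(X)) stop("data-quality error: non-numeric design matrix")
  if (any(!is.finite(X))) {
    stop("data-quality error: non-finite values in design matrix")
  }
  X
}
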