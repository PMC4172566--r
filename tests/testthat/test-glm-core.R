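test_that("a penalized zero-variance feature always gets weight zero", {
  set.seed(11)
  X <- cbind(a = rnorm(30), const = rep(2.5, 30))
  y <- rbinom(30, 1, plogis(X[, 1]))
  for (kind in c("l1", "l2")) {
    m <- fit_glm(X, y, "bernoulli", penalty_spec(kind, 1))
    expect_identical(unname(m$weights["const"]), 0)
  }
})

test_that("overwhelming L1 penalty shrinks to the intercept-only model", {
  set.seed(12)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("g1", "g2")))
  y <- rbinom(20, 1, 0.7)
  m <- fit_glm(X, y, "bernoulli", penalty_spec("l1", 1e8))
  expect_equal(unname(m$weights), c(0, 0))
  expect_equal(m$intercept, qlogis(mean(y)), tolerance = 1e-6)
  yg <- rnorm(20, 3)
  mg <- fit_glm(X, yg, "gaussian", penalty_spec("l1", 1e8))
  expect_equal(unname(mg$weights), c(0, 0))
  expect_equal(mg$intercept, mean(yg), tolerance = 1e-8)
})

test_that("fit matches the brute-force grid oracle on small instances", {
  # randomized small instances across families and penalties; the fitted
  # objective must not exceed the dense grid minimum by more than 1e-3
  set.seed(13)
  configs <- expand.grid(family = c("bernoulli", "gaussian"),
                         kind = c("l1", "l2"),
                         strength = c(0.05, 0.5),
                         stringsAsFactors = FALSE)
  n_rep <- 3
  count <- 0
  for (r in seq_len(nrow(configs))) {
    cfg <- configs[r, ]
    for (rep in seq_len(n_rep)) {
      n <- sample(4:8, 1)
      p <- sample(1:2, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- if (cfg$family == "bernoulli") {
        y0 <- rbinom(n, 1, 0.5)
        # glmnet needs two observations per class
        y0[1:2] <- c(0, 1)
        y0[3:4] <- c(1, 0)
        y0
      } else {
        rnorm(n)
      }
      m <- fit_glm(X, y, cfg$family, penalty_spec(cfg$kind, cfg$strength))
      Xs <- oracle_standardize(X)
      obj_fit <- oracle_objective(Xs, y, m$weights, m$intercept,
                                  cfg$family, cfg$kind, cfg$strength)
      obj_grid <- oracle_grid_min(Xs, y, cfg$family, cfg$kind, cfg$strength)
      expect_lte(obj_fit, obj_grid + 1e-3)
      count <- count + 1
    }
  }
  expect_gte(count, 20)
})

test_that("bernoulli L2 fit on 6 samples matches a fine grid search", {
  set.seed(14)
  X <- matrix(rnorm(12), 6, 2)
  y <- c(0, 1, 0, 1, 1, 0)
  m <- fit_glm(X, y, "bernoulli", penalty_spec("l2", 0.5))
  Xs <- oracle_standardize(X)
  obj_fit <- oracle_objective(Xs, y, m$weights, m$intercept,
                              "bernoulli", "l2", 0.5)
  obj_grid <- oracle_grid_min(Xs, y, "bernoulli", "l2", 0.5,
                              lim = 2, n_grid = 81)
  expect_lte(obj_fit, obj_grid + 1e-3)
})

test_that("the returned solution beats the all-zero weight vector", {
  set.seed(15)
  for (rep in 1:5) {
    X <- matrix(rnorm(60), 20, 3)
    y <- rbinom(20, 1, plogis(X[, 1] - X[, 2]))
    if (length(unique(y)) < 2) next
    for (kind in c("l1", "l2")) {
      m <- fit_glm(X, y, "bernoulli", penalty_spec(kind, 0.1))
      Xs <- oracle_standardize(X)
      obj_fit <- oracle_objective(Xs, y, m$weights, m$intercept,
                                  "bernoulli", kind, 0.1)
      obj_zero <- oracle_objective(Xs, y, rep(0, 3), qlogis(mean(y)),
                                   "bernoulli", kind, 0.1)
      expect_lte(obj_fit, obj_zero + 1e-10)
    }
  }
})

test_that("prediction applies the inverse link and standardization", {
  set.seed(16)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("g1", "g2")))
  y <- rbinom(20, 1, 0.5)
  m <- fit_glm(X, y, "bernoulli", penalty_spec("l2", 0.5))
  # all-zero weights and intercept -> every probability exactly 0.5
  m0 <- m
  m0$weights[] <- 0
  m0$intercept <- 0
  expect_equal(unname(predict(m0, X)), rep(0.5, 20))
  # gaussian identity link arithmetic with standardization disabled
  mg <- fit_glm(X, rnorm(20), "gaussian", penalty_spec("none"))
  mg$weights[] <- c(2, -1)
  mg$intercept <- 3
  mg$center[] <- 0
  mg$scale[] <- 1
  expect_equal(unname(predict(mg, matrix(c(1, 1), 1, 2,
    dimnames = list(NULL, c("g1", "g2"))))), 4)
  # row-independence: batch prediction equals per-row prediction
  X5 <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("g1", "g2")))
  batch <- predict(m, X5)
  one <- vapply(1:5, function(i) predict(m, X5[i, , drop = FALSE]), 0)
  expect_equal(unname(batch), unname(one))
})

test_that("predictions are scale-invariant and probabilities stay in (0,1)", {
  set.seed(17)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("g1", "g2")))
  y <- as.integer(X[, 1] > 0)  # separable
  X2 <- X
  X2[, 1] <- X2[, 1] * 2  # doubled feature scale
  for (pen in list(penalty_spec("l2", 0.1), penalty_spec("none"))) {
    m1 <- fit_glm(X, y, "bernoulli", pen)
    m2 <- fit_glm(X2, y, "bernoulli", pen)
    expect_equal(predict(m1, X), predict(m2, X2), tolerance = 1e-6)
    p <- predict(m1, X)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("rank_features orders by |weight| with input-order ties, zeros last", {
  m <- structure(list(
    family = "gaussian",
    weights = c(a = 0.1, b = -3, c = 0),
    intercept = 0, penalty = "l1", penalty_strength = 1,
    feature_ids = c("a", "b", "c"),
    center = c(a = 0, b = 0, c = 0), scale = c(a = 1, b = 1, c = 1)
  ), class = "glm_model")
  expect_identical(rank_features(m), c("b", "a", "c"))
  m$weights <- c(a = 1, b = -1, c = 1)
  expect_identical(rank_features(m), c("a", "b", "c"))
  # always a permutation of the model's features
  set.seed(18)
  X <- matrix(rnorm(100), 20, 5,
              dimnames = list(NULL, paste0("g", 1:5)))
  fit <- fit_glm(X, rnorm(20), "gaussian", penalty_spec("l1", 0.05))
  expect_setequal(rank_features(fit), fit$feature_ids)
  expect_error(rank_features(list()), "state error")
})

test_that("input validation rejects bad designs and responses", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_glm(X, c(rep(0, 5), rep(2, 5)), "bernoulli"),
               "invalid-response")
  expect_error(fit_glm(X[0, , drop = FALSE], numeric(0), "gaussian"),
               "empty-input")
  Xb <- X
  Xb[3, 1] <- NA
  expect_error(fit_glm(Xb, rnorm(10), "gaussian"), "data-quality")
  expect_error(fit_glm(X, rnorm(9), "gaussian"), "length")
})

test_that("lambda selection is deterministic and responds to signal", {
  set.seed(19)
  n <- 60
  X <- matrix(rnorm(n * 10), n, 10)
  # pure noise: the selected L1 strength kills (almost) every weight
  y_noise <- rbinom(n, 1, 0.5)
  lam <- select_lambda_cv(X, y_noise, "bernoulli", "l1", seed = 5)
  m <- fit_glm(X, y_noise, "bernoulli", penalty_spec("l1", lam))
  expect_lte(sum(m$weights != 0), 1)
  # strong signal: at least one weight survives
  y_sig <- as.integer(X[, 1] + X[, 2] > 0)
  lam2 <- select_lambda_cv(X, y_sig, "bernoulli", "l1", seed = 5)
  m2 <- fit_glm(X, y_sig, "bernoulli", penalty_spec("l1", lam2))
  expect_gte(sum(m2$weights != 0), 1)
  # same inputs and seed -> identical strength
  expect_identical(lam2, select_lambda_cv(X, y_sig, "bernoulli", "l1",
                                          seed = 5))
  expect_identical(lam, select_lambda_cv(X, y_noise, "bernoulli", "l1",
                                         seed = 5))
})

test_that("models serialize to JSON and back without loss", {
  set.seed(20)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("g1", "g2")))
  m <- fit_glm(X, rnorm(20), "gaussian", penalty_spec("l1", 0.1))
  path <- withr::local_tempfile(fileext = ".json")
  write_glm_model(m, path)
  m2 <- read_glm_model(path)
  expect_equal(predict(m2, X), predict(m, X))
  expect_identical(m2$feature_ids, m$feature_ids)
  expect_equal(m2$weights, m$weights)
})
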