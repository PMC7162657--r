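planted_features <- function(n = 200, p = 16, n_signal = 5, beta = 0.6,
                             seed = 1) {
  set.seed(seed)
  age <- runif(n, 8, 23)
  X <- matrix(rnorm(n * p), n, p)
  for (j in seq_len(n_signal)) X[, j] <- X[, j] + beta * as.numeric(scale(age))
  colnames(X) <- sprintf("f%02d", seq_len(p))
  cohort <- data.frame(age = age, sex = rbinom(n, 1, 0.5),
                       handedness = rbinom(n, 1, 0.9),
                       motion = runif(n, 0.02, 0.3), tbv = rnorm(n, 1100, 90),
                       network_strength = rnorm(n, 100, 10))
  list(X = X, cohort = cohort, signal = seq_len(n_signal))
}

test_that("age-rank split takes odd ranks with stable ties", {
  sp <- split_by_age_rank(c(10, 8, 12, 9, 13, 11))
  expect_identical(sort(c(10, 8, 12, 9, 13, 11)[sp$subset1]), c(8, 10, 12))
  sp5 <- split_by_age_rank(c(5, 4, 3, 2, 1))
  expect_identical(length(sp5$subset1), 3L)
  expect_identical(length(sp5$subset2), 2L)
  # identical ages keep input order: subject 2 outranks subject 4
  sp_tie <- split_by_age_rank(c(1, 7, 2, 7))
  expect_identical(sp_tie$subset1, c(1L, 2L))
  expect_identical(sp_tie$subset2, c(3L, 4L))
})

test_that("ridge reduces to OLS at lambda 0 and to the mean at huge lambda", {
  set.seed(20)
  X <- matrix(rnorm(200), 50, 4)
  y <- X %*% c(1, -2, 0.5, 0) + rnorm(50, 0, 0.1)
  fit0 <- ridge_train_predict(X, y, X, lambda = 0)
  ols <- lm.fit(cbind(1, ridge_train_predict(X, y, X, 0)$train_scaled), y)
  expect_lt(max(abs(fit0$predictions - ols$fitted.values)), 1e-10)

  fit_inf <- ridge_train_predict(X, y, X, lambda = 1e8)
  expect_lt(max(abs(fit_inf$predictions - mean(y))), 1e-3)
})

test_that("min-max scaling is fit on train and applied to test", {
  train <- matrix(c(2, 3, 4), 3, 1)
  test <- matrix(5, 1, 1)
  fit <- ridge_train_predict(train, c(1, 2, 3), test, 0)
  expect_equal(unname(fit$train_scaled[, 1]), c(0, 0.5, 1))
  sc <- fit$scaling
  expect_equal(unname((5 - sc$lo) / (sc$hi - sc$lo)), 1.5)

  const <- cbind(train, 7)
  expect_message(fc <- ridge_train_predict(const, c(1, 2, 3), cbind(test, 7),
                                           0.1, verbose = TRUE), "constant")
  expect_identical(unname(fc$train_scaled[, 2]), rep(0, 3))
})

test_that("the lambda grid enumerates 16 powers of two", {
  cfg <- prediction_config()
  expect_identical(length(cfg$lambda_grid), 16L)
  expect_equal(cfg$lambda_grid, 2^(-10:5))
  expect_error(prediction_config(lambda_grid = c(2, 1)), "increasing")
})

test_that("inner accuracy normalization matches the hand example", {
  mm <- ctrlenergy:::.normalize_acc
  # mean r (0.2, 0.4, 0.6) -> (0, 0.5, 1); 1/MAE (1/3, 1/2, 1) -> (0, 0.25, 1)
  acc <- mm(c(0.2, 0.4, 0.6), "minmax") + mm(1 / c(3, 2, 1), "minmax")
  expect_equal(acc, c(0, 0.75, 2))
  expect_identical(which.max(acc), 3L)  # last lambda wins
})

test_that("a dominant lambda is selected and ties favor regularization", {
  pf <- planted_features(n = 120, seed = 21)
  cfg <- prediction_config(n_permutations = 0, seed = 3)
  set.seed(3)
  sel <- inner_select_lambda(pf$X, pf$cohort$age, cfg)
  expect_true(sel$lambda %in% cfg$lambda_grid)
  best <- max(sel$accuracy)
  expect_identical(sel$lambda,
                   cfg$lambda_grid[max(which(sel$accuracy == best))])
  expect_error(inner_select_lambda(pf$X[1:3, ], pf$cohort$age[1:3], cfg),
               "at least 4")
})

test_that("nested prediction recovers a planted signal out of sample", {
  pf <- planted_features(n = 200, seed = 22)
  cfg <- prediction_config(n_permutations = 0, seed = 5)
  res <- nested_prediction(pf$X, pf$cohort, cfg)
  expect_false(anyNA(res$predictions))         # every subject predicted once
  expect_gt(res$mean_partial_r, 0.4)
  base_mae <- mean(abs(pf$cohort$age - mean(pf$cohort$age)))
  expect_lt(res$mean_mae, base_mae)

  # destroyed correspondence: no out-of-sample signal
  set.seed(6)
  perm_r <- replicate(10, {
    px <- pf$X[sample.int(200), ]
    nested_prediction(px, pf$cohort, cfg)$mean_partial_r
  })
  expect_lt(abs(mean(perm_r)), 0.15)
})

test_that("nested prediction is seed deterministic in random mode", {
  pf <- planted_features(n = 80, p = 8, seed = 23)
  cfg <- prediction_config(split_mode = "random", n_random_repeats = 3,
                           n_permutations = 0, seed = 11)
  r1 <- nested_prediction(pf$X, pf$cohort, cfg)
  r2 <- nested_prediction(pf$X, pf$cohort, cfg)
  expect_identical(r1$repeat_metrics, r2$repeat_metrics)
})

test_that("Haufe transform matches hand products and silences suppressors", {
  # identity covariance: a = w (data whitened so cov is exactly identity)
  set.seed(24)
  Z <- matrix(rnorm(4000), 2000, 2)
  Z <- sweep(Z, 2, colMeans(Z)) %*% solve(chol(cov(Z)))
  w <- c(0.3, -1)
  expect_equal(haufe_transform(w, Z), w, tolerance = 1e-10)

  # explicit covariance product: Sigma = [[2,1],[1,1]], w = (1,0) -> a = (2,1)
  S <- matrix(c(2, 1, 1, 1), 2)
  Y <- Z %*% chol(S)                        # cov(Y) is exactly S
  expect_equal(haufe_transform(c(1, 0), Y), c(2, 1), tolerance = 1e-10)

  # suppressor: shares noise with a signal feature but is unrelated to y
  set.seed(25)
  n <- 500
  y <- rnorm(n)
  e <- rnorm(n)
  X <- cbind(sapply(1:10, function(i) y + rnorm(n)), supp = e)
  X[, 1] <- y + e                            # suppressor cancels this noise
  fit <- ridge_train_predict(X, y, X, lambda = 0.01)
  a <- haufe_transform(fit$weights, fit$train_scaled)
  expect_gt(abs(fit$weights[11]), 0.01)      # raw weight is non-negligible
  expect_lt(abs(a[11]), quantile(abs(a[1:10]), 0.1))
})

test_that("no training information leaks from the test fold", {
  pf <- planted_features(n = 100, p = 8, seed = 26)
  tr <- 1:50; te <- 51:100
  f1 <- ridge_train_predict(pf$X[tr, ], pf$cohort$age[tr], pf$X[te, ], 1)
  X_corrupt <- pf$X
  X_corrupt[te, ] <- X_corrupt[te, ] * 100 + 7
  f2 <- ridge_train_predict(X_corrupt[tr, ], pf$cohort$age[tr],
                            X_corrupt[te, ], 1)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$scaling, f2$scaling)
  # lambda selection sees only the training half
  cfg <- prediction_config(n_permutations = 0)
  set.seed(1); l1 <- inner_select_lambda(pf$X[tr, ], pf$cohort$age[tr], cfg)
  set.seed(1); l2 <- inner_select_lambda(X_corrupt[tr, ], pf$cohort$age[tr], cfg)
  expect_identical(l1$lambda, l2$lambda)
})
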