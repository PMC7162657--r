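#' Configuration for brain-maturity prediction
#'
#' @param lambda_grid ridge penalties; default the 16 consecutive integer
#'   powers of two from `2^-10` to `2^5`.
#' @param split_mode `"age_rank"` (deterministic odd/even age-rank halves)
#'   or `"random"` (repeated random halves).
#' @param n_random_repeats repeats in random mode (default 100).
#' @param n_permutations permutations for significance (default 1000; 0
#'   disables).
#' @param inner_normalization how the inner-accuracy components (mean r and
#'   mean 1/MAE over the grid) are normalized before summing: `"minmax"`
#'   (default, bounded to `[0, 1]`) or `"zscore"`.
#' @param covariates cohort columns partialed out of the prediction
#'   correlation.
#' @param seed integer seed.
#' @return list of class `prediction_config`.
#' @export
prediction_config <- function(lambda_grid = 2^(-10:5),
                              split_mode = c("age_rank", "random"),
                              n_random_repeats = 100, n_permutations = 1000,
                              inner_normalization = c("minmax", "zscore"),
                              covariates = .default_covariates, seed = 1L) {
  if (is.unsorted(lambda_grid, strictly = TRUE))
    stop("lambda grid must be strictly increasing")
  structure(list(lambda_grid = lambda_grid,
                 split_mode = match.arg(split_mode),
                 n_random_repeats = n_random_repeats,
                 n_permutations = n_permutations,
                 inner_normalization = match.arg(inner_normalization),
                 covariates = covariates, seed = as.integer(seed)),
            class = "prediction_config")
}

#' Split subjects into halves by age rank
#'
#' Subjects are sorted by age (stable sort: ties keep input order) and the
#' odd ranks (1st, 3rd, ...) form subset 1, the even ranks subset 2.
#'
#' @param age numeric age vector, or a cohort data.frame with an `age`
#'   column.
#' @return list with integer index vectors `subset1`, `subset2`.
#' @export
split_by_age_rank <- function(age) {
  if (is.data.frame(age)) age <- age$age
  if (length(age) < 4) stop("need at least 4 subjects to split")
  ord <- order(age)                       # radix sort: stable for ties
  list(subset1 = ord[seq(1, length(age), by = 2)],
       subset2 = ord[seq(2, length(age), by = 2)])
}

.minmax_fit <- function(X) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  list(lo = lo, hi = hi, constant = hi == lo)
}

.minmax_apply <- function(X, sc) {
  out <- sweep(X, 2, sc$lo)
  rng <- sc$hi - sc$lo
  rng[sc$constant] <- 1
  out <- sweep(out, 2, rng, "/")
  out[, sc$constant] <- 0
  out
}

#' Ridge regression with train-only min-max feature scaling
#'
#' Each feature is linearly scaled to `[0, 1]` across the training set and
#' the same scaling parameters are applied to the test set (test values may
#' fall outside `[0, 1]`). The intercept is unpenalized (fit by centering);
#' coefficients are the closed form `(X'X + lambda I)^{-1} X'y` on the
#' centered scaled design. A feature constant on the training set is scaled
#' to zero.
#'
#' @param train_X,train_y training design and response.
#' @param test_X matrix to predict (may be the training design).
#' @param lambda ridge penalty (>= 0).
#' @param verbose message on constant training features (default FALSE).
#' @return list with `predictions`, `weights` (on the scaled design),
#'   `intercept`, `scaling`, `train_scaled`.
#' @export
ridge_train_predict <- function(train_X, train_y, test_X, lambda,
                                verbose = FALSE) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  if (lambda < 0) stop("lambda must be nonnegative")
  sc <- .minmax_fit(train_X)
  if (verbose && any(sc$constant))
    message(sprintf("%d constant training feature(s) scaled to 0", sum(sc$constant)))
  Xs <- .minmax_apply(train_X, sc)
  Ts <- .minmax_apply(test_X, sc)
  mx <- colMeans(Xs); my <- mean(train_y)
  Xc <- sweep(Xs, 2, mx)
  p <- ncol(Xc)
  beta <- solve(crossprod(Xc) + lambda * diag(p), crossprod(Xc, train_y - my))
  preds <- drop(sweep(Ts, 2, mx) %*% beta) + my
  list(predictions = preds, weights = drop(beta), intercept = my,
       scaling = sc, train_scaled = Xs)
}

.normalize_acc <- function(v, how) {
  if (how == "zscore") {
    s <- sd(v)
    if (s == 0) return(rep(0, length(v)))
    return((v - mean(v)) / s)
  }
  rng <- max(v) - min(v)
  if (rng == 0) return(rep(0, length(v)))
  (v - min(v)) / rng
}

#' Select the ridge penalty by inner two-fold cross-validation
#'
#' The training set is split into two inner folds (odd/even age rank, or at
#' random), each lambda on the grid is fit on one fold and evaluated on the
#' other (both directions), and the mean correlation r and mean MAE over the
#' two folds are recorded. The per-lambda accuracy is the sum of the
#' normalized mean r and the normalized mean 1/MAE (normalized across the
#' grid, min-max by default); the lambda maximizing this sum is selected,
#' ties broken toward the larger (more regularized) lambda.
#'
#' @param train_X,train_y training data (>= 4 subjects).
#' @param config a [prediction_config]; its `lambda_grid`,
#'   `inner_normalization` and `split_mode` are used (random inner splits
#'   draw from the current RNG stream).
#' @return list with `lambda`, `accuracy` (per-grid-point sums), `mean_r`,
#'   `mean_mae`.
#' @export
inner_select_lambda <- function(train_X, train_y, config = prediction_config()) {
  n <- length(train_y)
  if (n < 4) stop("need at least 4 training subjects for the inner split")
  if (config$split_mode == "random") {
    ord <- sample.int(n)
    half <- floor(n / 2)
    folds <- list(ord[seq_len(half)], ord[seq(half + 1, n)])
  } else {
    sp <- split_by_age_rank(train_y)
    folds <- list(sp$subset1, sp$subset2)
  }
  grid <- config$lambda_grid
  mean_r <- mean_mae <- numeric(length(grid))
  for (g in seq_along(grid)) {
    rs <- maes <- numeric(2)
    for (d in 1:2) {
      tr <- folds[[d]]; te <- folds[[3 - d]]
      fit <- ridge_train_predict(train_X[tr, , drop = FALSE], train_y[tr],
                                 train_X[te, , drop = FALSE], grid[g])
      r <- if (sd(fit$predictions) == 0) 0 else cor(fit$predictions, train_y[te])
      rs[d] <- r
      maes[d] <- mean(abs(fit$predictions - train_y[te]))
    }
    mean_r[g] <- mean(rs)
    mean_mae[g] <- mean(maes)
  }
  acc <- .normalize_acc(mean_r, config$inner_normalization) +
    .normalize_acc(1 / mean_mae, config$inner_normalization)
  best <- max(which(acc == max(acc)))    # ties toward stronger regularization
  list(lambda = grid[best], accuracy = acc, mean_r = mean_r, mean_mae = mean_mae)
}

.run_nested_once <- function(X, y, covs, config, outer = NULL) {
  n <- length(y)
  if (is.null(outer)) {
    if (config$split_mode == "random") {
      ord <- sample.int(n)
      half <- floor(n / 2)
      outer <- list(subset1 = ord[seq_len(half)], subset2 = ord[seq(half + 1, n)])
    } else outer <- split_by_age_rank(y)
  }
  preds <- rep(NA_real_, n)
  fold <- data.frame(fold = 1:2, lambda = NA_real_, r = NA_real_,
                     partial_r = NA_real_, mae = NA_real_)
  for (d in 1:2) {
    tr <- outer[[d]]; te <- outer[[3 - d]]
    lam <- inner_select_lambda(X[tr, , drop = FALSE], y[tr], config)$lambda
    fit <- ridge_train_predict(X[tr, , drop = FALSE], y[tr],
                               X[te, , drop = FALSE], lam)
    preds[te] <- fit$predictions
    fold$lambda[d] <- lam
    fold$r[d] <- if (sd(fit$predictions) == 0) 0 else cor(fit$predictions, y[te])
    fold$partial_r[d] <- partial_correlation(fit$predictions, y[te],
                                             covs[te, , drop = FALSE])$r
    fold$mae[d] <- mean(abs(fit$predictions - y[te]))
  }
  list(predictions = preds, fold = fold)
}

#' Nested two-fold cross-validated brain-maturity prediction
#'
#' Outer two-fold cross-validation (both directions, so every subject is
#' predicted exactly once per scheme) with the ridge penalty chosen by the
#' inner two-fold procedure on each training half. Reports per-fold
#' correlation, covariate-adjusted partial correlation and MAE (years). In
#' random mode the whole nested procedure is repeated on
#' `n_random_repeats` random half-splits and metrics averaged. When
#' `n_permutations > 0`, the feature-to-subject correspondence is permuted
#' and the full nested procedure rerun to obtain `(k + 1) / (n + 1)`
#' permutation p-values for the mean partial r and mean MAE.
#'
#' @param features subjects x features matrix (e.g. per-node control energy).
#' @param cohort cohort table providing `age` and the covariates.
#' @param config a [prediction_config].
#' @return list of class `prediction_result` with `predictions`,
#'   `fold_metrics`, `mean_partial_r`, `mean_mae`, `permutation_p_r`,
#'   `permutation_p_mae`, and in random mode `repeat_metrics`.
#' @export
nested_prediction <- function(features, cohort, config = prediction_config()) {
  X <- as.matrix(features)
  y <- cohort$age
  if (nrow(X) != length(y)) stop("features must be aligned to the cohort")
  covs <- cohort[, config$covariates, drop = FALSE]
  set.seed(config$seed)
  if (config$split_mode == "random") {
    reps <- vector("list", config$n_random_repeats)
    for (r in seq_len(config$n_random_repeats))
      reps[[r]] <- .run_nested_once(X, y, covs, config)
    rep_metrics <- do.call(rbind, lapply(seq_along(reps), function(r)
      cbind(repeat_id = r, reps[[r]]$fold)))
    main <- reps[[1]]
    out <- list(predictions = main$predictions, fold_metrics = main$fold,
                repeat_metrics = rep_metrics,
                mean_partial_r = mean(rep_metrics$partial_r),
                mean_mae = mean(rep_metrics$mae))
  } else {
    main <- .run_nested_once(X, y, covs, config)
    out <- list(predictions = main$predictions, fold_metrics = main$fold,
                mean_partial_r = mean(main$fold$partial_r),
                mean_mae = mean(main$fold$mae))
  }
  out$permutation_p_r <- out$permutation_p_mae <- NA_real_
  if (config$n_permutations > 0) {
    if (config$n_permutations < 100)
      stop("n_permutations must be at least 100 when significance is requested")
    perm_cfg <- config
    perm_cfg$split_mode <- "age_rank"   # deterministic scheme inside the loop
    perm_r <- perm_mae <- numeric(config$n_permutations)
    for (i in seq_len(config$n_permutations)) {
      px <- X[sample.int(nrow(X)), , drop = FALSE]
      pm <- .run_nested_once(px, y, covs, perm_cfg)
      perm_r[i] <- mean(pm$fold$partial_r)
      perm_mae[i] <- mean(pm$fold$mae)
    }
    out$permutation_p_r <-
      (sum(perm_r >= out$mean_partial_r) + 1) / (config$n_permutations + 1)
    out$permutation_p_mae <-
      (sum(perm_mae <= out$mean_mae) + 1) / (config$n_permutations + 1)
  }
  class(out) <- "prediction_result"
  out
}

#' Haufe transform of ridge weights into an activation pattern
#'
#' Decoding weights of a linear model are not directly interpretable as
#' regional importance; left-multiplying the weight vector by the feature
#' covariance matrix, `a = Sigma_X w`, converts them into an activation
#' (forward-model) pattern whose absolute value ranks feature importance and
#' silences suppressor features.
#'
#' @param weights weight vector (on the scaled design).
#' @param train_X the scaled training design the model was fit on.
#' @return numeric activation pattern, one value per feature.
#' @export
haufe_transform <- function(weights, train_X) {
  drop(stats::cov(as.matrix(train_X)) %*% weights)
}

#' Interpretive full-sample model with Haufe-transformed weights
#'
#' Trains a single ridge model on all subjects (penalty chosen by the inner
#' two-fold procedure on the full sample) and returns both the raw weights
#' and the Haufe-transformed activation pattern.
#'
#' @inheritParams nested_prediction
#' @return list with `lambda`, `weights`, `haufe_weights`.
#' @export
full_model_haufe <- function(features, cohort, config = prediction_config()) {
  X <- as.matrix(features)
  y <- cohort$age
  set.seed(config$seed)
  lam <- inner_select_lambda(X, y, config)$lambda
  fit <- ridge_train_predict(X, y, X, lam)
  list(lambda = lam, weights = fit$weights,
       haufe_weights = haufe_transform(fit$weights, fit$train_scaled))
}
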