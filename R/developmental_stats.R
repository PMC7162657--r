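.default_covariates <- c("sex", "handedness", "motion", "tbv", "network_strength")

.check_cohort <- function(feature, cohort, covariates) {
  if (length(feature) != nrow(cohort))
    stop("feature length must equal the number of cohort rows")
  missing_cols <- setdiff(c("age", covariates), names(cohort))
  if (length(missing_cols))
    stop("cohort table lacks columns: ", paste(missing_cols, collapse = ", "))
}

#' Developmental (age) generalized additive model for one feature
#'
#' Fits `feature ~ s(age) + covariates` with a penalized cubic regression
#' spline (basis dimension 10) and REML smoothness selection, the standard
#' way of modeling developmental trajectories that may be linear or
#' curvilinear. The smooth-term p-value is converted to a signed Z,
#' `Z = sign(partial r) * qnorm(p/2, lower.tail = FALSE)`, where the sign comes from the
#' linear partial correlation of the feature with age given the covariates
#' (GAM smooth statistics are unsigned; this reconstruction restores the
#' direction of the association). The partial r and its Fisher-z 95% CI are
#' reported as the linear effect size.
#'
#' @param feature numeric vector, one value per subject.
#' @param cohort data.frame with `age` and the covariate columns.
#' @param covariates character vector of linear covariate column names
#'   (default sex, handedness, motion, tbv, network_strength).
#' @param extra_covariates optional additional linear covariates, either a
#'   character vector of cohort columns or a named list/data.frame of
#'   vectors (e.g. modal controllability, modularity Q, participation).
#' @param feature_id label carried into the result.
#' @return list of class `gam_result` with `feature_id`, `z_value`,
#'   `p_value`, `q_value` (NA until [fdr_correct]), `partial_r`, `ci_low`,
#'   `ci_high`, `edf`, `fit`.
#' @export
fit_age_gam <- function(feature, cohort, covariates = .default_covariates,
                        extra_covariates = NULL, feature_id = "feature") {
  .check_cohort(feature, cohort, covariates)
  dat <- data.frame(.y = feature, cohort[, c("age", covariates), drop = FALSE])
  if (!is.null(extra_covariates)) {
    if (is.character(extra_covariates)) {
      dat <- cbind(dat, cohort[, extra_covariates, drop = FALSE])
      covariates <- c(covariates, extra_covariates)
    } else {
      extra <- as.data.frame(extra_covariates)
      dat <- cbind(dat, extra)
      covariates <- c(covariates, names(extra))
    }
  }
  if (anyNA(dat)) stop("missing values are not allowed in the age model")
  qrX <- qr(cbind(1, as.matrix(dat[, c("age", covariates), drop = FALSE])))
  if (qrX$rank < ncol(qrX$qr)) {
    cols <- c("(intercept)", "age", covariates)
    stop("rank-deficient design; collinear columns: ",
         paste(cols[qrX$pivot[seq(qrX$rank + 1, ncol(qrX$qr))]], collapse = ", "))
  }
  fml <- stats::as.formula(paste(".y ~ s(age, bs = \"cr\", k = 10) +",
                                 paste(covariates, collapse = " + ")))
  fit <- mgcv::gam(fml, data = dat, method = "REML")
  sm <- summary(fit)
  p <- max(sm$s.table[1, "p-value"], 1e-300)
  pc <- partial_correlation(feature, cohort$age,
                            dat[, covariates, drop = FALSE])
  z <- sign(pc$r) * qnorm(p / 2, lower.tail = FALSE)
  structure(list(feature_id = feature_id, z_value = z, p_value = p,
                 q_value = NA_real_, partial_r = pc$r,
                 ci_low = pc$ci_low, ci_high = pc$ci_high,
                 edf = unname(sm$s.table[1, "edf"]), fit = fit),
            class = "gam_result")
}

#' Cognition (executive-function) model for one feature
#'
#' Fits `feature ~ ef_score + s(age) + covariates`, reporting the linear
#' executive-function term: its p-value signed into a Z as in [fit_age_gam],
#' and the partial correlation of feature and executive score after removing
#' the spline-adjusted age trend and the covariates from both. Subjects with
#' a missing executive score are dropped with a message (mirroring cohorts
#' where a few subjects lack cognitive data).
#'
#' @inheritParams fit_age_gam
#' @return a `gam_result` for the executive-function term.
#' @export
fit_cognition_gam <- function(feature, cohort, covariates = .default_covariates,
                              feature_id = "feature") {
  .check_cohort(feature, cohort, covariates)
  if (!"ef_score" %in% names(cohort)) stop("cohort table lacks column ef_score")
  keep <- !is.na(cohort$ef_score)
  if (any(!keep)) {
    message(sprintf("dropping %d subject(s) with missing executive score", sum(!keep)))
    cohort <- cohort[keep, , drop = FALSE]
    feature <- feature[keep]
  }
  dat <- data.frame(.y = feature,
                    cohort[, c("age", "ef_score", covariates), drop = FALSE])
  if (anyNA(dat)) stop("missing values are not allowed in the cognition model")
  fml <- stats::as.formula(paste(".y ~ ef_score + s(age, bs = \"cr\", k = 10) +",
                                 paste(covariates, collapse = " + ")))
  fit <- mgcv::gam(fml, data = dat, method = "REML")
  sm <- summary(fit)
  p <- max(sm$p.table["ef_score", "Pr(>|t|)"], 1e-300)
  est <- sm$p.table["ef_score", "Estimate"]
  # partial r of feature vs EF given the spline-adjusted age + covariates
  base <- stats::as.formula(paste("~ s(age, bs = \"cr\", k = 10) +",
                                  paste(covariates, collapse = " + ")))
  rf <- resid(mgcv::gam(stats::update(base, .y ~ .), data = dat, method = "REML"))
  dat$.e <- dat$ef_score
  re <- resid(mgcv::gam(stats::update(base, .e ~ .), data = dat, method = "REML"))
  r <- cor(rf, re)
  ci <- .fisher_ci(r, n = nrow(dat), k = length(covariates) + 1)
  z <- sign(est) * qnorm(p / 2, lower.tail = FALSE)
  structure(list(feature_id = feature_id, z_value = z, p_value = p,
                 q_value = NA_real_, partial_r = r,
                 ci_low = ci[1], ci_high = ci[2],
                 edf = unname(sm$s.table[1, "edf"]), fit = fit),
            class = "gam_result")
}

.fisher_ci <- function(r, n, k, level = 0.95) {
  n_eff <- n - k
  if (n_eff - 3 <= 0) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  half <- qnorm(1 - (1 - level) / 2) / sqrt(n_eff - 3)
  tanh(c(z - half, z + half))
}

#' Linear partial correlation with Fisher-z confidence interval
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing each
#' on the covariates (plus intercept) by ordinary least squares. The 95% CI
#' uses the Fisher z transform with the effective sample size reduced by the
#' number of covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of covariates, or NULL.
#' @return list with `r`, `ci_low`, `ci_high`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  k <- if (is.null(covariates) || NCOL(covariates) == 0) 0 else NCOL(covariates)
  if (n <= k + 3) stop("need n > number of covariates + 3")
  if (k > 0) {
    Z <- cbind(1, as.matrix(covariates))
    rx <- resid(stats::lm.fit(Z, x))
    ry <- resid(stats::lm.fit(Z, y))
  } else {
    rx <- x - mean(x); ry <- y - mean(y)
  }
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("undefined correlation: constant residuals")
  r <- cor(rx, ry)
  ci <- .fisher_ci(r, n, k)
  list(r = r, ci_low = ci[1], ci_high = ci[2])
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `q_values` and logical `rejected` (`q_value <= q`).
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  qv <- p.adjust(p_values, method = "BH")
  list(q_values = qv, rejected = qv <= q)
}

#' Bootstrapped single-mediator analysis
#'
#' The predictor `x`, mediator `m` and outcome `y` are first residualized on
#' the covariates (OLS with intercept) and standardized to unit variance;
#' paths are then estimated by two OLS fits (`m ~ x` gives a; `y ~ m + x`
#' gives b and c-prime; `y ~ x` gives c) so that `indirect = a * b` and the
#' exact OLS identity `c = c' + a * b` holds. The indirect-effect confidence
#' interval is a percentile bootstrap over case resampling and the p-value is
#' the two-sided sign proportion of the bootstrap distribution.
#'
#' @param x,m,y numeric vectors of equal length.
#' @param covariates optional data.frame/matrix of nuisance covariates.
#' @param n_boot number of bootstrap resamples (>= 100; default 10000).
#' @param seed integer seed for the resampling.
#' @param level CI level (default 0.95).
#' @return list of class `mediation_result` with `path_a`, `path_b`,
#'   `path_c`, `path_c_prime`, `indirect`, `ci_low`, `ci_high`, `p_value`,
#'   `n_boot`.
#' @export
mediation_bootstrap <- function(x, m, y, covariates = NULL, n_boot = 10000,
                                seed = 1L, level = 0.95) {
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("x, m, y must have equal length")
  if (n_boot < 100) stop("n_boot must be at least 100")
  std_resid <- function(v) {
    if (!is.null(covariates) && NCOL(covariates) > 0) {
      v <- resid(stats::lm.fit(cbind(1, as.matrix(covariates)), v))
    } else v <- v - mean(v)
    s <- sd(v)
    if (s == 0) stop("degenerate residuals: zero variance")
    v / s
  }
  X <- std_resid(x); M <- std_resid(m); Y <- std_resid(y)
  paths <- function(X, M, Y) {
    sxx <- sum(X * X); sxm <- sum(X * M); sxy <- sum(X * Y)
    smm <- sum(M * M); smy <- sum(M * Y)
    a <- sxm / sxx
    det <- smm * sxx - sxm^2
    b <- (smy * sxx - sxy * sxm) / det
    cp <- (sxy * smm - smy * sxm) / det
    c(a = a, b = b, c = sxy / sxx, c_prime = cp)
  }
  pt_est <- paths(X, M, Y)
  set.seed(seed)
  boot <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    pb <- paths(X[idx] - mean(X[idx]), M[idx] - mean(M[idx]),
                Y[idx] - mean(Y[idx]))
    boot[i] <- pb["a"] * pb["b"]
  }
  ci <- unname(quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2)))
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  structure(list(path_a = unname(pt_est["a"]), path_b = unname(pt_est["b"]),
                 path_c = unname(pt_est["c"]),
                 path_c_prime = unname(pt_est["c_prime"]),
                 indirect = unname(pt_est["a"] * pt_est["b"]),
                 ci_low = ci[1], ci_high = ci[2], p_value = min(p, 1),
                 n_boot = n_boot),
            class = "mediation_result")
}

#' Mass-univariate age or cognition models over a feature matrix
#'
#' Applies [fit_age_gam] (or [fit_cognition_gam]) to every column of a
#' feature matrix and attaches BH-corrected q-values.
#'
#' @param features subjects x features numeric matrix.
#' @param cohort cohort table.
#' @param model `"age"` or `"cognition"`.
#' @param ... passed to the per-feature fit.
#' @return data.frame with one row per feature: `feature_id`, `z_value`,
#'   `p_value`, `q_value`, `rejected`, `partial_r`, `ci_low`, `ci_high`,
#'   `edf`.
#' @export
gam_table <- function(features, cohort, model = c("age", "cognition"), ...) {
  model <- match.arg(model)
  features <- as.matrix(features)
  ids <- colnames(features)
  if (is.null(ids)) ids <- sprintf("feature_%03d", seq_len(ncol(features)))
  fits <- lapply(seq_len(ncol(features)), function(j) {
    if (model == "age")
      fit_age_gam(features[, j], cohort, feature_id = ids[j], ...)
    else fit_cognition_gam(features[, j], cohort, feature_id = ids[j], ...)
  })
  out <- data.frame(
    feature_id = ids,
    z_value = vapply(fits, `[[`, numeric(1), "z_value"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    partial_r = vapply(fits, `[[`, numeric(1), "partial_r"),
    ci_low = vapply(fits, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(fits, `[[`, numeric(1), "ci_high"),
    edf = vapply(fits, `[[`, numeric(1), "edf"),
    stringsAsFactors = FALSE
  )
  fdr <- fdr_correct(out$p_value)
  out$q_value <- fdr$q_values
  out$rejected <- fdr$rejected
  out[, c("feature_id", "z_value", "p_value", "q_value", "rejected",
          "partial_r", "ci_low", "ci_high", "edf")]
}
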