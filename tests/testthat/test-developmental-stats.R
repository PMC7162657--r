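make_cohort_table <- function(n, seed) {
  set.seed(seed)
  data.frame(age = runif(n, 8, 23), sex = rbinom(n, 1, 0.5),
             handedness = rbinom(n, 1, 0.9), motion = runif(n, 0.02, 0.3),
             tbv = rnorm(n, 1100, 90), network_strength = rnorm(n, 100, 10),
             ef_score = rnorm(n))
}

test_that("age model recovers a planted linear decline", {
  co <- make_cohort_table(500, 1)
  feat <- -0.5 * scale(co$age) + rnorm(500)
  res <- fit_age_gam(as.numeric(feat), co)
  expect_lt(res$z_value, -4)
  expect_lt(res$partial_r, -0.3)
  expect_lt(res$p_value, 1e-4)
  expect_true(res$ci_low <= res$partial_r && res$partial_r <= res$ci_high)
  # linear generative effect: partial r matches covariate-adjusted Pearson r
  pc <- partial_correlation(as.numeric(feat), co$age,
                            co[, default_covs])
  expect_lt(abs(res$partial_r - pc$r), 1e-12)
})

test_that("spline captures a purely quadratic effect the partial r misses", {
  co <- make_cohort_table(500, 2)
  mid <- mean(range(co$age))
  feat <- 0.4 * scale((co$age - mid)^2) + rnorm(500)
  res <- fit_age_gam(as.numeric(feat), co)
  expect_lt(res$p_value, 0.01)
  expect_lt(abs(res$partial_r), 0.1)
  expect_gt(res$edf, 1.5)  # genuinely nonlinear smooth
})

test_that("age model errors on collinear or incomplete input", {
  co <- make_cohort_table(100, 3)
  co$dup <- co$motion
  expect_error(fit_age_gam(rnorm(100), co, extra_covariates = "dup"),
               "collinear")
  expect_error(fit_age_gam(rnorm(99), co), "length")
})

test_that("cognition model recovers a planted executive-function effect", {
  co <- make_cohort_table(500, 4)
  feat <- -0.2 * co$ef_score + rnorm(500)
  res <- fit_cognition_gam(feat, co)
  expect_lt(res$z_value, 0)
  expect_lt(res$p_value, 0.01)
  expect_lt(res$partial_r, 0)

  co2 <- co
  co2$ef_score[c(3, 7)] <- NA
  expect_message(res2 <- fit_cognition_gam(feat, co2), "2 subject")
  expect_s3_class(res2, "gam_result")
})

test_that("partial correlation matches the inverse-correlation-matrix oracle", {
  x <- rnorm(80)
  expect_equal(partial_correlation(x, x)$r, 1)

  set.seed(6)
  n <- 200
  Z <- matrix(rnorm(n * 3), n)
  x <- Z %*% c(1, 0.5, 0) + rnorm(n)
  y <- Z %*% c(0.5, 0, 1) + 0.3 * x + rnorm(n)
  r_pkg <- partial_correlation(as.numeric(x), as.numeric(y), Z)$r
  # oracle: partial correlation from the inverse correlation matrix
  R <- solve(cor(cbind(x, y, Z)))
  r_oracle <- -R[1, 2] / sqrt(R[1, 1] * R[2, 2])
  expect_equal(r_pkg, r_oracle, tolerance = 1e-10)

  expect_error(partial_correlation(rep(1, 50), rnorm(50)), "constant")
  expect_error(partial_correlation(rnorm(4), rnorm(4), matrix(rnorm(8), 4)),
               "covariates")
})

test_that("Fisher-z interval matches the hand calculation", {
  set.seed(8)
  # construct data with sample correlation exactly 0.5 at n = 103
  x <- rnorm(103)
  e <- resid(lm(rnorm(103) ~ x)); e <- e / sd(e)
  y <- 0.5 * (x - mean(x)) / sd(x) + sqrt(1 - 0.25) * e
  pc <- partial_correlation(x, y)
  expect_equal(pc$r, 0.5, tolerance = 1e-10)
  expect_equal(pc$ci_low, tanh(atanh(0.5) - 1.96 / 10), tolerance = 1e-3)
  expect_equal(pc$ci_high, tanh(atanh(0.5) + 1.96 / 10), tolerance = 1e-3)
  expect_equal(round(c(pc$ci_low, pc$ci_high), 2), c(0.34, 0.63))
})

test_that("BH correction matches the hand example and a brute-force oracle", {
  res <- fdr_correct(c(0.001, 0.01, 0.02, 0.04, 0.2), q = 0.05)
  expect_identical(res$rejected, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(fdr_correct(rep(1, 6))$rejected, rep(FALSE, 6))
  expect_true(fdr_correct(0.04)$rejected)
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")

  bh_oracle <- function(p) {  # step-up from the largest rank
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(9)
  worst <- 0
  for (i in 1:1000) {
    p <- runif(sample(2:30, 1))
    worst <- max(worst, max(abs(fdr_correct(p)$q_values - bh_oracle(p))))
  }
  expect_lt(worst, 1e-12)
})

test_that("mediation recovers a planted chain and obeys OLS identities", {
  set.seed(10)
  n <- 2000
  x <- rnorm(n)
  m <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  y <- 0.5 * m + sqrt(1 - 0.25) * rnorm(n)
  res <- mediation_bootstrap(x, m, y, n_boot = 2000, seed = 11)
  expect_equal(res$indirect, res$path_a * res$path_b, tolerance = 1e-12)
  expect_equal(res$path_c, res$path_c_prime + res$path_a * res$path_b,
               tolerance = 1e-10)
  expect_lt(abs(res$indirect - 0.30), 0.05)
  expect_gt(res$ci_low, 0)
  expect_lt(res$p_value, 0.01)

  res2 <- mediation_bootstrap(x, m, y, n_boot = 2000, seed = 11)
  expect_identical(res2$ci_low, res$ci_low)  # seed-deterministic bootstrap

  expect_error(mediation_bootstrap(x, m, y, n_boot = 50), "at least 100")
  expect_error(mediation_bootstrap(x, rep(1, n), y, n_boot = 200),
               "degenerate")
})

test_that("independent mediator yields a null indirect effect", {
  set.seed(12)
  n <- 500
  x <- rnorm(n); m <- rnorm(n); y <- 0.3 * x + rnorm(n)
  res <- mediation_bootstrap(x, m, y, n_boot = 1000, seed = 13)
  expect_lt(abs(res$indirect), 0.1)
  expect_true(res$ci_low <= 0 && res$ci_high >= 0)
})

test_that("gam_table attaches BH q-values across features", {
  co <- make_cohort_table(150, 14)
  set.seed(15)
  feats <- cbind(signal = as.numeric(-0.6 * scale(co$age) + 0.5 * rnorm(150)),
                 noise1 = rnorm(150), noise2 = rnorm(150))
  tab <- gam_table(feats, co, model = "age")
  expect_identical(nrow(tab), 3L)
  expect_true(tab$rejected[tab$feature_id == "signal"])
  expect_true(all(tab$q_value >= 0 & tab$q_value <= 1))
})
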