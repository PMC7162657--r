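test_that("generated connectomes satisfy the structural invariants", {
  ch <- generate_cohort(cohort_spec(n_subjects = 5, n_nodes = 64, seed = 3))
  expect_length(ch$connectomes, 5)
  for (cn in ch$connectomes) {
    W <- cn$weights
    expect_identical(dim(W), c(64L, 64L))
    expect_identical(max(abs(W - t(W))), 0)
    expect_identical(unname(diag(W)), rep(0, 64))
    expect_gte(min(W[upper.tri(W)]), 0)
  }
  expect_identical(length(ch$partition), 64L)
  expect_identical(sort(unique(ch$partition)),
                   sort(names(cohort_spec()$partition_sizes)))
  # within-system block weights exceed between-system weights in expectation
  W <- ch$connectomes[[1]]$weights
  same <- outer(ch$partition, ch$partition, "==") & upper.tri(W)
  diff <- (!outer(ch$partition, ch$partition, "==")) & upper.tri(W)
  expect_gt(mean(W[same]), mean(W[diff]))
})

test_that("phenotype table is complete and motion declines with age", {
  ch <- generate_cohort(cohort_spec(n_subjects = 300, seed = 5))
  ph <- ch$phenotypes
  expect_identical(nrow(ph), 300L)
  expect_false(anyNA(ph))
  expect_true(all(ph$age >= 8 & ph$age <= 23))
  expect_true(all(ph$sex %in% 0:1))
  expect_lt(cor(ph$age, ph$motion), -0.15)
  expect_gt(ph$network_strength[1], 0)
})

test_that("planted age effect on within-FP connectivity is recovered", {
  ch <- generate_cohort(cohort_spec(n_subjects = 300, age_effect_gamma = 0.3,
                                    seed = 7))
  fp <- which(ch$partition == "fronto_parietal")
  wfp <- vapply(ch$connectomes, function(cn) {
    blk <- cn$weights[fp, fp]
    mean(blk[upper.tri(blk)])
  }, numeric(1))
  expect_gt(cor(ch$phenotypes$age, wfp), 0.3)
  # monotone in expectation: regression slope positive
  expect_gt(coef(lm(wfp ~ ch$phenotypes$age))[2], 0)
})

test_that("no planted effect means nominal false-positive rate", {
  # 200 replicate gamma = 0 cohorts; age/within-FP association at alpha=0.05
  set.seed(17)
  seeds <- sample.int(1e6, 200)
  hits <- vapply(seeds, function(s) {
    ch <- generate_cohort(cohort_spec(n_subjects = 50, n_nodes = 16,
                                      partition_sizes = c(visual = 4, motor = 4,
                                                          fronto_parietal = 4,
                                                          default_mode = 4),
                                      age_effect_gamma = 0,
                                      cingulate_loading_c = 0, seed = s))
    fp <- which(ch$partition == "fronto_parietal")
    wfp <- vapply(ch$connectomes, function(cn) {
      blk <- cn$weights[fp, fp]
      mean(blk[upper.tri(blk)])
    }, numeric(1))
    stats::cor.test(ch$phenotypes$age, wfp)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.09)
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(cohort_spec(n_subjects = 4, seed = 42))
  b <- generate_cohort(cohort_spec(n_subjects = 4, seed = 42))
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$connectomes[[3]]$weights, b$connectomes[[3]]$weights)
  c2 <- generate_cohort(cohort_spec(n_subjects = 4, seed = 43))
  expect_false(identical(a$connectomes[[1]]$weights, c2$connectomes[[1]]$weights))
})

test_that("invalid specs are rejected with parameter errors", {
  expect_error(cohort_spec(within_weight_mean = -1), "positive")
  expect_error(cohort_spec(between_weight_mean = 0.5, within_weight_mean = 0.2),
               "below")
  expect_error(cohort_spec(age_range = c(23, 8)), "age_range")
  expect_error(cohort_spec(partition_sizes = c(visual = 10, fronto_parietal = 10),
                           n_nodes = 64), "sum")
  # multiplier driving weights nonpositive is reported with the subject
  expect_error(generate_cohort(cohort_spec(n_subjects = 10,
                                           cingulate_loading_c = 2, seed = 1)),
               "subject")
})

test_that("cohort write/read round trip is lossless", {
  dir <- withr::local_tempdir()
  ch <- generate_cohort(cohort_spec(n_subjects = 3, seed = 9))
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  for (i in 1:3) {
    expect_lt(max(abs(back$connectomes[[i]]$weights - ch$connectomes[[i]]$weights)),
              1e-12)
  }
  expect_equal(back$phenotypes$age, ch$phenotypes$age, tolerance = 1e-12)
  expect_identical(back$partition, ch$partition)
  expect_identical(back$cingulate_nodes, ch$cingulate_nodes)
})

test_that("read errors name the offending subject or column", {
  dir <- withr::local_tempdir()
  ch <- generate_cohort(cohort_spec(n_subjects = 3, seed = 9))
  write_cohort(ch, dir)
  file.remove(file.path(dir, "matrices", "sub-0002.tsv"))
  expect_error(read_cohort(dir), "sub-0002")

  dir2 <- withr::local_tempdir()
  write_cohort(ch, dir2)
  ph <- data.table::fread(file.path(dir2, "phenotypes.tsv"))
  ph$age[2] <- NA
  data.table::fwrite(ph, file.path(dir2, "phenotypes.tsv"), sep = "\t")
  expect_error(read_cohort(dir2), "age")
})
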