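# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- expr
  .fixture_env[[name]]
}

# modest planted cohort used across modules (gamma = 0.3 defaults)
small_cohort <- function() {
  fixture("small_cohort", generate_cohort(cohort_spec(n_subjects = 60, seed = 11)))
}

small_energy <- function() {
  fixture("small_energy", cohort_control_energy(small_cohort()$connectomes))
}

# random symmetric nonnegative zero-diagonal adjacency
random_adjacency <- function(n, density = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- if (density < 1) sample(ut, ceiling(length(ut) * density)) else ut
  A[on] <- runif(length(on), 0.05, 1)
  A + t(A)
}

default_covs <- c("sex", "handedness", "motion", "tbv", "network_strength")
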