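#' Specify a synthetic connectome cohort
#'
#' Defines the generative conditions for a seeded synthetic cohort of
#' weighted structural connectomes plus phenotypes. Connectomes are
#' block-modular: edge weights are lognormal-noised around a within-system or
#' between-system mean (heavy-tailed, mimicking tractography connection
#' probabilities). Three effects are planted: (i) within-fronto-parietal
#' edge weights grow multiplicatively with age, `(1 + gamma * (age - lo) /
#' (hi - lo))`; (ii) a standardized latent `L = a * z(age) + e` scales all
#' edges incident to two designated cingulate nodes inside the
#' fronto-parietal block by `(1 + c * L)`; (iii) the executive score is
#' `ef = b * L + f * z(age) + noise`, so the age -> connectivity -> executive
#' chain is carried by the connectomes themselves and any mediation signal
#' must travel through the downstream energy computation. Motion declines
#' with age (correlation about -0.3) to stress covariate adjustment.
#'
#' @param n_subjects number of subjects (default 300).
#' @param n_nodes number of nodes (default 64).
#' @param partition_sizes named integer vector of nodes per system; must sum
#'   to `n_nodes` and include a `fronto_parietal` entry of at least 2 (its
#'   first two nodes are the designated cingulate pair). Default: 8 equal
#'   systems.
#' @param age_range numeric length-2, years (default `c(8, 23)`).
#' @param within_weight_mean,between_weight_mean block weight means,
#'   `between < within`, both positive (defaults 0.15 / 0.05).
#' @param weight_noise_sd lognormal sigma of the multiplicative edge noise
#'   (default 0.5).
#' @param age_effect_gamma within-fronto-parietal age slope (default 0.3).
#' @param latent_loading_a,ef_loading_b,ef_age_loading_f,cingulate_loading_c
#'   standardized path coefficients of the planted mediation chain
#'   (defaults 0.5, 0.4, 0.3, 0.15).
#' @param seed integer seed (default 1).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 300, n_nodes = 64, partition_sizes = NULL,
                        age_range = c(8, 23),
                        within_weight_mean = 0.15, between_weight_mean = 0.05,
                        weight_noise_sd = 0.5, age_effect_gamma = 0.3,
                        latent_loading_a = 0.5, ef_loading_b = 0.4,
                        ef_age_loading_f = 0.3, cingulate_loading_c = 0.15,
                        seed = 1L) {
  if (is.null(partition_sizes)) {
    if (n_nodes %% 8 != 0)
      stop("parameter error: default partition needs n_nodes divisible by 8")
    partition_sizes <- setNames(rep(n_nodes / 8, 8),
                                c("visual", "motor", "dorsal_attention",
                                  "ventral_attention", "limbic",
                                  "fronto_parietal", "default_mode",
                                  "subcortical"))
  }
  spec <- list(n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
               partition_sizes = partition_sizes, age_range = age_range,
               within_weight_mean = within_weight_mean,
               between_weight_mean = between_weight_mean,
               weight_noise_sd = weight_noise_sd,
               age_effect_gamma = age_effect_gamma,
               latent_loading_a = latent_loading_a, ef_loading_b = ef_loading_b,
               ef_age_loading_f = ef_age_loading_f,
               cingulate_loading_c = cingulate_loading_c,
               seed = as.integer(seed))
  if (spec$n_subjects < 1) stop("parameter error: n_subjects must be positive")
  if (sum(partition_sizes) != spec$n_nodes)
    stop("parameter error: partition sizes must sum to n_nodes")
  if (!"fronto_parietal" %in% names(partition_sizes) ||
      partition_sizes[["fronto_parietal"]] < 2)
    stop("parameter error: partition needs a fronto_parietal block of >= 2 nodes")
  if (within_weight_mean <= 0 || between_weight_mean <= 0)
    stop("parameter error: weight means must be positive")
  if (between_weight_mean >= within_weight_mean)
    stop("parameter error: between_weight_mean must be below within_weight_mean")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("parameter error: age_range lower bound must be below upper bound")
  if (weight_noise_sd < 0) stop("parameter error: weight_noise_sd must be nonnegative")
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws the cohort defined by a [cohort_spec]: per-subject symmetric,
#' nonnegative, zero-diagonal weighted adjacency matrices with the planted
#' age and mediation effects, and a phenotype table (age, sex, handedness,
#' in-scanner motion, total brain volume, total network strength, executive
#' score). Fully reproducible from the spec seed.
#'
#' @param spec a [cohort_spec].
#' @return list of class `synthetic_cohort` with `connectomes` (list of
#'   [connectome]), `phenotypes` (data.frame), `partition`, `node_labels`,
#'   `cingulate_nodes` (indices of the designated mediator nodes) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  N <- spec$n_nodes
  sizes <- spec$partition_sizes
  partition <- rep(names(sizes), times = sizes)
  node_labels <- unlist(lapply(names(sizes), function(s)
    sprintf("%s_%02d", s, seq_len(sizes[[s]]))))
  fp <- which(partition == "fronto_parietal")
  cing <- fp[1:2]
  node_labels[cing] <- c("cingulate_L", "cingulate_R")

  lo <- spec$age_range[1]; hi <- spec$age_range[2]
  age <- runif(n, lo, hi)
  z_age <- if (n > 1 && sd(age) > 0) as.numeric(scale(age)) else numeric(n)
  sex <- rbinom(n, 1, 0.5)
  handedness <- rbinom(n, 1, 0.88)
  motion <- 0.15 * exp(0.4 * (-0.3 * z_age + sqrt(1 - 0.3^2) * rnorm(n)))
  tbv <- 1100 + 80 * sex + rnorm(n, 0, 90)
  a <- spec$latent_loading_a
  L <- a * z_age + sqrt(max(0, 1 - a^2)) * rnorm(n)
  b <- spec$ef_loading_b; f <- spec$ef_age_loading_f
  ef_resid_var <- 1 - b^2 - f^2 - 2 * a * b * f
  ef <- b * L + f * z_age + sqrt(max(0, ef_resid_var)) * rnorm(n)

  base <- matrix(spec$between_weight_mean, N, N)
  for (s in names(sizes)) {
    idx <- partition == s
    base[idx, idx] <- spec$within_weight_mean
  }
  sig <- spec$weight_noise_sd
  ut <- upper.tri(base)
  fp_mask <- matrix(FALSE, N, N); fp_mask[fp, fp] <- TRUE
  cing_mask <- matrix(FALSE, N, N)
  cing_mask[cing, ] <- TRUE; cing_mask[, cing] <- TRUE

  connectomes <- vector("list", n)
  strength <- numeric(n)
  for (i in seq_len(n)) {
    age_fac <- 1 + spec$age_effect_gamma * (age[i] - lo) / (hi - lo)
    cing_fac <- 1 + spec$cingulate_loading_c * L[i]
    if (age_fac <= 0 || cing_fac <= 0)
      stop(sprintf("generation error: nonpositive edge multiplier for subject %d", i))
    w <- matrix(0, N, N)
    # lognormal multiplicative noise with unit mean around the block means
    w[ut] <- base[ut] * exp(sig * rnorm(sum(ut)) - sig^2 / 2)
    w[ut][fp_mask[ut]] <- w[ut][fp_mask[ut]] * age_fac
    w[ut][cing_mask[ut]] <- w[ut][cing_mask[ut]] * cing_fac
    w <- w + t(w)
    connectomes[[i]] <- connectome(w, partition, node_labels)
    strength[i] <- sum(w[ut])
  }
  phen <- data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
                     age = age, sex = sex, handedness = handedness,
                     motion = motion, tbv = tbv,
                     network_strength = strength, ef_score = ef,
                     stringsAsFactors = FALSE)
  structure(list(connectomes = connectomes, phenotypes = phen,
                 partition = partition, node_labels = node_labels,
                 cingulate_nodes = cing, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects, %d nodes, %d systems (seed %d)\n",
              length(x$connectomes), length(x$partition),
              length(unique(x$partition)), x$spec$seed))
  invisible(x)
}

#' Write a cohort to a directory of delimited-text files
#'
#' Layout: `matrices/<subject_id>.tsv` (full N x N tab-separated matrix),
#' `manifest.tsv` (subject_id, path), `phenotypes.tsv`, and `partition.tsv`
#' (node_index 0-based, node_name, system_label). The round trip through
#' [read_cohort] reproduces matrices to text-serialization precision and the
#' phenotype table exactly as printed.
#'
#' @param cohort a `synthetic_cohort` (or compatible list).
#' @param directory output directory, created if needed.
#' @return invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(file.path(directory, "matrices"), recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$phenotypes$subject_id
  paths <- file.path("matrices", paste0(ids, ".tsv"))
  for (i in seq_along(ids)) {
    data.table::fwrite(as.data.frame(cohort$connectomes[[i]]$weights),
                       file.path(directory, paths[i]),
                       sep = "\t", col.names = FALSE)
  }
  manifest <- data.frame(subject_id = ids, path = paths, stringsAsFactors = FALSE)
  data.table::fwrite(manifest, file.path(directory, "manifest.tsv"), sep = "\t")
  data.table::fwrite(cohort$phenotypes, file.path(directory, "phenotypes.tsv"), sep = "\t")
  part <- data.frame(node_index = seq_along(cohort$partition) - 1L,
                     node_name = cohort$node_labels,
                     system_label = cohort$partition, stringsAsFactors = FALSE)
  data.table::fwrite(part, file.path(directory, "partition.tsv"), sep = "\t")
  invisible(manifest)
}

#' Read a cohort written by [write_cohort]
#'
#' @param directory directory containing `manifest.tsv`, `phenotypes.tsv`,
#'   `partition.tsv` and the per-subject matrices.
#' @return list of class `synthetic_cohort` (without the generating spec).
#' @export
read_cohort <- function(directory) {
  manifest <- as.data.frame(data.table::fread(file.path(directory, "manifest.tsv")))
  phen <- as.data.frame(data.table::fread(file.path(directory, "phenotypes.tsv")))
  part <- as.data.frame(data.table::fread(file.path(directory, "partition.tsv")))
  required <- c("age", "sex", "handedness", "motion", "tbv",
                "network_strength", "ef_score")
  for (col in intersect(required, names(phen))) {
    if (anyNA(phen[[col]]))
      stop(sprintf("validation error: missing values in phenotype column '%s'", col))
  }
  connectomes <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(directory, manifest$path[i])
    if (!file.exists(f))
      stop(sprintf("I/O error: matrix file missing for subject %s", manifest$subject_id[i]))
    w <- as.matrix(data.table::fread(f, header = FALSE))
    dimnames(w) <- NULL
    if (max(abs(w - t(w))) > 1e-8)
      stop(sprintf("validation error: non-symmetric matrix for subject %s",
                   manifest$subject_id[i]))
    w <- (w + t(w)) / 2  # remove any residual serialization asymmetry
    connectomes[[i]] <- connectome(w, part$system_label, part$node_name)
  }
  cing <- which(part$node_name %in% c("cingulate_L", "cingulate_R"))
  structure(list(connectomes = connectomes, phenotypes = phen,
                 partition = part$system_label, node_labels = part$node_name,
                 cingulate_nodes = if (length(cing)) cing else NULL,
                 spec = NULL),
            class = "synthetic_cohort")
}
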