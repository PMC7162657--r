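#' Default pipeline configuration
#'
#' A fully populated configuration for [run_pipeline] covering every stage:
#' cohort generation, control-energy computation, null-network comparison,
#' developmental and cognition models, maturity prediction and mediation.
#' Values can be overridden by supplying a partial list to `overrides` or by
#' editing the YAML written with `yaml::write_yaml`.
#'
#' @param overrides named list of sections/values overriding the defaults.
#' @return nested list with sections `cohort`, `control`, `nulls`, `gam`,
#'   `prediction`, `mediation` plus `seed` and `output_dir`.
#' @export
default_pipeline_config <- function(overrides = NULL) {
  cfg <- list(
    seed = 1L,
    output_dir = "ctrlenergy_out",
    cohort = list(n_subjects = 300, n_nodes = 64, age_effect_gamma = 0.3,
                  within_weight_mean = 0.15, between_weight_mean = 0.05,
                  weight_noise_sd = 0.5, latent_loading_a = 0.5,
                  ef_loading_b = 0.4, ef_age_loading_f = 0.3,
                  cingulate_loading_c = 0.15),
    control = list(target_system = "fronto_parietal",
                   constrain = "target_system", rho = 1,
                   horizon_T = 1, dt = 0.001),
    nulls = list(n_null = 20),
    gam = list(covariates = .default_covariates),
    prediction = list(split_mode = "age_rank", n_random_repeats = 100,
                      n_permutations = 0),
    mediation = list(n_boot = 10000)
  )
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  cfg
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or an in-memory list. All problems are collected
#' and reported together (not fail-fast); unknown keys produce warnings and
#' the run proceeds, type or range violations are errors.
#'
#' @param config path to a YAML file, or a nested list.
#' @return the parsed configuration (with defaults filled for any omitted
#'   values inside present sections), or an error listing every problem.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  errors <- character()
  known <- names(default_pipeline_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  for (sec in c("cohort", "control", "nulls", "gam", "prediction", "mediation"))
    if (is.null(config[[sec]]))
      errors <- c(errors, sprintf("missing section '%s'", sec))
  if (is.null(config$seed)) errors <- c(errors, "missing 'seed'")
  if (is.null(config$output_dir)) errors <- c(errors, "missing 'output_dir'")
  num_rules <- list(
    c("control", "rho", "rho must be positive"),
    c("control", "dt", "dt must be positive"),
    c("control", "horizon_T", "horizon_T must be positive"),
    c("cohort", "n_subjects", "n_subjects must be positive"),
    c("nulls", "n_null", "n_null must be positive"),
    c("mediation", "n_boot", "n_boot must be positive")
  )
  for (rule in num_rules) {
    v <- config[[rule[1]]][[rule[2]]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      errors <- c(errors, rule[3])
  }
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  modifyList(default_pipeline_config(), config)
}

.stage <- function(name, log_con, expr) {
  t0 <- Sys.time()
  msg <- sprintf("[%s] stage '%s' started", format(t0), name)
  writeLines(msg, log_con); message(msg)
  out <- tryCatch(expr, error = function(e) {
    fail <- sprintf("stage '%s' failed: %s", name, conditionMessage(e))
    writeLines(fail, log_con)
    close(log_con)
    stop(fail, call. = FALSE)
  })
  writeLines(sprintf("[%s] stage '%s' done (%.1f s)", format(Sys.time()), name,
                     as.numeric(difftime(Sys.time(), t0, units = "secs"))),
             log_con)
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates, in order: cohort simulation, per-subject optimal control
#' energy, the null-network comparison, mass-univariate age and cognition
#' models with FDR, nested cross-validated maturity prediction, and the
#' mediation analysis (age -> mean cingulate-node energy -> executive
#' score). Each stage writes a tab-separated table into the output directory
#' and a run log records seeds, parameters and timings. Per-stage seeds are
#' derived from the global seed by fixed offsets, so reruns with an
#' identical configuration are byte-identical. A failing stage aborts with
#' the stage name, keeping partial outputs and the log.
#'
#' @param config a configuration list or YAML path (see [validate_config],
#'   [default_pipeline_config]).
#' @return invisibly, a list with the output directory, the key tables and
#'   summary statistics.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(cfg$output_dir, "run_log.txt"), open = "wt")
  writeLines(c(sprintf("ctrlenergy %s | R %s", as.character(utils::packageVersion("ctrlenergy")),
                       getRversion()),
               sprintf("global seed: %d", cfg$seed),
               yaml::as.yaml(cfg[c("cohort", "control", "nulls", "prediction",
                                   "mediation")])), log_con)
  tsv <- function(x, name) {
    data.table::fwrite(as.data.frame(x), file.path(cfg$output_dir, name), sep = "\t")
  }

  cohort <- .stage("simulate", log_con, {
    spec <- do.call(cohort_spec, c(cfg$cohort, list(seed = cfg$seed)))
    ch <- generate_cohort(spec)
    write_cohort(ch, file.path(cfg$output_dir, "cohort"))
    ch
  })
  phen <- cohort$phenotypes

  energy <- .stage("energy", log_con, {
    en <- cohort_control_energy(cohort$connectomes,
                                target_system = cfg$control$target_system,
                                constrain = cfg$control$constrain,
                                rho = cfg$control$rho,
                                horizon_T = cfg$control$horizon_T,
                                dt = cfg$control$dt)
    tsv(cbind(subject_id = phen$subject_id, as.data.frame(en$nodal)),
        "energy_nodal.tsv")
    tsv(cbind(subject_id = phen$subject_id, as.data.frame(en$system),
              whole_brain = en$whole_brain, total_distance = en$total_distance,
              terminal_error = en$terminal_error),
        "energy_summary.tsv")
    en
  })

  null_res <- .stage("null_comparison", log_con, {
    part <- cohort$partition
    x0 <- build_state(part, "baseline")
    xT <- build_state(part, "system_indicator", system = cfg$control$target_system)
    s_set <- if (cfg$control$constrain == "all") seq_along(part)
             else which(part == cfg$control$target_system)
    null_mean <- numeric(length(cohort$connectomes))
    for (i in seq_along(cohort$connectomes)) {
      ens <- null_ensemble(cohort$connectomes[[i]], n_null = cfg$nulls$n_null,
                           seed = cfg$seed + 1000L + i)
      e <- vapply(ens$surrogates, function(s) {
        An <- normalize_adjacency(s, mode = "control")
        sol <- solve_optimal_control(control_task(An, x0, xT, s_set,
                                                  horizon_T = cfg$control$horizon_T,
                                                  rho = cfg$control$rho,
                                                  dt = cfg$control$dt))
        mean(sol$nodal_energy)
      }, numeric(1))
      null_mean[i] <- mean(e)
    }
    test <- real_vs_null_energy_test(energy$whole_brain, null_mean)
    tsv(data.frame(subject_id = phen$subject_id,
                   real_energy = energy$whole_brain, null_mean_energy = null_mean),
        "null_energies.tsv")
    tsv(data.frame(t = test$t, df = test$df, p_value = test$p_value,
                   mean_diff = test$mean_diff), "null_test.tsv")
    c(test, list(null_mean = null_mean))
  })

  age_tab <- .stage("age_gam", log_con, {
    feats <- cbind(whole_brain = energy$whole_brain, energy$system, energy$nodal)
    tab <- gam_table(feats, phen, model = "age", covariates = cfg$gam$covariates)
    tab$level <- c("whole_brain", rep("system", ncol(energy$system)),
                   rep("node", ncol(energy$nodal)))
    tsv(tab, "age_gam.tsv")
    tab
  })

  cog_tab <- .stage("cognition_gam", log_con, {
    tab <- gam_table(energy$nodal, phen, model = "cognition",
                     covariates = cfg$gam$covariates)
    tsv(tab, "cognition_gam.tsv")
    tab
  })

  pred <- .stage("prediction", log_con, {
    pc <- prediction_config(split_mode = cfg$prediction$split_mode,
                            n_random_repeats = cfg$prediction$n_random_repeats,
                            n_permutations = cfg$prediction$n_permutations,
                            covariates = cfg$gam$covariates,
                            seed = cfg$seed + 2000L)
    res <- nested_prediction(energy$nodal, phen, pc)
    fm <- full_model_haufe(energy$nodal, phen, pc)
    tsv(data.frame(subject_id = phen$subject_id, age = phen$age,
                   predicted_age = res$predictions), "predictions.tsv")
    tsv(res$fold_metrics, "prediction_metrics.tsv")
    tsv(data.frame(node = colnames(energy$nodal), weight = fm$weights,
                   haufe_weight = fm$haufe_weights), "prediction_weights.tsv")
    c(res, list(full_model = fm))
  })

  med <- .stage("mediation", log_con, {
    m_feat <- rowMeans(energy$nodal[, cohort$cingulate_nodes, drop = FALSE])
    res <- mediation_bootstrap(phen$age, m_feat, phen$ef_score,
                               covariates = phen[, cfg$gam$covariates],
                               n_boot = cfg$mediation$n_boot,
                               seed = cfg$seed + 3000L)
    tsv(data.frame(path_a = res$path_a, path_b = res$path_b, path_c = res$path_c,
                   path_c_prime = res$path_c_prime, indirect = res$indirect,
                   ci_low = res$ci_low, ci_high = res$ci_high,
                   p_value = res$p_value, n_boot = res$n_boot), "mediation.tsv")
    res
  })

  writeLines(sprintf("[%s] pipeline complete", format(Sys.time())), log_con)
  close(log_con)
  invisible(list(output_dir = cfg$output_dir, cohort = cohort, energy = energy,
                 null_test = null_res, age_gam = age_tab, cognition_gam = cog_tab,
                 prediction = pred, mediation = med))
}
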