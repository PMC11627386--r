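#' Run the full MET analysis pipeline
#'
#' Simulates (or loads) a plot-level MET dataset, then runs every stage:
#' per-trial mixed models, the stage-2 FA order scan, varimax rotation and
#' latent-regression stability, AMMI and GGE on the (imputed) two-way
#' table, joint variance components with likelihood-ratio tests, and
#' loading-covariate correlations. Every tabular artifact is written as
#' CSV under `out_dir`, together with a JSON run manifest (parameters,
#' seed, package version) and, for simulated runs, the generating truth.
#'
#' @param config A [sim_config()], a list of its arguments, or a path to a
#'   YAML file holding them (plus optional `k_max`, `stable_band`,
#'   `responsive_threshold`).
#' @param out_dir Output directory (created if absent). `NULL` skips all
#'   file output.
#' @param data Optional pre-built [met_dataset()]; when given, `config` is
#'   only used for analysis settings and no simulation is run.
#' @param covariates Optional covariate table; defaults to
#'   [simulate_covariates()] on simulated runs.
#' @param k_max Highest FA order scanned (default 4, capped at s - 1).
#' @return A list with every intermediate object (`data`, `truth`,
#'   `stage1`, `means`, `search`, `rotated`, `stability`, `ammi`, `gge`,
#'   `joint_vc`, `lrt`, `covariate_report`, `files`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL, data = NULL,
                         covariates = NULL, k_max = 4) {
  extra <- list()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "sim_config")) {
    config <- as.list(config)
    extra <- config[setdiff(names(config), names(formals(sim_config)))]
    config <- do.call(sim_config, config[intersect(names(config),
                                                   names(formals(sim_config)))])
  }
  if (!is.null(extra$k_max)) k_max <- extra$k_max
  stable_band <- if (!is.null(extra$stable_band)) extra$stable_band else 0.5
  responsive_threshold <- if (!is.null(extra$responsive_threshold))
    extra$responsive_threshold else 1

  truth <- NULL
  if (is.null(data)) {
    sim <- simulate_met(config)
    data <- sim$data
    truth <- sim$truth
    if (is.null(covariates)) covariates <- simulate_covariates(truth)
  }

  files <- character(0)
  emit <- function(obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    readr::write_csv(tibble::as_tibble(obj), path)
    files[[name]] <<- path
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_phenotypes(data, file.path(out_dir, "pheno.csv"))
    files[["pheno.csv"]] <- file.path(out_dir, "pheno.csv")
    if (!is.null(covariates)) emit(covariates, "covariates.csv")
    if (!is.null(truth)) {
      jsonlite::write_json(
        list(Lambda_true = truth$Lambda_true, Psi_true = truth$Psi_true,
             scores_true = truth$scores_true, G_true = truth$G_true,
             env_means = truth$env_means, resid_sd = truth$resid_sd,
             mu = truth$mu, config = unclass(truth$config)),
        file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE)
      files[["truth.json"]] <- file.path(out_dir, "truth.json")
    }
  }

  stage1 <- fit_all_trials(data)
  emit(stage1$summary, "single_trial_summary.csv")
  means <- build_means_table(stage1$fits)
  blues_long <- predictably_long(means$means, "blue")
  emit(blues_long, "adjusted_means.csv")

  search <- model_search(means, k_range = seq_len(min(k_max, ncol(means$means) - 1)))
  emit(search$table, "model_comparison.csv")
  fit <- search$best
  emit(tibble::as_tibble(fit$Lambda, rownames = "environment"), "loadings.csv")
  emit(tibble::tibble(environment = names(fit$psi), psi = fit$psi),
       "specific_variances.csv")
  emit(tibble::as_tibble(genetic_correlations(fit), rownames = "environment"),
       "genetic_correlations.csv")
  preds <- predict_genotype_env(fit)
  emit(preds, "predicted_values.csv")

  rotated <- varimax_rotate(fit)
  stability <- latent_regression(rotated)
  stab_tab <- classify_stability(stability, stable_band = stable_band,
                                 responsive_threshold = responsive_threshold)
  emit(tibble::as_tibble(rotated$Lambda_rot, rownames = "environment"),
       "loadings_rotated.csv")
  emit(stab_tab, "stability.csv")
  emit(stability$plot_data, "latent_regression_points.csv")

  two_way <- impute_two_way(means$means, rank = min(fit$k, 2))
  pooled <- stats::weighted.mean(stage1$summary$sigma_e2, stage1$summary$n_gen)
  ammi <- fit_ammi(two_way, n_terms = min(4, min(dim(two_way)) - 1),
                   R = config$reps, sigma2 = pooled)
  emit(ammi$anova, "ammi_anova.csv")
  emit(ammi_stability(ammi), "ammi_ranking.csv")
  gge <- fit_gge(two_way, n_pcs = 2)
  emit(tibble::as_tibble(gge$genotype_coords, rownames = "genotype"),
       "gge_genotype_coords.csv")
  emit(tibble::as_tibble(gge$env_coords, rownames = "environment"),
       "gge_env_coords.csv")

  jvc <- fit_joint_vc(data)
  lrt <- lrt_effects(data)
  emit(tibble::as_tibble(jvc[c("sigma_g2", "sigma_gxe2", "sigma_e2",
                               "sigma_rep2", "sigma_p2", "CVg", "CVr", "CVp",
                               "CV_ratio", "r_ge", "r_i2", "H2_entry_mean",
                               "P_minus_G", "E", "R", "mean")]),
       "joint_variance_components.csv")
  emit(lrt, "lrt_effects.csv")

  cov_report <- NULL
  if (!is.null(covariates)) {
    cov_report <- loading_covariate_correlations(rotated, covariates)
    emit(cov_report$table, "loading_covariate_correlations.csv")
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(package = "famet",
           version = as.character(utils::packageVersion("famet")),
           r_version = R.version.string,
           seed = config$seed,
           config = unclass(config),
           k_max = k_max, k_best = search$k_best,
           stable_band = stable_band,
           responsive_threshold = responsive_threshold,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      file.path(out_dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
    files[["manifest.json"]] <- file.path(out_dir, "manifest.json")
  }

  invisible(list(data = data, truth = truth, covariates = covariates,
                 stage1 = stage1, means = means, search = search,
                 fit = fit, rotated = rotated, stability = stability,
                 stability_table = stab_tab, ammi = ammi, gge = gge,
                 joint_vc = jvc, lrt = lrt, covariate_report = cov_report,
                 files = files))
}

predictably_long <- function(M, value_name) {
  long <- expand.grid(genotype = rownames(M), environment = colnames(M),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long[[value_name]] <- M[cbind(match(long$genotype, rownames(M)),
                               match(long$environment, colnames(M)))]
  tibble::as_tibble(long[!is.na(long[[value_name]]), , drop = FALSE])
}
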