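#' Simulation configuration for a synthetic MET
#'
#' Parameters of the generating model used by [simulate_met()]. Defaults
#' emulate a cassava-style uniform-yield trial series: 22 genotypes in 20
#' year-by-location environments, RCBD with 3 replicates, fresh-root-yield
#' scale (grand mean ~24 t/ha), a 2-factor genetic covariance across
#' environments and heterogeneous residual variances tuned to give
#' single-trial Cullis heritabilities of roughly 0.5-0.8.
#'
#' @param m Number of genotypes.
#' @param s Number of environments (each environment is one trial).
#' @param k_true Number of latent genetic factors (`1 <= k_true <= s`,
#'   `k_true < m`).
#' @param reps Replicates per trial (RCBD).
#' @param mu Grand mean of the trait (t/ha for yields, % for DMC).
#' @param env_effects_sd SD of environment main effects.
#' @param loading_sd SD of factor loadings; the first factor's loadings are
#'   drawn positive (half-normal), mimicking a dominant common factor.
#' @param psi_range Range (low, high) of the uniform draw of
#'   environment-specific genetic variances psi.
#' @param resid_sd_range Range of the uniform draw of per-environment
#'   residual SDs.
#' @param rep_sd SD of replicate (block) effects within trials.
#' @param missing_cell_rate Fraction of genotype-by-environment cells
#'   removed completely at random (see [apply_unbalance()]).
#' @param min_env_coverage Minimum fraction of environments each genotype
#'   must retain under unbalance.
#' @param covariate_target_r Population correlation between the engineered
#'   covariate and the first-factor loadings (see [simulate_covariates()]).
#' @param trait Trait label attached to the records.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m = 22, s = 20, k_true = 2, reps = 3, mu = 24,
                       env_effects_sd = 5, loading_sd = 1.5,
                       psi_range = c(0.25, 1), resid_sd_range = c(1.5, 3),
                       rep_sd = 1, missing_cell_rate = 0.2,
                       min_env_coverage = 0.5, covariate_target_r = 0.58,
                       trait = "FRY", seed = 42) {
  cfg <- list(m = m, s = s, k_true = k_true, reps = reps, mu = mu,
              env_effects_sd = env_effects_sd, loading_sd = loading_sd,
              psi_range = psi_range, resid_sd_range = resid_sd_range,
              rep_sd = rep_sd, missing_cell_rate = missing_cell_rate,
              min_env_coverage = min_env_coverage,
              covariate_target_r = covariate_target_r,
              trait = match.arg(trait, FAMET_TRAITS), seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (k_true < 1 || k_true >= m) stop("need m > k_true >= 1", call. = FALSE)
    if (s < k_true) stop("need s >= k_true", call. = FALSE)
    if (reps < 1) stop("need reps >= 1", call. = FALSE)
    if (any(psi_range <= 0) || any(resid_sd_range <= 0)) {
      stop("psi_range and resid_sd_range must be positive", call. = FALSE)
    }
    if (missing_cell_rate < 0 || missing_cell_rate >= 1) {
      stop("missing_cell_rate must lie in [0, 1)", call. = FALSE)
    }
    if (min_env_coverage <= 0 || min_env_coverage > 1) {
      stop("min_env_coverage must lie in (0, 1]", call. = FALSE)
    }
    if (abs(covariate_target_r) >= 1) {
      stop("covariate_target_r must lie in (-1, 1)", call. = FALSE)
    }
  })
  invisible(cfg)
}

env_labels <- function(s) {
  years <- 2013 + (seq_len(s) - 1) %% 9
  sprintf("%d.E%02d", years, seq_len(s))
}

#' Simulate a plot-level multi-environment trial dataset
#'
#' Generates plot records under the factor-analytic generative model: the
#' genetic effect of genotype i in environment l is
#' `u_il = sum_r lambda_lr f_ir + delta_il` with scores `f ~ N(0, 1)` and
#' specific deviations `delta_il ~ N(0, psi_l)`, so the rows of the m x s
#' genetic-effect matrix have covariance `G = Lambda Lambda' + diag(psi)`
#' across environments. A plot value is
#' `mu + env_mean_l + rep_effect_lr + u_il + e`, with per-environment
#' residual SDs and per-trial replicate effects. Unbalance is applied via
#' [apply_unbalance()] when `missing_cell_rate > 0`.
#'
#' @param config A [sim_config()].
#' @return A list with `data` (a [met_dataset()]) and `truth` (a `sim_truth`
#'   list: `Lambda_true`, `Psi_true`, `scores_true`, `G_true`, `env_means`,
#'   `resid_sd`, `genetic_effects`, `mu`, `config`).
#' @export
simulate_met <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::local_seed(config$seed)
  m <- config$m; s <- config$s; k <- config$k_true
  genotypes <- sprintf("G%02d", seq_len(m))
  envs <- env_labels(s)

  Lambda <- matrix(rnorm(s * k, 0, config$loading_sd), s, k,
                   dimnames = list(envs, paste0("FA", seq_len(k))))
  Lambda[, 1] <- abs(Lambda[, 1])   # dominant first factor, mostly positive
  Psi <- runif(s, config$psi_range[1], config$psi_range[2])
  names(Psi) <- envs
  scores <- matrix(rnorm(m * k), m, k,
                   dimnames = list(genotypes, paste0("FA", seq_len(k))))
  delta <- sweep(matrix(rnorm(m * s), m, s), 2, sqrt(Psi), `*`)
  u <- scores %*% t(Lambda) + delta
  dimnames(u) <- list(genotypes, envs)
  env_means <- rnorm(s, 0, config$env_effects_sd)
  names(env_means) <- envs
  resid_sd <- runif(s, config$resid_sd_range[1], config$resid_sd_range[2])
  names(resid_sd) <- envs
  rep_eff <- matrix(rnorm(s * config$reps, 0, config$rep_sd), s, config$reps)

  grid <- expand.grid(genotype = genotypes, environment = envs,
                      replicate = seq_len(config$reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(grid$genotype, genotypes)
  ei <- match(grid$environment, envs)
  value <- config$mu + env_means[ei] + rep_eff[cbind(ei, grid$replicate)] +
    u[cbind(gi, ei)] + rnorm(nrow(grid), 0, resid_sd[ei])
  if (config$trait == "DMC") value <- pmin(pmax(value, 1), 99)

  records <- tibble::tibble(
    trial_id = grid$environment,
    environment = grid$environment,
    year = as.integer(substr(grid$environment, 1, 4)),
    location = sub("^[0-9]+\\.", "", grid$environment),
    genotype = grid$genotype,
    replicate = as.integer(grid$replicate),
    set_or_block = NA_character_,
    trait = config$trait,
    value = value
  )
  data <- met_dataset(records, trait = config$trait)

  truth <- structure(
    list(Lambda_true = Lambda, Psi_true = Psi, scores_true = scores,
         G_true = tcrossprod(Lambda) + diag(Psi),
         env_means = env_means, resid_sd = resid_sd,
         genetic_effects = u, mu = config$mu, config = config),
    class = "sim_truth"
  )

  if (config$missing_cell_rate > 0) {
    data <- apply_unbalance(data, rate = config$missing_cell_rate,
                            min_env_coverage = config$min_env_coverage,
                            seed = config$seed + 1L)
  }
  list(data = data, truth = truth)
}

#' Remove genotype-by-environment cells completely at random
#'
#' Emulates the unbalance of real trial series, where clones enter and
#' leave the network between years. Whole cells (all replicates of a
#' genotype in an environment) are removed in random order, subject to:
#' (a) every genotype retains at least `min_env_coverage` of the
#' environments, (b) every environment keeps at least 3 genotypes, and
#' (c) the environment-sharing graph stays connected. Removal is
#' reproducible from `seed`.
#'
#' @param data A [met_dataset()].
#' @param rate Target fraction of cells to remove, in \[0, 1).
#' @param min_env_coverage Minimum per-genotype environment coverage.
#' @param seed Integer seed.
#' @return The thinned [met_dataset()]; removed cells disappear from the
#'   records entirely (the cell was never planted).
#' @export
apply_unbalance <- function(data, rate, min_env_coverage = 0.5, seed = 1L) {
  stopifnot(inherits(data, "met_dataset"))
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(data)
  withr::local_seed(seed)
  inc <- data$incidence
  s <- ncol(inc)
  target <- floor(rate * sum(inc))
  min_envs <- ceiling(min_env_coverage * s)
  cells <- which(inc, arr.ind = TRUE)
  cells <- cells[sample.int(nrow(cells)), , drop = FALSE]
  removed <- 0L
  for (i in seq_len(nrow(cells))) {
    if (removed >= target) break
    r <- cells[i, 1]; c <- cells[i, 2]
    cand <- inc
    cand[r, c] <- FALSE
    if (sum(cand[r, ]) < min_envs) next
    if (sum(cand[, c]) < 3) next
    if (!incidence_connected(cand)) next
    inc <- cand
    removed <- removed + 1L
  }
  if (removed < target) {
    stop(sprintf(paste0("cannot remove %.0f%% of cells under the coverage/",
                        "connectivity constraints; maximum feasible rate ",
                        "here is %.2f"),
                 100 * rate, removed / sum(data$incidence)), call. = FALSE)
  }
  keep_cell <- inc[cbind(match(data$records$genotype, rownames(inc)),
                         match(data$records$environment, colnames(inc)))]
  met_dataset(data$records[keep_cell, , drop = FALSE], trait = data$trait)
}

incidence_connected <- function(inc) {
  shared <- t(inc) %*% inc
  adj <- (shared > 0) * 1L
  diag(adj) <- 0L
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(gr)$no == 1L
}

#' Simulate environmental covariates linked to the first factor
#'
#' Builds one engineered covariate (`Rain`, on a rainfall-like mm scale)
#' whose population correlation with the true first-factor loadings is
#' `target_r`, via the mixture `c = r z(Lambda_1) + sqrt(1 - r^2) noise` on
#' standardized vectors, plus independent nuisance covariates on plausible
#' meteorological scales (Tmax, Tmin, Tav, Rh, Wspeed, Solrad, Altitude).
#'
#' @param truth A `sim_truth` from [simulate_met()].
#' @param target_r Population correlation, |target_r| < 1.
#' @param seed Integer seed.
#' @return A covariate tibble (one row per environment) with attribute
#'   `achieved_r`, the realized sample correlation with `Lambda_true[, 1]`.
#' @export
simulate_covariates <- function(truth, target_r = truth$config$covariate_target_r,
                                seed = truth$config$seed + 2L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (abs(target_r) >= 1) stop("|target_r| must be < 1", call. = FALSE)
  s <- nrow(truth$Lambda_true)
  if (s < 3) stop("need at least 3 environments for a correlation target",
                  call. = FALSE)
  withr::local_seed(seed)
  z <- as.numeric(scale(truth$Lambda_true[, 1]))
  c_std <- target_r * z + sqrt(1 - target_r^2) * rnorm(s)
  tab <- tibble::tibble(
    environment = rownames(truth$Lambda_true),
    Tmax = rnorm(s, 30, 2),
    Tmin = rnorm(s, 20, 2),
    Tav = rnorm(s, 25, 1.5),
    Rain = 900 + 250 * c_std,
    Rh = rnorm(s, 75, 4),
    Wspeed = abs(rnorm(s, 2, 1)),
    Solrad = rnorm(s, 18, 2),
    Altitude = runif(s, 10, 800)
  )
  attr(tab, "achieved_r") <- cor(tab$Rain, truth$Lambda_true[, 1])
  tab
}
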