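test_that("structured REML log-likelihood matches the dense brute-force oracle", {
  for (sd in 1:5) {
    withr::with_seed(sd, {
      m <- 15; s <- 4; k <- 2
      L <- matrix(rnorm(s * k), s, k)
      psi <- runif(s, 0.2, 1)
      d <- runif(s, 0.05, 0.3)
      Y <- matrix(rnorm(m * s, 10), m, s,
                  dimnames = list(paste0("G", 1:m), paste0("E", 1:s)))
      Y[sample(length(Y), 6)] <- NA
      ll <- fa_loglik(Y, L, psi, d)
      oracle <- dense_fa_reml(Y, L, psi, d)
      expect_equal(ll, oracle, tolerance = 1e-8)
    })
  }
})

test_that("parameter counting follows the FA_k formula", {
  expect_identical(fa_n_params(10, 2), 29L)
  expect_identical(fa_n_params(10, 1), 20L)
  expect_identical(fa_n_params(10, 0), 10L)
  expect_identical(fa_n_params(10, 2, include_stage2_resid = TRUE), 39L)
  expect_error(fa_n_params(3, 4), "exceed")
})

test_that("means table validates incidence and connectivity", {
  M <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("G", 1:4), paste0("E", 1:3)))
  expect_s3_class(means_table(M), "means_table")
  M2 <- M
  M2[1:2, 3] <- NA
  expect_error(means_table(M2), "fewer than 3 genotypes")
  # two blocks of genotypes tested in disjoint environment sets
  M3 <- matrix(NA_real_, 6, 4,
               dimnames = list(paste0("G", 1:6), paste0("E", 1:4)))
  M3[1:3, 1:2] <- rnorm(6)
  M3[4:6, 3:4] <- rnorm(6)
  expect_error(means_table(M3), "disconnected")
})

test_that("build_means_table assembles trial BLUEs with missing cells", {
  d1 <- make_rcbd(m = 6, r = 2, seed = 1)
  d1$trial_id <- d1$environment <- "T1"
  d2 <- make_rcbd(m = 6, r = 2, seed = 2)
  d2$trial_id <- d2$environment <- "T2"
  d2 <- d2[d2$genotype != "G06", ]   # G06 only in T1
  fits <- list(fit_trial(d1), fit_trial(d2))
  mt <- build_means_table(fits)
  expect_equal(dim(mt$means), c(6, 2))
  expect_true(is.na(mt$means["G06", "T2"]))
  expect_false(anyNA(mt$means[, "T1"]))
  expect_length(mt$d, 2)
  expect_error(build_means_table(fits[1]), "at least 2")
})

strong <- sim_means(m = 80, s = 6, k_true = 2, seed = 41)

test_that("FA fit recovers rank-1 structure and dominates the truth in likelihood", {
  one <- sim_means(m = 200, s = 4, k_true = 1, seed = 42,
                   psi_range = c(1e-4, 2e-4), resid_sd_range = c(0.3, 0.6))
  fit1 <- fit_fa(one$means, k = 1)
  R <- genetic_correlations(fit1)
  expect_true(all(abs(R[upper.tri(R)]) > 0.95))

  fit <- fit_fa(strong$means, k = 2)
  ll_truth <- fa_loglik(strong$means, strong$truth$Lambda_true,
                        strong$truth$Psi_true, fit$d)
  expect_gte(fit$logREML + 1e-6, ll_truth)
  expect_true(fit$converged)
  # identifiability constraint: upper triangle of the unrotated loadings
  expect_lt(max(abs(fit$Lambda[upper.tri(fit$Lambda)])), 1e-12)
  # diag(G_hat) decomposes into communality + specific variance
  expect_equal(diag(fit$G_hat), rowSums(fit$Lambda^2) + fit$psi,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("near-saturated FA reproduces the sample covariance of environment columns", {
  sat <- sim_means(m = 150, s = 4, k_true = 2, seed = 43)
  fit <- fit_fa(sat$means, k = 3, stage2_resid = "none")
  S <- cov(sat$means$means)
  expect_lt(norm(fit$G_hat - S, "F") / norm(S, "F"), 0.05)
})

test_that("model search is AIC-consistent and nested in likelihood", {
  search <- model_search(strong$means, k_range = 1:3)
  expect_equal(search$k_best, 2)
  expect_true(all(diff(search$table$logREML) >= -1e-6))
  expect_equal(search$table$AIC,
               -2 * search$table$logREML + 2 * search$table$n_params)
  only1 <- model_search(strong$means, k_range = 1)
  expect_equal(only1$k_best, 1)
  expect_error(model_search(strong$means, k_range = 0:2), "k_range")
})

test_that("variance explained follows the trace formula and is additive", {
  fit <- list(Lambda = matrix(c(2, 2, 1), 3, 1), psi = c(0.5, 0.25, 0.25))
  expect_equal(variance_explained(fit)$overall, 90)
  fit0 <- list(Lambda = matrix(c(2, 2, 1), 3, 1), psi = rep(0, 3))
  expect_equal(variance_explained(fit0)$overall, 100)
  fit2 <- list(Lambda = cbind(c(2, 1, 1), c(0, sqrt(2), -1)),
               psi = c(0.4, 0.3, 0.3))
  ve <- variance_explained(fit2)
  expect_equal(unname(ve$per_factor), c(60, 30))
  expect_equal(sum(ve$per_factor), ve$overall)
  expect_error(variance_explained(list(Lambda = matrix(0, 2, 1),
                                       psi = c(0, 0))), "zero")
})

test_that("genetic correlations are unit-diagonal, sign-correct and PSD", {
  lam <- c(2, -1, 0.5)
  fit <- list(G_hat = tcrossprod(lam))
  R <- genetic_correlations(fit)
  expect_equal(abs(R[upper.tri(R)]), rep(1, 3), ignore_attr = TRUE)
  expect_equal(sign(R[1, 2]), -1)

  G0 <- diag(c(1, 2, 3))
  G0[1, 1] <- 1  # env with psi-only variance, zero loadings
  fitz <- list(G_hat = G0)
  Rz <- genetic_correlations(fitz)
  expect_equal(Rz[1, 2], 0)

  for (sd in 1:100) {
    withr::with_seed(sd, {
      s <- sample(3:8, 1); k <- sample(1:3, 1)
      G <- tcrossprod(matrix(rnorm(s * k), s, k)) + diag(runif(s, 0.01, 1))
    })
    ev <- eigen(genetic_correlations(list(G_hat = G)),
                symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("predictions fill every cell and beat column means in untested cells", {
  cfg <- sim_config(m = 60, s = 8, k_true = 2, missing_cell_rate = 0.25,
                    seed = 51)
  sim <- simulate_met(cfg)
  st1 <- fit_all_trials(sim$data)
  mt <- build_means_table(st1$fits)
  fit <- fit_fa(mt, k = 2)
  preds <- predict_genotype_env(fit)
  expect_equal(nrow(preds), 60 * 8)
  expect_false(anyNA(preds$predicted))

  obs <- preds$tested
  yobs <- mt$means[cbind(match(preds$genotype[obs], rownames(mt$means)),
                         match(preds$environment[obs], colnames(mt$means)))]
  expect_gt(cor(preds$predicted[obs], yobs), 0.9)

  # untested cells: compare to the true genetic effects; the FA prediction
  # must beat the environment-mean baseline (which carries no genotype info)
  un <- !obs
  truth_u <- sim$truth$genetic_effects[
    cbind(match(preds$genotype[un], rownames(sim$truth$genetic_effects)),
          match(preds$environment[un], colnames(sim$truth$genetic_effects)))]
  r_fa <- cor(preds$genetic_value[un], truth_u)
  r_base <- cor(rep(colMeans(mt$means, na.rm = TRUE)[preds$environment[un]],
                    1), truth_u)
  expect_gt(r_fa, max(r_base, 0))

  # a genotype with zero scores is predicted at the environment intercept
  fit0 <- fit
  fit0$blups_in_env["G01", ] <- 0
  fit0$fitted["G01", ] <- fit0$env_intercepts
  p0 <- predict_genotype_env(fit0)
  g1 <- p0[p0$genotype == "G01", ]
  expect_equal(g1$predicted,
               unname(fit0$env_intercepts[g1$environment]))
})

test_that("fit accuracy is 1 at perfect fit, high for strong signal, low under the null", {
  fit <- fit_fa(strong$means, k = 2)
  perfect <- fit
  perfect$fitted <- ifelse(is.na(strong$means$means),
                           perfect$fitted, strong$means$means)
  expect_equal(fit_accuracy(perfect, strong$means), 1)
  expect_gt(fit_accuracy(fit), 0.9)

  # pure noise: genotype effects carry no signal; holdout correlation ~ 0
  withr::with_seed(61, {
    Y <- matrix(rnorm(50 * 6, 20), 50, 6,
                dimnames = list(sprintf("G%02d", 1:50), paste0("E", 1:6)))
    hold <- matrix(FALSE, 50, 6)
    hold[sample(length(Y), 60)] <- TRUE
    Ytrain <- Y; Ytrain[hold] <- NA
  })
  fit_null <- fit_fa(means_table(Ytrain), k = 1, stage2_resid = "none")
  r_hold <- cor(fit_null$fitted[hold], Y[hold])
  expect_lt(abs(r_hold), 0.3)
  tiny <- matrix(NA_real_, nrow(fit$fitted), ncol(fit$fitted),
                 dimnames = dimnames(fit$fitted))
  tiny[1, 1] <- 1; tiny[2, 2] <- 2
  expect_error(fit_accuracy(fit, tiny), "at least 3 observed cells")
})

test_that("G_hat is invariant to orthonormal rotation of the loadings", {
  fit <- fit_fa(strong$means, k = 2)
  for (sd in 1:5) {
    Q <- withr::with_seed(sd, random_rotation(2))
    G_rot <- tcrossprod(fit$Lambda %*% Q) + diag(fit$psi)
    expect_equal(G_rot, fit$G_hat, tolerance = 1e-8, ignore_attr = TRUE)
  }
})
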