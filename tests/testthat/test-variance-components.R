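test_that("derived genetic parameters follow their closed forms", {
  m <- vc_metrics(sigma_g2 = 1, sigma_gxe2 = 2, sigma_e2 = 4, E = 2, R = 2,
                  mean = 10)
  expect_equal(m$sigma_p2, 3)
  expect_equal(m$H2_entry_mean, 1 / 3)
  expect_equal(m$CVg, 10)
  expect_equal(m$CVr, 20)
  expect_equal(m$CV_ratio, 0.5)
  expect_equal(m$r_i2, 2 / 7)
  expect_equal(vc_metrics(2, 2, 1, 3, 3, 10)$r_ge, 0.5)
  expect_equal(m$P_minus_G, 100 * sqrt(3) / 10 - 10)
})

test_that("ratio identities hold over random component values", {
  for (sd in 1:50) {
    p <- withr::with_seed(500 + sd, runif(3, 0.01, 5))
    m <- vc_metrics(p[1], p[2], p[3], E = 4, R = 3, mean = 20)
    expect_equal(m$r_ge + p[2] / (p[1] + p[2]), 1)
    expect_true(m$r_ge >= 0 && m$r_ge <= 1)
    expect_true(m$r_i2 >= 0 && m$r_i2 <= 1)
    expect_gte(m$sigma_p2, p[1])
    expect_gte(m$P_minus_G, 0)
  }
})

joint_sim <- local({
  cfg <- sim_config(m = 25, s = 6, k_true = 2, reps = 3,
                    missing_cell_rate = 0, seed = 111)
  simulate_met(cfg)
})

test_that("joint REML components match two-way ANOVA moments on balanced data", {
  # balanced crossed layout without replicate effects: REML equals the
  # expected-mean-squares estimators when the estimates are interior
  withr::with_seed(112, {
    m <- 15; s <- 5; r <- 3
    g <- rnorm(m, 0, sqrt(3))
    ge <- matrix(rnorm(m * s, 0, sqrt(1.5)), m, s)
    re <- matrix(rnorm(s * r, 0, 0.8), s, r)
    grid <- expand.grid(genotype = sprintf("G%02d", 1:m),
                        environment = paste0("E", 1:s), replicate = 1:r,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gi <- match(grid$genotype, sprintf("G%02d", 1:m))
    ei <- match(grid$environment, paste0("E", 1:s))
    grid$value <- 20 + g[gi] + ge[cbind(gi, ei)] + re[cbind(ei, grid$replicate)] +
      rnorm(nrow(grid))
  })
  grid$trial_id <- grid$environment
  grid$trait <- "FRY"
  grid$replicate <- as.integer(grid$replicate)
  data <- met_dataset(grid, "FRY")
  jvc <- fit_joint_vc(data)

  ms <- summary(aov(value ~ environment + factor(replicate):environment +
                      genotype + genotype:environment,
                    data = grid))[[1]]
  mse <- ms["Residuals", "Mean Sq"]
  ms_ge <- ms["environment:genotype", "Mean Sq"]
  ms_g <- ms["genotype", "Mean Sq"]
  sigma_gxe2 <- (ms_ge - mse) / 3
  sigma_g2 <- (ms_g - ms_ge) / (3 * 5)
  expect_gt(sigma_g2, 0); expect_gt(sigma_gxe2, 0)
  expect_equal(jvc$sigma_g2, sigma_g2, tolerance = 1e-4)
  expect_equal(jvc$sigma_gxe2, sigma_gxe2, tolerance = 1e-4)
  expect_equal(jvc$sigma_e2, mse, tolerance = 1e-3)
  expect_equal(jvc$E, 5)
  expect_equal(jvc$R, 3)
})

test_that("null interaction drives r_ge up and r_i2 down", {
  rge <- ri2 <- numeric(6)
  for (sd in 1:6) {
    cfg <- sim_config(m = 20, s = 5, k_true = 1, reps = 2,
                      psi_range = c(1e-6, 2e-6),
                      loading_sd = 2, missing_cell_rate = 0, seed = 600 + sd)
    sim <- simulate_met(cfg)
    # rank-1 with no specific variance still leaves some gxe; remove it by
    # making all loadings equal -> pure genotype main effect
    truth <- sim$truth
    rec <- sim$data$records
    lam1 <- truth$Lambda_true[, 1]
    ei <- match(rec$environment, names(lam1))
    gi <- match(rec$genotype, rownames(truth$scores_true))
    rec$value <- rec$value - truth$genetic_effects[cbind(gi, ei)] +
      mean(lam1) * truth$scores_true[gi, 1]
    jvc <- fit_joint_vc(met_dataset(rec, "FRY"))
    rge[sd] <- jvc$r_ge; ri2[sd] <- jvc$r_i2
  }
  expect_gt(mean(rge), 0.9)
  expect_lt(mean(ri2), 0.1)
})

test_that("LRT statistics are zero for identical fits and powerful under signal", {
  jvc_tab <- lrt_effects(joint_sim$data)
  expect_equal(nrow(jvc_tab), 2)
  expect_lt(jvc_tab$p_value[jvc_tab$term == "genotype"], 0.001)
  expect_lt(jvc_tab$p_value[jvc_tab$term == "genotype:environment"], 0.001)
  expect_true(all(jvc_tab$statistic >= 0))

  # statistic exactly 0 -> p = 1 (identical full and reduced likelihoods)
  mk <- function(stat) {
    if (stat <= 0) 1 else 0.5 * pchisq(stat, 1, lower.tail = FALSE)
  }
  expect_equal(mk(0), 1)
})

test_that("gxe LRT respects its nominal size under the null", {
  rejections <- 0
  n_rep <- 100
  for (sd in seq_len(n_rep)) {
    withr::with_seed(700 + sd, {
      m <- 12; s <- 4; r <- 2
      g <- rnorm(m, 0, 1.5)
      grid <- expand.grid(genotype = sprintf("G%02d", 1:m),
                          environment = paste0("E", 1:s), replicate = 1:r,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      gi <- match(grid$genotype, sprintf("G%02d", 1:m))
      grid$value <- 20 + g[gi] + rnorm(nrow(grid))
    })
    grid$trial_id <- grid$environment
    grid$trait <- "FRY"
    grid$replicate <- as.integer(grid$replicate)
    tab <- lrt_effects(met_dataset(grid, "FRY"))
    p <- tab$p_value[tab$term == "genotype:environment"]
    rejections <- rejections + (is.finite(p) && p < 0.05)
  }
  # boundary-corrected test: size should be near (at most) nominal
  expect_lte(rejections / n_rep, 0.12)
})

test_that("loading-covariate correlations match cor.test and flag short pairs", {
  withr::with_seed(113, {
    L <- matrix(rnorm(20), 10, 2,
                dimnames = list(paste0("E", 1:10), c("FA1", "FA2")))
  })
  covs <- tibble::tibble(environment = paste0("E", 1:10),
                         exact = L[, 1], noise = rnorm(10))
  rep <- loading_covariate_correlations(list(Lambda_rot = L), covs)
  expect_equal(rep$r["FA1", "exact"], 1, tolerance = 1e-12)
  expect_lt(rep$p["FA1", "exact"], 1e-12)
  expect_equal(rep$stars["FA1", "exact"], "***")
  ct <- cor.test(L[, 2], covs$noise)
  expect_equal(rep$r["FA2", "noise"], unname(ct$estimate))
  expect_equal(rep$p["FA2", "noise"], ct$p.value)

  covs$sparse <- c(rnorm(3), rep(NA, 7))
  rep2 <- loading_covariate_correlations(list(Lambda_rot = L), covs)
  expect_true(is.na(rep2$r["FA1", "sparse"]))
  expect_error(loading_covariate_correlations(
    list(Lambda_rot = L[1:3, ]),
    tibble::tibble(environment = paste0("E", 1:3), x = rnorm(3))),
    "fewer than 4")
})

test_that("the covariate t-test is calibrated and recovers an engineered signal", {
  s <- 55
  crit <- qnorm(0.975)
  rejections <- withr::with_seed(114, {
    sum(vapply(1:1000, function(i) {
      x <- rnorm(s); y <- rnorm(s)
      cor.test(x, y)$p.value < 0.05
    }, logical(1)))
  })
  band <- qnorm(0.975) * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rejections / 1000, 0.05 - band)
  expect_lt(rejections / 1000, 0.05 + band)

  cfg <- sim_config(m = 10, s = s, k_true = 2, missing_cell_rate = 0,
                    seed = 115)
  sim <- simulate_met(cfg)
  covs <- simulate_covariates(sim$truth, target_r = 0.58, seed = 116)
  rot <- list(Lambda_rot = sim$truth$Lambda_true)
  rep <- loading_covariate_correlations(rot, covs)
  expect_lt(abs(rep$r["FA1", "Rain"] - 0.58), 0.2)
})
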