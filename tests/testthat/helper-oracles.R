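# Shared fixtures and independent oracles, built in code at test time.

# Balanced RCBD plot table for one trial.
make_rcbd <- function(m = 8, r = 3, mu = 20, sigma_g = 2, sigma_r = 1,
                      sigma_e = 1.5, seed = 1, trait = "FRY") {
  withr::with_seed(seed, {
    g <- rnorm(m, 0, sigma_g)
    b <- rnorm(r, 0, sigma_r)
    grid <- expand.grid(genotype = sprintf("G%02d", 1:m), replicate = 1:r,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$value <- mu + g[match(grid$genotype, sprintf("G%02d", 1:m))] +
      b[grid$replicate] + rnorm(nrow(grid), 0, sigma_e)
    tibble::tibble(trial_id = "T1", environment = "T1",
                   genotype = grid$genotype,
                   replicate = as.integer(grid$replicate),
                   trait = trait, value = grid$value)
  })
}

# ANOVA moment estimators for a balanced RCBD (genotype and replicate
# crossed): sigma_g2 = (MS_G - MS_E) / r, sigma_e2 = MS_E.
anova_rcbd_oracle <- function(d) {
  fit <- aov(value ~ factor(genotype) + factor(replicate), data = d)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  r <- length(unique(d$replicate))
  m <- length(unique(d$genotype))
  list(sigma_g2 = (ms[1] - ms[3]) / r,
       sigma_r2 = (ms[2] - ms[3]) / m,
       sigma_e2 = ms[3])
}

# Dense brute-force REML log-likelihood of the stage-2 FA model: the full
# covariance over observed cells is assembled explicitly and the standard
# REML expression evaluated with dense solves.
dense_fa_reml <- function(Y, Lambda, psi, d) {
  s <- ncol(Y)
  C <- tcrossprod(Lambda) + diag(psi + d, s)
  N <- sum(!is.na(Y))
  V <- matrix(0, N, N)
  X <- matrix(0, N, s)
  y <- numeric(N)
  pos <- 0
  for (i in seq_len(nrow(Y))) {
    o <- which(!is.na(Y[i, ]))
    idx <- pos + seq_along(o)
    V[idx, idx] <- C[o, o]
    X[cbind(idx, o)] <- 1
    y[idx] <- Y[i, o]
    pos <- pos + length(o)
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r + (N - s) * log(2 * pi)))
}

# Random orthonormal k x k matrix (QR of a Gaussian matrix).
random_rotation <- function(k) {
  qrd <- qr(matrix(rnorm(k * k), k, k))
  Q <- qr.Q(qrd)
  Q %*% diag(sign(diag(qr.R(qrd))), k)
}

# Small simulated MET ready for the stage-2 fit.
sim_means <- function(m = 60, s = 6, k_true = 2, seed = 1, ...) {
  cfg <- sim_config(m = m, s = s, k_true = k_true, missing_cell_rate = 0,
                    seed = seed, ...)
  sim <- simulate_met(cfg)
  st1 <- fit_all_trials(sim$data)
  list(means = build_means_table(st1$fits), truth = sim$truth,
       data = sim$data, stage1 = st1)
}
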