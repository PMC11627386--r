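#' Construct a genotype-by-environment means table
#'
#' @param means Numeric genotype x environment matrix of adjusted means,
#'   `NA` for cells where a genotype was not tested. Needs row and column
#'   names.
#' @param se Optional matrix of the same shape with the standard errors of
#'   the means.
#' @param d Optional length-s vector of per-environment sampling variances
#'   of the means (the genotype-specific part, i.e. `var(m_i - m_j) / 2`);
#'   used as the fixed stage-2 residual by [fit_fa()]. Defaults to the
#'   column means of `se^2` when `se` is given.
#' @return An object of class `means_table`.
#' @export
means_table <- function(means, se = NULL, d = NULL) {
  means <- as.matrix(means)
  if (is.null(rownames(means)) || is.null(colnames(means))) {
    stop("means matrix needs genotype row names and environment column names",
         call. = FALSE)
  }
  if (ncol(means) < 2) stop("need at least 2 environments", call. = FALSE)
  n_per_env <- colSums(!is.na(means))
  if (any(n_per_env < 3)) {
    stop("environment(s) with fewer than 3 genotypes: ",
         paste(colnames(means)[n_per_env < 3], collapse = ", "),
         call. = FALSE)
  }
  inc <- !is.na(means)
  if (!incidence_connected(inc)) {
    shared <- t(inc) %*% inc
    adj <- (shared > 0) * 1L; diag(adj) <- 0L
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    small <- which(comp$membership == which.min(comp$csize))
    stop("environment incidence is disconnected; isolated component: ",
         paste(colnames(means)[small], collapse = ", "), call. = FALSE)
  }
  if (!is.null(se)) {
    se <- as.matrix(se)
    stopifnot(all(dim(se) == dim(means)))
  }
  if (is.null(d) && !is.null(se)) d <- colMeans(se^2, na.rm = TRUE)
  if (!is.null(d)) stopifnot(length(d) == ncol(means), all(d >= 0))
  structure(list(means = means, se = se, d = d), class = "means_table")
}

#' Assemble the stage-2 means table from stage-1 trial fits
#'
#' Environments are the trials; cells are the stage-1 BLUEs, missing where
#' a genotype was absent from a trial. Connectivity of the incidence is
#' validated.
#'
#' @param fits A list of [fit_trial()] objects (e.g. `fit_all_trials()$fits`).
#' @return A [means_table()] carrying per-cell standard errors.
#' @export
build_means_table <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 trial fits", call. = FALSE)
  envs <- vapply(fits, function(f) as.character(f$trial_id), character(1))
  genotypes <- sort(unique(unlist(lapply(fits, function(f) names(f$blues)))))
  M <- matrix(NA_real_, length(genotypes), length(envs),
              dimnames = list(genotypes, envs))
  S <- M
  for (j in seq_along(fits)) {
    f <- fits[[j]]
    M[names(f$blues), j] <- f$blues
    S[names(f$blues_se), j] <- f$blues_se
  }
  d <- vapply(fits, function(f) {
    if (!is.null(f$blue_d)) f$blue_d else NA_real_
  }, numeric(1))
  means_table(M, se = S, d = if (all(is.finite(d))) pmax(d, 0) else NULL)
}

#' Number of variance-covariance parameters of an FA_k model
#'
#' `s k - k (k - 1) / 2` free loadings (upper triangle of Lambda fixed at
#' zero for identifiability) plus `s` specific variances, plus `s` stage-2
#' residual variances when those are modeled as free parameters. `k = 0`
#' denotes the diagonal (independent-environments) model.
#'
#' @param s Number of environments.
#' @param k Factor order.
#' @param include_stage2_resid Count a free diagonal stage-2 residual.
#' @return Integer parameter count.
#' @export
fa_n_params <- function(s, k, include_stage2_resid = FALSE) {
  if (k > s) stop("k must not exceed s", call. = FALSE)
  n <- s * k - k * (k - 1) / 2 + s
  if (include_stage2_resid) n <- n + s
  as.integer(n)
}

# Pattern groups: genotypes sharing an observed-environment set are
# collapsed so each likelihood evaluation does one Cholesky per pattern.
fa_patterns <- function(Y) {
  obs <- !is.na(Y)
  key <- apply(obs, 1, function(z) paste(which(z), collapse = ","))
  idx <- split(seq_len(nrow(Y)), key)
  lapply(idx, function(rows) {
    o <- which(obs[rows[1], ])
    list(rows = rows, obs = o, Yt = t(Y[rows, o, drop = FALSE]))
  })
}

# Restricted log-likelihood of the stage-2 FA model at fixed parameters.
# Model: y_il = beta_l + u_il + e_il, rows of u iid N(0, LL' + diag(psi)),
# e_il ~ N(0, d_l); environment intercepts beta are the fixed effects
# profiled out by REML. Returns the pieces needed for fitting and BLUPs.
fa_reml_core <- function(patterns, Lambda, psi, d, want_blups = FALSE) {
  s <- nrow(Lambda)
  G <- tcrossprod(Lambda)
  diag(G) <- diag(G) + psi
  C <- G
  diag(C) <- diag(C) + d
  XtVX <- matrix(0, s, s)
  XtVy <- numeric(s)
  yVy <- 0
  logdet <- 0
  N <- 0L
  solves <- vector("list", length(patterns))
  for (p in seq_along(patterns)) {
    pat <- patterns[[p]]
    o <- pat$obs
    ch <- tryCatch(chol(C[o, o, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    ng <- length(pat$rows)
    logdet <- logdet + 2 * ng * sum(log(diag(ch)))
    CiY <- backsolve(ch, forwardsolve(t(ch), pat$Yt))
    Cinv <- chol2inv(ch)
    XtVX[o, o] <- XtVX[o, o] + ng * Cinv
    XtVy[o] <- XtVy[o] + rowSums(CiY)
    yVy <- yVy + sum(pat$Yt * CiY)
    N <- N + ng * length(o)
    if (want_blups) solves[[p]] <- list(Cinv = Cinv)
  }
  chX <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  beta <- backsolve(chX, forwardsolve(t(chX), XtVy))
  q <- yVy - sum(XtVy * beta)
  logdetX <- 2 * sum(log(diag(chX)))
  ll <- -0.5 * (logdet + logdetX + q + (N - s) * log(2 * pi))
  out <- list(ll = ll, beta = as.numeric(beta), N = N, G = G, C = C)
  if (want_blups) out$solves <- solves
  out
}

#' Restricted log-likelihood of the FA model at fixed parameters
#'
#' Evaluates the REML log-likelihood of the stage-2 factor-analytic model
#' for a given loading matrix, specific variances and stage-2 residual
#' variances, with the environment intercepts profiled out. Exposed so the
#' likelihood can be checked against independent dense-matrix evaluations.
#'
#' @param means A [means_table()] or a plain genotype x environment matrix.
#' @param Lambda s x k loading matrix.
#' @param psi Length-s specific variances (non-negative).
#' @param d Length-s stage-2 residual variances (non-negative; default 0).
#' @return The restricted log-likelihood (a scalar).
#' @export
fa_loglik <- function(means, Lambda, psi, d = rep(0, length(psi))) {
  Y <- if (inherits(means, "means_table")) means$means else as.matrix(means)
  Lambda <- as.matrix(Lambda)
  stopifnot(nrow(Lambda) == ncol(Y), length(psi) == ncol(Y),
            length(d) == ncol(Y))
  core <- fa_reml_core(fa_patterns(Y), Lambda, psi, d)
  if (is.null(core)) stop("covariance not positive definite", call. = FALSE)
  core$ll
}

fa_free_idx <- function(s, k) which(row(matrix(0, s, k)) >= col(matrix(0, s, k)))

fa_pack <- function(Lambda, psi, idx) c(Lambda[idx], log(psi))

fa_unpack <- function(theta, s, k, idx) {
  Lambda <- matrix(0, s, k)
  nl <- length(idx)
  Lambda[idx] <- theta[seq_len(nl)]
  list(Lambda = Lambda, psi = exp(theta[nl + seq_len(s)]))
}

# Eigen start: leading k components of the pairwise-complete sample
# covariance of environment columns, rotated to lower-trapezoidal form.
fa_start <- function(Y, k, d) {
  S <- suppressWarnings(cov(Y, use = "pairwise.complete.obs"))
  S[!is.finite(S)] <- 0
  S <- (S + t(S)) / 2
  ee <- eigen(S, symmetric = TRUE)
  ev <- pmax(ee$values[seq_len(k)], mean(abs(ee$values)) * 1e-3)
  L <- ee$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  L <- fa_lower_trapezoid(L)
  psi <- pmax(diag(S) - rowSums(L^2) - d, 0.05 * pmax(diag(S), 1e-6))
  list(Lambda = L, psi = psi)
}

# Rotate Lambda to lower-trapezoidal form (upper triangle zero) without
# changing Lambda Lambda'.
fa_lower_trapezoid <- function(L) {
  qrL <- qr(t(L))
  R <- qr.R(qrL)
  Lt <- t(R[, seq_len(nrow(L)), drop = FALSE])
  # column signs: positive diagonal
  for (j in seq_len(ncol(Lt))) {
    if (Lt[j, j] < 0) Lt[, j] <- -Lt[, j]
  }
  Lt
}

#' Fit the joint factor-analytic mixed model of order k
#'
#' Stage 2 of the two-stage MET analysis. For the genotype-by-environment
#' table of adjusted means, maximizes the restricted likelihood of
#' `y_il = beta_l + u_il + e_il`, where the rows `u_i` are iid
#' `N(0, Lambda Lambda' + diag(psi))` across environments and `e_il` is a
#' diagonal stage-2 residual. `Lambda` is constrained upper-triangle-zero
#' during optimization (identifiability); interpret loadings only after
#' varimax rotation ([varimax_rotate()]). Missing cells are allowed; the
#' incidence must be connected. Genotype scores, environment-level BLUPs
#' for all cells (tested or not) and the implied genetic covariance
#' `G = Lambda Lambda' + diag(psi)` are returned.
#'
#' The stage-2 residual is either fixed from the stage-1 standard errors
#' (`"se"`, the default whenever the table carries them: `d_l` is the mean
#' squared SE in environment l) or absorbed into the specific variances
#' (`"none"`). A free diagonal stage-2 residual on top of free `psi` is not
#' identifiable and is deliberately not offered.
#'
#' @param means A [means_table()].
#' @param k Factor order, `1 <= k <= s - 1`.
#' @param stage2_resid `"auto"` (se when available, else none), `"se"`,
#'   or `"none"`.
#' @param n_starts Number of optimizer starts (eigen start plus jittered
#'   copies).
#' @param start Optional list with `Lambda`, `psi` used as an extra start
#'   (e.g. a lower-order fit when scanning orders).
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @return An object of class `fa_fit`: `k`, `Lambda` (s x k), `psi`,
#'   `d` (stage-2 residual variances used), `scores` (m x k),
#'   `env_intercepts`, `G_hat`, `logREML`, `n_params`, `AIC`, `blups_in_env`
#'   (m x s genetic-effect BLUPs for every cell), `fitted` (m x s
#'   intercept + BLUP), `tested` (logical incidence), `converged`.
#' @export
fit_fa <- function(means, k, stage2_resid = c("auto", "se", "none"),
                   n_starts = 2, start = NULL, maxit = 1000) {
  stopifnot(inherits(means, "means_table"))
  stage2_resid <- match.arg(stage2_resid)
  Y <- means$means
  s <- ncol(Y); m <- nrow(Y)
  if (k < 1 || k > s - 1) stop("need 1 <= k <= s - 1", call. = FALSE)
  use_se <- switch(stage2_resid,
                   auto = !is.null(means$d) || !is.null(means$se),
                   se = TRUE, none = FALSE)
  if (use_se && is.null(means$d) && is.null(means$se)) {
    stop("stage2_resid = 'se' needs a means table with standard errors",
         call. = FALSE)
  }
  d <- if (!use_se) rep(0, s) else
    if (!is.null(means$d)) means$d else colMeans(means$se^2, na.rm = TRUE)

  patterns <- fa_patterns(Y)
  idx <- fa_free_idx(s, k)
  vscale <- mean(apply(Y, 2, var, na.rm = TRUE), na.rm = TRUE)
  lower <- c(rep(-Inf, length(idx)), rep(log(vscale * 1e-8), s))
  upper <- c(rep(Inf, length(idx)), rep(log(vscale * 1e4), s))

  negll <- function(theta) {
    par <- fa_unpack(theta, s, k, idx)
    core <- fa_reml_core(patterns, par$Lambda, par$psi, d)
    if (is.null(core) || !is.finite(core$ll)) return(1e10)
    -core$ll
  }

  st0 <- fa_start(Y, k, d)
  starts <- list(st0)
  if (!is.null(start)) {
    L0 <- matrix(0, s, k)
    k0 <- min(ncol(start$Lambda), k)
    L0[, seq_len(k0)] <- start$Lambda[, seq_len(k0)]
    if (k0 < k) L0[, (k0 + 1):k] <- 0.05 * sqrt(vscale)
    starts <- c(starts, list(list(Lambda = fa_lower_trapezoid(L0),
                                  psi = pmax(start$psi, vscale * 1e-6))))
  }
  if (n_starts > length(starts)) {
    withr::with_seed(s * 1000L + k, {
      for (j in seq_len(n_starts - length(starts))) {
        starts <- c(starts, list(list(
          Lambda = st0$Lambda * matrix(1 + 0.3 * rnorm(s * k), s, k),
          psi = st0$psi * exp(0.3 * rnorm(s)))))
      }
    })
  }

  best <- NULL
  for (st in starts) {
    theta0 <- fa_pack(st$Lambda, pmin(pmax(st$psi, vscale * 1e-7), vscale * 1e3),
                      idx)
    opt <- tryCatch(
      optim(theta0, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("FA fit failed from all starts", call. = FALSE)

  par <- fa_unpack(best$par, s, k, idx)
  Lambda <- par$Lambda
  for (j in seq_len(k)) if (Lambda[j, j] < 0) Lambda[, j] <- -Lambda[, j]
  psi <- par$psi
  core <- fa_reml_core(patterns, Lambda, psi, d, want_blups = TRUE)

  # BLUPs per pattern: u_i = G[, obs] C_obs^{-1} (y_i[obs] - beta[obs]),
  # scores f_i = Lambda[obs, ]' C_obs^{-1} resid_i.
  G <- core$G
  dimnames(G) <- list(colnames(Y), colnames(Y))
  u_hat <- matrix(0, m, s, dimnames = dimnames(Y))
  scores <- matrix(0, m, k, dimnames = list(rownames(Y), paste0("FA", seq_len(k))))
  for (p in seq_along(patterns)) {
    pat <- patterns[[p]]
    o <- pat$obs
    Rm <- pat$Yt - core$beta[o]
    KR <- core$solves[[p]]$Cinv %*% Rm
    u_hat[pat$rows, ] <- t(G[, o, drop = FALSE] %*% KR)
    scores[pat$rows, ] <- t(crossprod(Lambda[o, , drop = FALSE], KR))
  }
  dimnames(Lambda) <- list(colnames(Y), paste0("FA", seq_len(k)))
  names(psi) <- colnames(Y)
  np <- fa_n_params(s, k, include_stage2_resid = FALSE)
  fitted <- sweep(u_hat, 2, core$beta, `+`)

  structure(
    list(k = k, Lambda = Lambda, psi = psi, d = d,
         scores = scores,
         env_intercepts = setNames(core$beta, colnames(Y)),
         G_hat = G, logREML = core$ll,
         n_params = np, AIC = -2 * core$ll + 2 * np,
         blups_in_env = u_hat, fitted = fitted,
         tested = !is.na(Y), means = means,
         converged = best$convergence == 0),
    class = "fa_fit"
  )
}

#' @export
print.fa_fit <- function(x, ...) {
  ve <- variance_explained(x)
  cat("<fa_fit> FA_", x$k, ": ", nrow(x$scores), " genotypes x ",
      nrow(x$Lambda), " environments\n", sep = "")
  cat(sprintf("  logREML=%.2f  NP=%d  AIC=%.2f  converged=%s\n",
              x$logREML, x$n_params, x$AIC, x$converged))
  cat(sprintf("  %% genetic variance explained: %.1f (per factor: %s)\n",
              ve$overall, paste(sprintf("%.1f", ve$per_factor), collapse = ", ")))
  invisible(x)
}

#' Scan FA orders and select by AIC
#'
#' Fits FA_k for each order in `k_range`, computes
#' `AIC = -2 logREML + 2 NP` with NP the count of variance-covariance
#' parameters, and returns the minimum-AIC fit together with the
#' model-comparison table (NP, logREML, AIC per order). Each order is
#' warm-started from the previous one in addition to its own eigen start,
#' which keeps the restricted likelihood non-decreasing in k.
#'
#' @param means A [means_table()].
#' @param k_range Integer vector of orders (default `1:4`).
#' @param ... Passed to [fit_fa()].
#' @return An object of class `fa_search`: `table` (tibble with k,
#'   n_params, logREML, AIC, converged), `fits` (list), `best` (the chosen
#'   `fa_fit`), `k_best`.
#' @export
model_search <- function(means, k_range = 1:4, ...) {
  stopifnot(inherits(means, "means_table"))
  s <- ncol(means$means)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 1 || max(k_range) > s - 1) {
    stop("k_range must lie within [1, s - 1]", call. = FALSE)
  }
  fits <- list()
  prev <- NULL
  for (k in k_range) {
    fit <- tryCatch(fit_fa(means, k, start = prev, ...),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      fits[[as.character(k)]] <- fit
      prev <- list(Lambda = fit$Lambda, psi = fit$psi)
    }
  }
  if (length(fits) == 0) stop("no FA order could be fitted", call. = FALSE)
  table <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(k = f$k, n_params = f$n_params,
                   logREML = f$logREML, AIC = f$AIC, converged = f$converged)
  }))
  conv <- table[table$converged, ]
  pick <- if (nrow(conv) > 0) conv$k[which.min(conv$AIC)] else
    table$k[which.min(table$AIC)]
  structure(
    list(table = table, fits = fits,
         best = fits[[as.character(pick)]], k_best = pick),
    class = "fa_search"
  )
}

#' @export
print.fa_search <- function(x, ...) {
  cat("<fa_search> chosen order k =", x$k_best, "\n")
  print(x$table)
  invisible(x)
}

#' Percentage of genetic variance explained by the factors
#'
#' Overall: `100 tr(Lambda Lambda') / tr(Lambda Lambda' + diag(psi))`.
#' Per factor r: `100 (lambda_r' lambda_r) / tr(Lambda Lambda' + diag(psi))`;
#' the per-factor shares sum to the overall percentage.
#'
#' @param fit An [fit_fa()] result, or a list with `Lambda` and `psi`.
#' @return List with `overall` (scalar %) and `per_factor` (length-k %).
#' @export
variance_explained <- function(fit) {
  Lambda <- as.matrix(fit$Lambda)
  psi <- fit$psi
  common <- colSums(Lambda^2)
  denom <- sum(common) + sum(psi)
  if (denom <= 0) stop("total genetic variance is zero", call. = FALSE)
  list(overall = 100 * sum(common) / denom,
       per_factor = 100 * common / denom)
}

#' Between-environment genetic correlation matrix
#'
#' `rho_ll' = G_ll' / sqrt(G_ll G_l'l')` from the implied genetic
#' covariance `G = Lambda Lambda' + diag(psi)`. Environments with zero
#' genetic variance get `NA` rows/columns and are listed in attribute
#' `undefined`.
#'
#' @param fit An [fit_fa()] result (or any list with `G_hat`).
#' @return s x s correlation matrix with unit diagonal.
#' @export
genetic_correlations <- function(fit) {
  G <- fit$G_hat
  v <- diag(G)
  bad <- v <= 0
  sdv <- sqrt(ifelse(bad, NA, v))
  R <- G / outer(sdv, sdv)
  diag(R)[!bad] <- 1
  structure(R, undefined = colnames(G)[bad])
}

#' Predicted genotype values in tested and untested environments
#'
#' Every genotype-environment cell is filled:
#' `prediction = env_intercept_l + lambda_l' f_i + specific BLUP`, where
#' the specific (environment-unique) effect contributes only in cells that
#' were actually observed; in untested cells the prediction rests on the
#' common factors alone.
#'
#' @param fit An [fit_fa()] result.
#' @return A tibble with `genotype`, `environment`, `predicted`,
#'   `genetic_value` (prediction minus environment intercept), `tested`.
#' @export
predict_genotype_env <- function(fit) {
  stopifnot(inherits(fit, "fa_fit"))
  long <- expand.grid(genotype = rownames(fit$fitted),
                      environment = colnames(fit$fitted),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(long$genotype, rownames(fit$fitted))
  ei <- match(long$environment, colnames(fit$fitted))
  tibble::tibble(
    genotype = long$genotype,
    environment = long$environment,
    predicted = fit$fitted[cbind(gi, ei)],
    genetic_value = fit$blups_in_env[cbind(gi, ei)],
    tested = fit$tested[cbind(gi, ei)]
  )
}

#' Observed-versus-fitted correlation of an FA fit
#'
#' Pearson correlation between the observed adjusted means and the fitted
#' values (environment intercept plus genetic BLUP) over the observed
#' cells — a simple goodness-of-fit summary for the chosen order.
#'
#' @param fit An [fit_fa()] result.
#' @param means Means table; defaults to the one the model was fitted to.
#' @return Correlation in \[-1, 1\].
#' @export
fit_accuracy <- function(fit, means = fit$means) {
  Y <- if (inherits(means, "means_table")) means$means else as.matrix(means)
  obs <- !is.na(Y)
  if (sum(obs) < 3) stop("need at least 3 observed cells", call. = FALSE)
  cor(Y[obs], fit$fitted[obs])
}
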