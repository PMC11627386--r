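#' Varimax criterion of a loading matrix
#'
#' Sum over factors of the variance of the squared loadings,
#' `sum_j [ mean(L_j^4) - mean(L_j^2)^2 ]` — the quantity raw varimax
#' maximizes over orthogonal rotations.
#'
#' @param L Loading matrix.
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(L) {
  L <- as.matrix(L)
  sum(colMeans(L^4) - colMeans(L^2)^2)
}

#' Varimax rotation of an FA fit
#'
#' Rotates loadings and co-rotates genotype scores by the orthogonal
#' varimax rotation (raw varimax by default; Kaiser row normalization
#' optional), then reorders factors by explained variance (descending) and
#' fixes column signs so each factor's largest-magnitude loading is
#' positive. `Lambda Lambda'`, the implied genetic covariance and all
#' fitted values are unchanged by construction.
#'
#' @param fit An [fit_fa()] result.
#' @param kaiser_normalize Normalize rows to unit communality during
#'   rotation (default `FALSE`, raw varimax).
#' @param tol Convergence tolerance of the rotation.
#' @return An object of class `rotated_fa`: `Lambda_rot`, `scores_rot`,
#'   `rotation` (k x k orthonormal, `Lambda_rot = Lambda %*% rotation`),
#'   `varimax_criterion`, `var_explained` (per rotated factor, %), and the
#'   originating `fit`.
#' @export
varimax_rotate <- function(fit, kaiser_normalize = FALSE, tol = 1e-10) {
  Lambda <- as.matrix(fit$Lambda)
  scores <- as.matrix(fit$scores)
  k <- ncol(Lambda)
  rot <- diag(k)
  if (k > 1) {
    vm <- varimax(Lambda, normalize = kaiser_normalize, eps = tol)
    rot <- as.matrix(vm$rotmat)
  }
  L <- Lambda %*% rot
  ord <- order(colSums(L^2), decreasing = TRUE)
  P <- diag(k)[, ord, drop = FALSE]
  L <- L[, ord, drop = FALSE]
  signs <- vapply(seq_len(k), function(j) {
    v <- L[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  L <- sweep(L, 2, signs, `*`)
  rot <- rot %*% P %*% diag(signs, k)
  S <- scores %*% rot
  colnames(L) <- colnames(S) <- paste0("FA", seq_len(k))
  rownames(L) <- rownames(Lambda)
  rownames(S) <- rownames(scores)
  denom <- sum(Lambda^2) + sum(fit$psi)
  structure(
    list(Lambda_rot = L, scores_rot = S, rotation = rot,
         varimax_criterion = varimax_criterion(L),
         var_explained = 100 * colSums(L^2) / denom,
         fit = fit),
    class = "rotated_fa"
  )
}

#' @export
print.rotated_fa <- function(x, ...) {
  cat("<rotated_fa> k =", ncol(x$Lambda_rot),
      " criterion =", signif(x$varimax_criterion, 4), "\n")
  cat("  % variance per rotated factor:",
      paste(sprintf("%.1f", x$var_explained), collapse = ", "), "\n")
  invisible(x)
}

#' Latent-regression stability table
#'
#' For each genotype and each rotated factor, the latent-regression slope
#' `beta1` is the rotated genotype score: the regression line of the
#' genotype's predicted genetic values on the environmental loadings of
#' that factor is `mean_blup + beta1 * loading`. Slopes near zero mean the
#' genotype is insensitive to the environmental gradient the factor
#' captures (stable); large positive slopes mean it responds strongly to
#' environments loading high on the factor.
#'
#' @param rot A [varimax_rotate()] result.
#' @param fit The underlying [fit_fa()]; defaults to `rot$fit`.
#' @return An object of class `stability_table`: `table` (tibble with
#'   `genotype`, `factor`, `beta1`, `mean_blup`, `var_explained`) and
#'   `plot_data` (tibble with `factor`, `environment`, `loading`,
#'   `genotype`, `predicted` genetic value, `tested`) for latent-regression
#'   plots.
#' @export
latent_regression <- function(rot, fit = rot$fit) {
  stopifnot(inherits(rot, "rotated_fa"))
  k <- ncol(rot$Lambda_rot)
  genotypes <- rownames(rot$scores_rot)
  mean_blup <- rowMeans(fit$blups_in_env)
  table <- tidyr::expand_grid(genotype = genotypes, factor = seq_len(k))
  table$beta1 <- rot$scores_rot[cbind(match(table$genotype, genotypes),
                                      table$factor)]
  table$mean_blup <- mean_blup[table$genotype]
  table$var_explained <- rot$var_explained[table$factor]

  envs <- rownames(rot$Lambda_rot)
  pd <- tidyr::expand_grid(factor = seq_len(k), environment = envs,
                           genotype = genotypes)
  pd$loading <- rot$Lambda_rot[cbind(match(pd$environment, envs), pd$factor)]
  gi <- match(pd$genotype, rownames(fit$blups_in_env))
  ei <- match(pd$environment, colnames(fit$blups_in_env))
  pd$predicted <- fit$blups_in_env[cbind(gi, ei)]
  pd$tested <- fit$tested[cbind(gi, ei)]

  structure(list(table = table, plot_data = pd), class = "stability_table")
}

#' @export
print.stability_table <- function(x, ...) {
  cat("<stability_table>", length(unique(x$table$genotype)), "genotypes x",
      max(x$table$factor), "factors\n")
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Classify genotypes by latent-regression slope
#'
#' `|beta1| <= stable_band` is stable; `beta1 >= responsive_threshold` is
#' responsive (performs better in environments loading high on the
#' factor); `beta1 <= -responsive_threshold` is negatively responsive;
#' anything else is intermediate.
#'
#' @param stab A [latent_regression()] result or its `table` tibble.
#' @param stable_band Half-width of the stability band around zero
#'   (default 0.5).
#' @param responsive_threshold Slope magnitude counted as responsive
#'   (default 1).
#' @return The table with a `classification` factor column.
#' @export
classify_stability <- function(stab, stable_band = 0.5,
                               responsive_threshold = 1) {
  if (stable_band <= 0 || responsive_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  tab <- if (inherits(stab, "stability_table")) stab$table else
    tibble::as_tibble(stab)
  b <- tab$beta1
  cls <- ifelse(abs(b) <= stable_band, "stable",
                ifelse(b >= responsive_threshold, "responsive",
                       ifelse(b <= -responsive_threshold,
                              "negatively-responsive", "intermediate")))
  tab$classification <- factor(cls, levels = c("stable", "responsive",
                                               "negatively-responsive",
                                               "intermediate"))
  tab
}
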