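#' Impute missing cells of a two-way means table
#'
#' EM-style alternation for unbalanced genotype-by-environment tables:
#' missing cells are initialized from the additive fit
#' `mu + genotype effect + environment effect`, then repeatedly replaced
#' by the additive-plus-rank-r SVD reconstruction of the completed table
#' until the largest cell change falls below `tol`. AMMI and GGE need a
#' complete table; this is the standard way to get one.
#'
#' @param x Genotype x environment matrix with `NA` for missing cells.
#' @param rank Rank of the multiplicative term used in the reconstruction.
#' @param tol Convergence tolerance on the largest imputed-cell change.
#' @param max_iter Maximum EM iterations.
#' @return The completed matrix with attribute `imputed` (logical mask of
#'   filled cells) and `iterations`.
#' @export
impute_two_way <- function(x, rank = 1, tol = 1e-8, max_iter = 500) {
  x <- as.matrix(x)
  miss <- is.na(x)
  if (!any(miss)) {
    return(structure(x, imputed = miss, iterations = 0L))
  }
  if (any(rowSums(!miss) == 0) || any(colSums(!miss) == 0)) {
    stop("fully missing row or column: table is disconnected", call. = FALSE)
  }
  rank <- min(rank, dim(x) - 1)
  # additive start from observed cells
  mu <- mean(x, na.rm = TRUE)
  a <- rowMeans(x, na.rm = TRUE) - mu
  b <- colMeans(x, na.rm = TRUE) - mu
  xc <- x
  xc[miss] <- (mu + outer(a, b, `+`))[miss]
  for (it in seq_len(max_iter)) {
    mu <- mean(xc)
    a <- rowMeans(xc) - mu
    b <- colMeans(xc) - mu
    add <- mu + outer(a, b, `+`)
    sv <- svd(xc - add)
    r <- seq_len(rank)
    recon <- add + sv$u[, r, drop = FALSE] %*%
      (sv$d[r] * t(sv$v[, r, drop = FALSE]))
    delta <- max(abs(recon[miss] - xc[miss]))
    xc[miss] <- recon[miss]
    if (delta < tol) {
      return(structure(xc, imputed = miss, iterations = it))
    }
  }
  stop("imputation did not converge in ", max_iter,
       " iterations (last cell change ", signif(delta, 3), ")", call. = FALSE)
}

#' AMMI decomposition of a complete two-way table
#'
#' Additive main effects plus multiplicative interaction: double-centering
#' removes the grand mean and the genotype and environment main effects;
#' the SVD of the interaction residual gives the multiplicative terms
#' `sum_n lambda_n xi_in eta_jn`. When the replicate count and a pooled
#' residual variance are supplied, each term gets a Gollob F test with
#' `df_n = m + s - 1 - 2n` against the error variance of a mean,
#' `sigma2 / R`.
#'
#' @param x Complete genotype x environment matrix of means.
#' @param n_terms Number of multiplicative terms to keep (default: all,
#'   `min(m, s) - 1`).
#' @param R Replicates behind each mean (for the F tests).
#' @param sigma2 Pooled plot-level residual variance (for the F tests).
#' @return An object of class `ammi_fit`: `grand_mean`, `genotype_effects`,
#'   `env_effects`, `sv` (singular values, all terms), `genotype_scores`,
#'   `env_scores` (orthonormal singular vectors, kept terms), `ss`
#'   (per-term interaction SS), `ss_pct`, `interaction_ss`, `anova`
#'   (per-term tibble with df and, when available, F and p),
#'   `n_significant`.
#' @export
fit_ammi <- function(x, n_terms = NULL, R = NULL, sigma2 = NULL) {
  x <- as.matrix(x)
  if (any(is.na(x))) stop("AMMI needs a complete table; see impute_two_way()",
                          call. = FALSE)
  m <- nrow(x); s <- ncol(x)
  max_terms <- min(m, s) - 1
  if (is.null(n_terms)) n_terms <- max_terms
  if (n_terms > max_terms) {
    stop("n_terms must not exceed min(m, s) - 1 = ", max_terms, call. = FALSE)
  }
  mu <- mean(x)
  alpha <- rowMeans(x) - mu
  beta <- colMeans(x) - mu
  Z <- x - mu - outer(alpha, rep(1, s)) - outer(rep(1, m), beta)
  sv <- svd(Z)
  lam <- sv$d
  keep <- seq_len(n_terms)
  ss <- lam^2
  int_ss <- sum(Z^2)
  df <- m + s - 1 - 2 * seq_along(lam)
  anova <- tibble::tibble(
    term = paste0("IPCA", seq_len(n_terms)),
    singular_value = lam[keep],
    ss = ss[keep],
    ss_pct = 100 * ss[keep] / int_ss,
    df = df[keep]
  )
  n_sig <- NA_integer_
  if (!is.null(R) && !is.null(sigma2)) {
    err <- sigma2 / R
    anova$F <- (anova$ss / anova$df) / err
    # mean-scale F against the plot-level pooled error of a mean; df2 large
    anova$p <- pchisq(anova$F * anova$df, df = anova$df, lower.tail = FALSE)
    n_sig <- sum(anova$p < 0.05)
  }
  structure(
    list(grand_mean = mu, genotype_effects = alpha, env_effects = beta,
         sv = lam,
         genotype_scores = sv$u[, keep, drop = FALSE],
         env_scores = sv$v[, keep, drop = FALSE],
         ss = ss, ss_pct = 100 * ss / int_ss,
         interaction_ss = int_ss, anova = anova,
         n_terms = n_terms, n_significant = n_sig,
         genotypes = rownames(x), environments = colnames(x)),
    class = "ammi_fit"
  )
}

#' @export
print.ammi_fit <- function(x, ...) {
  cat("<ammi_fit>", length(x$genotype_effects), "genotypes x",
      length(x$env_effects), "environments;", x$n_terms, "terms kept\n")
  print(x$anova)
  invisible(x)
}

#' AMMI stability ranking by first-axis score magnitude
#'
#' Genotypes are ranked by `|IPCA1 score|` ascending (smallest interaction
#' first, i.e. most stable); ties are broken by genotype main effect,
#' descending.
#'
#' @param res An [fit_ammi()] result.
#' @return Tibble with `genotype`, `ipca1`, `abs_ipca1`, `main_effect`,
#'   `rank`.
#' @export
ammi_stability <- function(res) {
  stopifnot(inherits(res, "ammi_fit"))
  ipca1 <- res$genotype_scores[, 1]
  ord <- order(abs(ipca1), -res$genotype_effects)
  out <- tibble::tibble(
    genotype = if (!is.null(res$genotypes)) res$genotypes else
      paste0("G", seq_along(ipca1)),
    ipca1 = ipca1,
    abs_ipca1 = abs(ipca1),
    main_effect = res$genotype_effects
  )[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' GGE decomposition of a complete two-way table
#'
#' Environment-centering (subtracting environment means) retains genotype
#' main effects plus G-by-E; the SVD of the centered table with symmetric
#' scaling (`sqrt(lambda_n)` assigned to both sides) gives the biplot
#' coordinates. Per-PC variance proportions are `lambda_n^2 / sum lambda^2`.
#'
#' @param x Complete genotype x environment matrix of means.
#' @param n_pcs Number of principal components to keep (default 2).
#' @return An object of class `gge_fit`: `genotype_coords`, `env_coords`
#'   (symmetrically scaled, kept PCs), `proportions` (all PCs),
#'   `cumulative_12`, `degenerate` flag, and the full `sv`.
#' @export
fit_gge <- function(x, n_pcs = 2) {
  x <- as.matrix(x)
  if (any(is.na(x))) stop("GGE needs a complete table; see impute_two_way()",
                          call. = FALSE)
  if (n_pcs > min(dim(x))) {
    stop("n_pcs must not exceed min(m, s)", call. = FALSE)
  }
  centered <- sweep(x, 2, colMeans(x))
  sv <- svd(centered)
  tot <- sum(sv$d^2)
  degenerate <- tot < .Machine$double.eps * length(x)
  props <- if (degenerate) rep(NA_real_, length(sv$d)) else sv$d^2 / tot
  keep <- seq_len(n_pcs)
  scale_d <- sqrt(sv$d[keep])
  gcoord <- sweep(sv$u[, keep, drop = FALSE], 2, scale_d, `*`)
  ecoord <- sweep(sv$v[, keep, drop = FALSE], 2, scale_d, `*`)
  rownames(gcoord) <- rownames(x)
  rownames(ecoord) <- colnames(x)
  colnames(gcoord) <- colnames(ecoord) <- paste0("PC", keep)
  structure(
    list(genotype_coords = gcoord, env_coords = ecoord,
         proportions = props,
         cumulative_12 = if (degenerate) NA_real_ else
           sum(props[seq_len(min(2, length(props)))]),
         sv = sv$d, degenerate = degenerate, centered = centered),
    class = "gge_fit"
  )
}

#' @export
print.gge_fit <- function(x, ...) {
  cat("<gge_fit>", nrow(x$genotype_coords), "genotypes x",
      nrow(x$env_coords), "environments\n")
  if (x$degenerate) {
    cat("  degenerate: no genotypic or G-by-E variation\n")
  } else {
    cat(sprintf("  PC1+PC2 explain %.1f%% of G + GxE\n",
                100 * x$cumulative_12))
  }
  invisible(x)
}
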