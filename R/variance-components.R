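#' Derived genetic parameters from joint variance components
#'
#' Plugs components into the standard formulas:
#' `sigma_p2 = sigma_g2 + sigma_gxe2 / E + sigma_e2 / (E R)`,
#' `CVg = 100 sqrt(sigma_g2) / mean`, `CVr = 100 sqrt(sigma_e2) / mean`,
#' `CV_ratio = CVg / CVr`, `r_ge = sigma_g2 / (sigma_g2 + sigma_gxe2)`,
#' `r_i2 = sigma_gxe2 / (sigma_g2 + sigma_gxe2 + sigma_e2)`,
#' `H2 = sigma_g2 / sigma_p2`, `CVp = 100 sqrt(sigma_p2) / mean`,
#' `P_minus_G = CVp - CVg`.
#'
#' @param sigma_g2,sigma_gxe2,sigma_e2 Variance components.
#' @param E Number of environments.
#' @param R Replicates per environment.
#' @param mean Overall trait mean.
#' @return A list of the derived quantities plus the inputs.
#' @export
vc_metrics <- function(sigma_g2, sigma_gxe2, sigma_e2, E, R, mean) {
  stopifnot(sigma_g2 >= 0, sigma_gxe2 >= 0, sigma_e2 >= 0, E > 0, R > 0,
            mean > 0)
  sigma_p2 <- sigma_g2 + sigma_gxe2 / E + sigma_e2 / (E * R)
  CVg <- 100 * sqrt(sigma_g2) / mean
  CVr <- 100 * sqrt(sigma_e2) / mean
  CVp <- 100 * sqrt(sigma_p2) / mean
  list(sigma_g2 = sigma_g2, sigma_gxe2 = sigma_gxe2, sigma_e2 = sigma_e2,
       E = E, R = R, mean = mean,
       sigma_p2 = sigma_p2,
       CVg = CVg, CVr = CVr, CVp = CVp,
       CV_ratio = if (CVr > 0) CVg / CVr else NA_real_,
       r_ge = if (sigma_g2 + sigma_gxe2 > 0)
         sigma_g2 / (sigma_g2 + sigma_gxe2) else NA_real_,
       r_i2 = if (sigma_g2 + sigma_gxe2 + sigma_e2 > 0)
         sigma_gxe2 / (sigma_g2 + sigma_gxe2 + sigma_e2) else NA_real_,
       H2_entry_mean = if (sigma_p2 > 0) sigma_g2 / sigma_p2 else NA_real_,
       P_minus_G = CVp - CVg)
}

#' Joint across-environment variance components
#'
#' REML fit of the compound joint model: environment fixed, genotype,
#' genotype-by-environment and replicate-within-environment random,
#' heterogeneous unknowns pooled into a single residual. Returns the
#' components and the derived genetic parameters of [vc_metrics()], using
#' harmonic-mean environment and replicate counts when the design is
#' unbalanced.
#'
#' @param data A [met_dataset()] with at least 2 environments.
#' @return An object of class `joint_vc` (the [vc_metrics()] list plus
#'   `sigma_rep2`, `logREML`, `fit`).
#' @export
fit_joint_vc <- function(data) {
  stopifnot(inherits(data, "met_dataset"))
  d <- data$records[!is.na(data$records$value), , drop = FALSE]
  if (length(unique(d$environment)) < 2) {
    stop("need at least 2 environments", call. = FALSE)
  }
  df <- data.frame(value = d$value,
                   genotype = factor(d$genotype),
                   environment = factor(d$environment),
                   replicate = factor(d$replicate))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE,
                            optimizer = "bobyqa",
                            optCtrl = list(rhoend = 1e-10))
  fit <- quiet_bobyqa(suppressMessages(
    lme4::lmer(value ~ environment + (1 | genotype) +
                 (1 | genotype:environment) + (1 | environment:replicate),
               data = df, REML = TRUE, control = ctrl)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) 0 else v
  }
  # harmonic means of per-genotype environment counts and per-cell replicate
  # counts; equal to E and R under balance
  env_per_gen <- table(unique(d[, c("genotype", "environment")])$genotype)
  E <- 1 / mean(1 / as.numeric(env_per_gen))
  reps_per_cell <- as.numeric(table(paste(d$genotype, d$environment)))
  R <- 1 / mean(1 / reps_per_cell)
  out <- vc_metrics(sigma_g2 = getvc("genotype"),
                    sigma_gxe2 = getvc("genotype:environment"),
                    sigma_e2 = getvc("Residual"),
                    E = E, R = R, mean = mean(d$value))
  out$sigma_rep2 <- getvc("environment:replicate")
  out$logREML <- as.numeric(logLik(fit))
  out$fit <- fit
  structure(out, class = "joint_vc")
}

#' @export
print.joint_vc <- function(x, ...) {
  cat("<joint_vc>\n")
  cat(sprintf("  sigma_g2=%.4f sigma_gxe2=%.4f sigma_e2=%.4f sigma_p2=%.4f\n",
              x$sigma_g2, x$sigma_gxe2, x$sigma_e2, x$sigma_p2))
  cat(sprintf("  CVg=%.2f%% CVr=%.2f%% ratio=%.2f r_ge=%.3f r_i2=%.3f H2=%.3f P-G=%.2f\n",
              x$CVg, x$CVr, x$CV_ratio, x$r_ge, x$r_i2, x$H2_entry_mean,
              x$P_minus_G))
  invisible(x)
}

#' Likelihood-ratio tests for the random terms of the joint model
#'
#' Refits the joint model dropping the genotype and the
#' genotype-by-environment term in turn; the LRT statistic is
#' `2 (logL_full - logL_reduced)` on REML fits with identical fixed
#' effects, with p-values from the 50:50 mixture of chi-square(0) and
#' chi-square(1) appropriate for a variance component tested on the
#' boundary.
#'
#' @param data A [met_dataset()].
#' @return Tibble with `term`, `logLik_full`, `logLik_reduced`, `statistic`,
#'   `p_value`.
#' @export
lrt_effects <- function(data) {
  stopifnot(inherits(data, "met_dataset"))
  d <- data$records[!is.na(data$records$value), , drop = FALSE]
  df <- data.frame(value = d$value,
                   genotype = factor(d$genotype),
                   environment = factor(d$environment),
                   replicate = factor(d$replicate))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE,
                            optimizer = "bobyqa",
                            optCtrl = list(rhoend = 1e-10))
  forms <- list(
    full = value ~ environment + (1 | genotype) + (1 | genotype:environment) +
      (1 | environment:replicate),
    no_g = value ~ environment + (1 | genotype:environment) +
      (1 | environment:replicate),
    no_gxe = value ~ environment + (1 | genotype) +
      (1 | environment:replicate)
  )
  fit1 <- function(f) {
    tryCatch(as.numeric(logLik(quiet_bobyqa(suppressMessages(
      lme4::lmer(f, data = df, REML = TRUE, control = ctrl))))),
      error = function(e) NA_real_)
  }
  ll <- vapply(forms, fit1, numeric(1))
  mk <- function(term, llr) {
    stat <- max(2 * (ll["full"] - llr), 0)
    p <- if (is.na(stat)) NA_real_ else
      if (stat <= 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
    tibble::tibble(term = term, logLik_full = ll[["full"]],
                   logLik_reduced = llr, statistic = stat, p_value = p)
  }
  dplyr::bind_rows(mk("genotype", ll[["no_g"]]),
                   mk("genotype:environment", ll[["no_gxe"]]))
}

#' Correlations between environmental covariates and factor loadings
#'
#' Pearson correlation, over environments, between each rotated factor's
#' environmental loadings and each covariate, with two-sided p-values from
#' `t = r sqrt((n - 2) / (1 - r^2))` and significance stars at
#' 0.05 / 0.01 / 0.001 (unadjusted by default; Benjamini-Hochberg
#' optionally).
#'
#' @param rot A [varimax_rotate()] result (or any list with a `Lambda_rot`
#'   matrix whose rownames are environments).
#' @param covariates Covariate tibble from [read_covariates()] or
#'   [simulate_covariates()] (an `environment` column plus numeric columns).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `loading_covariate_report`: tibbles `r`,
#'   `p`, `stars` (factors x covariates) and the long `table`. Pairs with
#'   fewer than 4 jointly observed environments are `NA` (flagged
#'   undefined).
#' @export
loading_covariate_correlations <- function(rot, covariates,
                                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  L <- rot$Lambda_rot
  envs <- intersect(rownames(L), covariates$environment)
  if (length(envs) < 4) {
    stop("fewer than 4 environments shared between loadings and covariates",
         call. = FALSE)
  }
  L <- L[envs, , drop = FALSE]
  cov_tab <- covariates[match(envs, covariates$environment), , drop = FALSE]
  cov_names <- setdiff(names(cov_tab), "environment")
  k <- ncol(L)
  rmat <- pmat <- matrix(NA_real_, k, length(cov_names),
                         dimnames = list(colnames(L), cov_names))
  for (f in seq_len(k)) {
    for (j in seq_along(cov_names)) {
      x <- L[, f]
      y <- cov_tab[[cov_names[j]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 4 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      rmat[f, j] <- unname(ct$estimate)
      pmat[f, j] <- ct$p.value
    }
  }
  if (adjust == "BH") {
    pmat[] <- p.adjust(pmat, method = "BH")
  }
  stars <- ifelse(is.na(pmat), "",
                  ifelse(pmat < 0.001, "***",
                         ifelse(pmat < 0.01, "**",
                                ifelse(pmat < 0.05, "*", ""))))
  long <- tidyr::expand_grid(factor = rownames(rmat), covariate = cov_names)
  long$r <- rmat[cbind(long$factor, long$covariate)]
  long$p <- pmat[cbind(long$factor, long$covariate)]
  long$stars <- stars[cbind(long$factor, long$covariate)]
  structure(list(r = rmat, p = pmat, stars = stars, table = long,
                 n = length(envs), adjust = adjust),
            class = "loading_covariate_report")
}

#' @importFrom stats p.adjust
#' @export
print.loading_covariate_report <- function(x, ...) {
  cat("<loading_covariate_report> over", x$n, "environments",
      if (x$adjust != "none") paste0("(", x$adjust, "-adjusted)"), "\n")
  disp <- matrix(paste0(formatC(x$r, digits = 2, format = "f"), x$stars),
                 nrow = nrow(x$r), dimnames = dimnames(x$r))
  print(disp, quote = FALSE)
  invisible(x)
}
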