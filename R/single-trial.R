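# bobyqa reports code 3 ("trust region step failed to reduce q") when it
# cannot improve at rhoend precision; treat that as converged and keep any
# other optimizer warning visible.
quiet_bobyqa <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("convergence code 3 from bobyqa", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Fit the stage-1 mixed model to one trial
#'
#' Fits, by REML, the per-trial model
#' `value = mu + replicate + genotype + error` with genotype and replicate
#' random and the intercept fixed, and the companion genotype-fixed model
#' used for adjusted means (BLUEs). Returns variance components, genotype
#' BLUPs with prediction error variances, BLUEs with standard errors, and
#' standardized conditional residuals.
#'
#' @param records Plot records of a single trial (a data frame with
#'   `genotype`, `replicate`, `value`), or a [met_dataset()] together with
#'   `trial`.
#' @param trial Trial id to extract when `records` is a [met_dataset()].
#' @return An object of class `trial_fit` with elements `trial_id`, `mu`,
#'   `sigma_g2`, `sigma_r2`, `sigma_e2`, `blups`, `pev`, `blues`,
#'   `blues_se`, `logREML`, `residuals` (tibble of standardized
#'   conditional residuals), `n_obs`, `genotypes`, and `boundary`
#'   (TRUE when a variance component was estimated at zero).
#' @export
fit_trial <- function(records, trial = NULL) {
  if (inherits(records, "met_dataset")) {
    if (is.null(trial)) stop("give a trial id when passing a met_dataset",
                             call. = FALSE)
    records <- records$records[records$records$trial_id == trial, ,
                               drop = FALSE]
  }
  trial_id <- if (!is.null(trial)) trial else unique(records$trial_id)[1]
  d <- records[!is.na(records$value), , drop = FALSE]
  d <- data.frame(genotype = factor(d$genotype),
                  replicate = factor(d$replicate),
                  value = d$value)
  if (nlevels(d$genotype) < 2) {
    stop("trial '", trial_id, "' has fewer than 2 genotypes", call. = FALSE)
  }
  if (nlevels(d$replicate) < 2) {
    stop("trial '", trial_id, "' has fewer than 2 replicates", call. = FALSE)
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE,
                            optimizer = "bobyqa",
                            optCtrl = list(rhoend = 1e-10))
  fit_r <- quiet_bobyqa(suppressMessages(
    lme4::lmer(value ~ 1 + (1 | genotype) + (1 | replicate),
               data = d, REML = TRUE, control = ctrl)))
  vc <- as.data.frame(lme4::VarCorr(fit_r))
  getvc <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) 0 else v
  }
  sigma_g2 <- getvc("genotype")
  sigma_r2 <- getvc("replicate")
  sigma_e2 <- getvc("Residual")
  re <- lme4::ranef(fit_r, condVar = TRUE)$genotype
  pv <- attr(re, "postVar")
  blups <- setNames(re[, 1], rownames(re))
  pev <- setNames(as.numeric(pv[1, 1, ]), rownames(re))

  fit_f <- quiet_bobyqa(suppressMessages(
    lme4::lmer(value ~ 0 + genotype + (1 | replicate),
               data = d, REML = TRUE, control = ctrl)))
  b <- lme4::fixef(fit_f)
  Vb <- as.matrix(vcov(fit_f))
  se <- sqrt(diag(Vb))
  gnames <- sub("^genotype", "", names(b))
  # genotype-specific part of the BLUE sampling variance: the average of
  # var(b_i - b_j)/2; block/replicate uncertainty shared by all genotypes
  # of the trial cancels here (it is absorbed by the environment intercept
  # in the stage-2 model)
  nb <- nrow(Vb)
  blue_d <- if (nb > 1) {
    mean(diag(Vb)) - (sum(Vb) - sum(diag(Vb))) / (nb * (nb - 1))
  } else as.numeric(Vb)

  sc_res <- resid(fit_r)
  sdr <- sd(sc_res)
  residuals <- tibble::tibble(
    genotype = as.character(d$genotype),
    replicate = as.character(d$replicate),
    value = d$value,
    std_resid = if (sdr > 0) as.numeric(sc_res) / sdr else 0 * sc_res
  )

  structure(
    list(trial_id = trial_id,
         mu = as.numeric(lme4::fixef(fit_r)[1]),
         sigma_g2 = sigma_g2, sigma_r2 = sigma_r2, sigma_e2 = sigma_e2,
         blups = blups, pev = pev,
         blues = setNames(as.numeric(b), gnames),
         blues_se = setNames(as.numeric(se), gnames),
         blue_d = blue_d,
         logREML = as.numeric(logLik(fit_r)),
         residuals = residuals,
         n_obs = nrow(d),
         genotypes = levels(d$genotype),
         boundary = min(sigma_g2, sigma_r2) < 1e-8),
    class = "trial_fit"
  )
}

#' @export
print.trial_fit <- function(x, ...) {
  cat("<trial_fit>", x$trial_id, "\n")
  cat(sprintf("  mu=%.3f sigma_g2=%.4f sigma_r2=%.4f sigma_e2=%.4f\n",
              x$mu, x$sigma_g2, x$sigma_r2, x$sigma_e2))
  cat(sprintf("  H2=%.3f Ac=%.3f CV%%=%.2f (%d genotypes, %d plots)\n",
              heritability_cullis(x), accuracy(x), cv_percent(x),
              length(x$genotypes), x$n_obs))
  invisible(x)
}

#' Cullis broad-sense heritability of a trial
#'
#' `H2 = 1 - mean(PEV) / (2 sigma_g^2)`, based on the mean prediction
#' error variance of the genotype BLUPs; clipped to \[0, 1\]. When the
#' genetic variance is estimated at zero the statistic is undefined and 0
#' is returned with attribute `undefined = TRUE`.
#'
#' @param fit A [fit_trial()] result.
#' @return Heritability in \[0, 1\].
#' @export
heritability_cullis <- function(fit) {
  if (fit$sigma_g2 <= 0) {
    return(structure(0, undefined = TRUE))
  }
  h2 <- 1 - mean(fit$pev) / (2 * fit$sigma_g2)
  min(max(h2, 0), 1)
}

#' Experimental (selection) accuracy of a trial
#'
#' Default form `Ac = sqrt(1 - mean(PEV) / sigma_g^2)`, the usual
#' correlation between true and predicted genotype effects. Setting
#' `as_printed = TRUE` returns the non-root form
#' `1 - mean(PEV) / sigma_g^2` (a reliability rather than an accuracy);
#' both are offered because both circulate in the applied literature.
#'
#' @param fit A [fit_trial()] result.
#' @param as_printed Use the non-root (reliability) form.
#' @return Accuracy in \[0, 1\]; values where `mean(PEV) > sigma_g^2` are
#'   clamped to 0 with attribute `clamped = TRUE`.
#' @export
accuracy <- function(fit, as_printed = FALSE) {
  if (fit$sigma_g2 <= 0) return(structure(0, undefined = TRUE))
  rel <- 1 - mean(fit$pev) / fit$sigma_g2
  if (rel < 0) return(structure(0, clamped = TRUE))
  if (as_printed) rel else sqrt(rel)
}

#' Residual coefficient of variation of a trial (%)
#'
#' `CV% = 100 * sigma_e / mu`, with the residual standard deviation in the
#' numerator.
#'
#' @param fit A [fit_trial()] result.
#' @param mu Trial mean; defaults to the fitted intercept.
#' @return CV in percent.
#' @export
cv_percent <- function(fit, mu = fit$mu) {
  if (mu <= 0) stop("mu must be positive", call. = FALSE)
  100 * sqrt(fit$sigma_e2) / mu
}

#' Adjusted genotype means (BLUEs) for one trial
#'
#' Generalized-least-squares genotype means from the genotype-fixed,
#' replicate-random model; on a balanced complete design these equal the
#' arithmetic genotype means. Genotypes absent from the trial are absent
#' from the table.
#'
#' @param records Plot records of one trial (see [fit_trial()]).
#' @param trial Optional trial id when `records` is a [met_dataset()].
#' @return A tibble with `genotype`, `blue`, `se`.
#' @export
adjusted_means <- function(records, trial = NULL) {
  fit <- if (inherits(records, "trial_fit")) records else fit_trial(records, trial)
  tibble::tibble(genotype = names(fit$blues),
                 blue = as.numeric(fit$blues),
                 se = as.numeric(fit$blues_se))
}

#' Residual outlier diagnostics for a trial fit
#'
#' Flags plots whose standardized conditional residual exceeds a threshold
#' in absolute value. Flags are advisory: nothing is removed.
#'
#' @param fit A [fit_trial()] result.
#' @param threshold Absolute standardized-residual threshold (default 3.5).
#' @return The residual tibble with a logical `flagged` column.
#' @export
residual_diagnostics <- function(fit, threshold = 3.5) {
  out <- fit$residuals
  out$flagged <- abs(out$std_resid) > threshold
  out
}

#' Stage-1 summary across all trials of a dataset
#'
#' Convenience wrapper fitting [fit_trial()] to every trial and collecting
#' the per-trial genetic parameters (the usual per-trial screening table).
#'
#' @param data A [met_dataset()].
#' @return A list with `fits` (named list of `trial_fit`) and `summary`
#'   (tibble: trial, mu, sigma_g2, sigma_r2, sigma_e2, H2, Ac, CV, n_gen).
#' @export
fit_all_trials <- function(data) {
  stopifnot(inherits(data, "met_dataset"))
  trials <- unique(data$records$trial_id)
  fits <- lapply(trials, function(tr) fit_trial(data, trial = tr))
  names(fits) <- trials
  summary <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(trial = f$trial_id, mu = f$mu,
                   sigma_g2 = f$sigma_g2, sigma_r2 = f$sigma_r2,
                   sigma_e2 = f$sigma_e2,
                   H2 = as.numeric(heritability_cullis(f)),
                   Ac = as.numeric(accuracy(f)),
                   CV = cv_percent(f),
                   n_gen = length(f$genotypes))
  }))
  list(fits = fits, summary = summary)
}
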