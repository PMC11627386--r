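---
title: "Factor-analytic analysis of multi-environment trials with famet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factor-analytic analysis of multi-environment trials with famet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

famet analyzes plant-breeding multi-environment trials (MET): series of
replicated field trials of a common set of genotypes across year-by-location
environments. Its core is a two-stage factor-analytic (FA) mixed-model
pipeline for dissecting genotype-by-environment (G×E) interaction, flanked by
the classical AMMI and GGE decompositions and a synthetic data generator that
makes the whole pipeline testable without field data. This vignette explains
the models, the assumptions behind them, the tunable parameters, and the
numerical and design choices that were genuinely open.

## Stage 1: per-trial mixed models

Each trial (one environment) is an RCBD analyzed with the linear mixed model

$$ y = \mu 1_n + Z_1 r + Z_2 g + \varepsilon, \qquad
   r \sim N(0, \sigma^2_r I), \;
   g \sim N(0, \sigma^2_g I), \;
   \varepsilon \sim N(0, \sigma^2_e I), $$

fitted by REML (`fit_trial()`, via lme4 with the bobyqa optimizer at
`rhoend = 1e-10`, tight enough that balanced-design estimates agree with the
closed-form ANOVA estimators to about 1e-8 relative). From the
genotype-random fit come the variance components, genotype BLUPs and their
prediction error variances (PEV), and three per-trial quality statistics:

* Cullis heritability $H^2 = 1 - \overline{PEV} / (2\hat\sigma^2_g)$,
  clipped to [0, 1];
* experimental accuracy, by default the root form
  $Ac = \sqrt{1 - \overline{PEV}/\hat\sigma^2_g}$ — the correlation between
  true and predicted effects. The non-root variant (a reliability) also
  circulates in the applied literature, so `accuracy(fit, as_printed = TRUE)`
  provides it; the root form is the default because it is the quantity
  usually called "accuracy";
* $CV\% = 100\,\hat\sigma_e/\hat\mu$, with the residual *standard deviation*
  in the numerator (the standard CV definition; a variance there would not be
  dimensionless).

Adjusted means for stage 2 are BLUEs from the companion genotype-fixed,
replicate-random fit — not BLUPs, which are shrunken and would bias the
stage-2 loadings. Residual diagnostics flag plots with standardized
conditional residuals beyond 3.5 in absolute value; flags are advisory and
nothing is ever auto-removed.

## Stage 2: the joint factor-analytic model

The genotype-by-environment table of adjusted means is modeled as

$$ \bar y_{il} = \beta_l + u_{il} + e_{il}, $$

where the rows $u_i = (u_{i1}, \dots, u_{is})$ are iid
$N(0, \Lambda \Lambda' + \Psi)$ across the $s$ environments, with $\Lambda$
an $s \times k$ loading matrix, $\Psi = \mathrm{diag}(\psi_1..\psi_s)$ the
environment-specific genetic variances, and $e_{il}$ a diagonal stage-2
residual. $\Lambda\Lambda'$ is the genetic covariance the environments
share through the $k$ latent factors; $\psi_l$ is genetic variance unique to
environment $l$. Genotype scores $f_i$ link the two sides: the genetic
effect decomposes as $u_{il} = \lambda_l' f_i + \delta_{il}$.

`fit_fa()` maximizes the restricted likelihood directly. Genotypes with the
same observed-environment set share one Cholesky factorization per
likelihood evaluation, so complete tables cost a single $s \times s$
factorization per evaluation and unbalanced tables one per missingness
pattern. Missing cells are allowed as long as the environment-sharing graph
is connected (`means_table()` refuses disconnected incidences, naming the
isolated component). BLUPs for *every* cell follow from the mixed-model
equations: $\hat u_i = G[, O_i]\, C_{O_i}^{-1} (y_i - \beta)_{O_i}$ with
$G = \Lambda\Lambda' + \Psi$, which predicts untested cells through the
common factors alone.

Numerical choices:

* **Identifiability.** $\Lambda$ is constrained upper-triangle-zero during
  optimization (any loading matrix can be rotated to this form without
  changing $\Lambda\Lambda'$); interpretation happens only after varimax
  rotation. Column signs are fixed so diagonal loadings are non-negative.
* **Stage-2 residual.** A free diagonal stage-2 residual on top of free
  $\Psi$ is not identifiable — only their sum enters the likelihood — so it
  is not offered. Instead the residual variance $d_l$ is fixed from stage 1
  (`stage2_resid = "se"`, the default when the means table carries standard
  errors) or absorbed into $\psi_l$ (`"none"`). The fixed $d_l$ is the
  *genotype-specific* part of the BLUE sampling variance, estimated as the
  average of $\mathrm{var}(\hat b_i - \hat b_j)/2$ from the BLUE
  variance-covariance matrix; block-level uncertainty shared by all
  genotypes of a trial cancels in differences and is absorbed by $\beta_l$,
  so using raw squared SEs would overstate $d_l$ and bias $\psi_l$ down.
* **Optimizer.** L-BFGS-B on (free loadings, $\log \psi$), converging at
  about 1e-9 relative. Starts: the leading-$k$ eigendecomposition of the
  pairwise-complete sample covariance of environment columns, rotated to
  lower-trapezoidal form, plus one jittered copy (`n_starts = 2`). With the
  eigen start the optimum was reached from every start in all our checks,
  so a larger multistart budget buys nothing at these problem sizes;
  `n_starts` is exposed for harder data. `model_search()` additionally
  warm-starts each order from the previous one, which keeps the restricted
  log-likelihood non-decreasing in $k$.
* **Order selection.** $AIC = -2\,\mathrm{logREML} + 2\,NP$ with $NP$
  counting variance-covariance parameters only
  ($sk - k(k-1)/2$ loadings plus $s$ specific variances); the minimum-AIC
  order wins.

Derived summaries: the percentage of genetic variance captured by the
factors, $\bar\nu = 100\,\mathrm{tr}(\Lambda\Lambda') /
\mathrm{tr}(\Lambda\Lambda' + \Psi)$ (the trace is applied to both numerator
and denominator — the only reading that yields a scalar percentage — and the
per-factor shares sum to the overall value); the between-environment genetic
correlation matrix $\rho_{ll'} = G_{ll'} / \sqrt{G_{ll} G_{l'l'}}$; and an
observed-versus-fitted Pearson correlation (`fit_accuracy()`) as a simple
goodness-of-fit number for the chosen order, typically above 0.9 when the
factors capture the data well.

## Varimax rotation and latent-regression stability

The unrotated loadings are a mathematical convenience; `varimax_rotate()`
applies raw varimax (Kaiser row normalization off by default — the choice is
exposed because sources differ and neither is canonical), reorders factors
by explained variance and fixes signs so each factor's largest-magnitude
loading is positive. $\Lambda\Lambda'$, the genetic correlations and all
fitted values are invariant; only the coordinate system changes.

`latent_regression()` reads stability off the rotated fit: for genotype $i$
and factor $r$, the regression line of predicted genetic values on the
environmental loadings of factor $r$ has slope $\beta_1 = \tilde f_{ir}$,
the rotated genotype score. No least-squares refit is needed — in the FA
decomposition the score *is* the latent-regression coefficient (on noiseless
data, multiple OLS of a genotype's effects on the rotated loading columns
returns the scores exactly, a property the tests assert). The exported plot
data carries the per-environment predicted values with tested/untested
flags; whether plotted points for tested cells include the
environment-specific deviation is a presentation choice, so both the full
BLUP (`predicted`) and the flags are exported and the line uses the mean
BLUP plus $\beta_1 x$ convention.

`classify_stability()` labels slopes: $|\beta_1| \le$ 0.5 stable,
$\beta_1 \ge$ 1 responsive, $\beta_1 \le -1$ negatively responsive, else
intermediate. The defaults follow the verbal conventions of the stability
literature (slopes "close to zero" are stable; slopes above 1 mark genotypes
that exploit favourable environments); both thresholds are arguments because
the bands are conventions, not estimates.

## AMMI and GGE

As comparators, `fit_ammi()` double-centers the two-way table (grand mean,
genotype and environment main effects — the genotype main effect is included
even though some presentations of the model elide it, since omitting it
would fold genotype differences into the interaction) and takes the SVD of
the residual; $\sum_n \lambda_n^2$ reproduces the interaction sum of squares
to machine precision. Multiplicative terms get Gollob degrees of freedom
$m + s - 1 - 2n$ and, when a replicate count and pooled error variance are
supplied, an F-type test against the error variance of a mean — chosen
because it is computable from the means table alone; resampling-based
alternatives are out of scope. Genotypes are ranked by $|IPCA_1|$ ascending
with main-effect tie-breaks. `fit_gge()` centers by environment means
(keeping G plus G×E), and symmetric scaling splits each singular value
$\sqrt{\lambda_n}$–$\sqrt{\lambda_n}$ between genotype and environment
coordinates. Both need complete tables; `impute_two_way()` fills missing
cells by alternating an additive fit with a rank-$r$ SVD reconstruction
until cells move less than `tol` (exact for tables that truly are
additive-plus-low-rank, which the tests verify by construction).

## Joint variance components and covariate correlations

`fit_joint_vc()` fits the compound joint model (environment fixed;
genotype, G×E and replicate-within-environment random; pooled residual) and
derives $\sigma^2_p = \sigma^2_g + \sigma^2_{g\times e}/E + \sigma^2_e/(ER)$,
$CV_g$, $CV_r$ and their ratio, $r_{ge} = \sigma^2_g/(\sigma^2_g +
\sigma^2_{g\times e})$, $r_i^2$, and entry-mean heritability
$\sigma^2_g/\sigma^2_p$. All CVs put standard deviations over the mean.
$P{-}G$ is the phenotypic minus the genotypic coefficient of variation,
with $CV_p = 100\sqrt{\sigma^2_p}/\bar x$ — the standard definition, made
explicit here because the quantity is often reported without one. Under
unbalance, $E$ and $R$ are harmonic means of the per-genotype environment
counts and per-cell replicate counts, the natural effective counts for
variances of means. Likelihood-ratio tests for the random terms use REML
fits with identical fixed effects and the 50:50 $\chi^2_0$:$\chi^2_1$
mixture appropriate for a variance tested on its boundary — without the
mixture the test would be conservative by about a factor of two.

`loading_covariate_correlations()` correlates each rotated factor's
loadings with each environmental covariate (Tmax, Tmin, Tav, Rain, Rh,
wind speed, solar radiation, altitude, plus any extra columns) across
environments, with two-sided t-based p-values starred at 0.05/0.01/0.001.
Raw p-values are the default, matching how such correlation grids are
conventionally reported; `adjust = "BH"` is available for users who prefer
false-discovery-rate control over the grid.

## The synthetic MET generator

`simulate_met()` draws data from exactly the process the stage-2 model
assumes: loadings $\Lambda$ (first factor half-normal, so it acts like the
dominant, mostly-positive common factor seen in real trial series; later
factors centered), specific deviations with diagonal $\Psi$, iid standard
normal scores, environment main effects, per-trial replicate effects, and
heterogeneous per-environment residual noise. Unbalance
(`apply_unbalance()`) removes whole genotype-environment cells completely
at random — mimicking clone promotion and removal between seasons — under
three constraints: each genotype keeps at least half the environments (the
usual screening rule for stability candidates), each environment keeps at
least three genotypes, and the environment-sharing graph stays connected.
`simulate_covariates()` engineers one covariate with an exact population
correlation to the first-factor loadings via the mixture
$c = r\,z(\Lambda_1) + \sqrt{1-r^2}\,\varepsilon$ (default target 0.58, a
magnitude typical of rainfall-loading associations in tropical root-crop
series), plus independent nuisance covariates on plausible meteorological
scales.

Default scales emulate a cassava-type fresh-root-yield series: 22 genotypes,
20 environments, 3 replicates, grand mean 24 t/ha, environment effects with
SD 5 t/ha, genetic signal of roughly 4–5 (t/ha)² per environment against
residual SDs of 1.5–3 t/ha. Two calibration facts guided these choices,
fixed before any downstream testing: per-trial Cullis $H^2$ should
concentrate above 0.6 with a long left tail (most real uniform-yield trials
do), and the factors should carry most of the genetic variance (specific
variances around 10–15% of the total). The generator reproduces both.

What the generator does *not* emulate: spatial field trend within trials,
non-normal or outlier-prone residuals, informative (non-MCAR) missingness
tied to genotype performance, correlated specific effects, and any real
weather process behind the covariates (they are statistical stand-ins).
Passing tests therefore demonstrate correctness of the estimation machinery
under the assumed model, not robustness to these violations.

## Verification strategy and problem sizes

The test suite checks every stage against an independent route: the FA
restricted likelihood against a dense brute-force evaluation of the full
covariance (m ≤ 20, s ≤ 5, agreement ~1e-14); balanced-design REML against
closed-form ANOVA estimators; BLUEs against direct GLS matrix inversion;
varimax against 1,000 random orthonormal rotations per case; AMMI singular
values against directly summed interaction SS; latent-regression slopes
against OLS. Statistical performance is measured by simulation at m = 200
genotypes and s = 10 environments (10 seeds) for covariance recovery and
AIC order selection, 1,000 null replicates at s = 55 for the calibration of
the covariate t-test, and one full 22 × 20 pipeline run — sizes chosen so
the whole suite exercises realistic scales while staying quick enough to
run routinely. At these conditions the Frobenius error of $\hat G$ is
dominated by genotype sampling: the sample covariance of the *true* genetic
effects at m = 200 already sits near 0.11 relative error, and REML tracks
that floor, so recovery accuracy is limited by the design, not the
estimator (which the tests show is unbiased and start-insensitive).

## Known limitations

* Stage 1 has no spatial (row-column, AR1) residual models and no
  heterogeneous block variances within a trial.
* Stage 2 places the FA structure on the genetic covariance only; replicate
  and residual structures are per-trial diagonals resolved in stage 1, and
  there is no pedigree or genomic relationship matrix, no multi-trait fit,
  and no one-stage joint fit of plot data.
* AMMI/GGE significance is Gollob-style only; no ASV/WAAS-type derived
  indices and no cross-validation of ranks.
* Mega-environment delineation is left to the user (the genetic correlation
  matrix and biplot coordinates are exported for it).
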