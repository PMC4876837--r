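---
title: "Splitting, analyzing, and meta-analyzing large tabular data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting, analyzing, and meta-analyzing large tabular data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`sammeta` treats a large rectangular dataset as a collection of
pseudo-studies. Each study $i$ is analyzed on its own, producing an
effect-size vector $y_i$ (regression slopes, an indirect/direct effect
pair, a reliability coefficient, or vectorized correlations) and its
sampling covariance matrix $V_i$, which downstream stages treat as known.
The pooling stage fits one of three marginal models:

* **fixed-effects**: $y_i \sim N(\gamma, V_i)$ — generalized least squares
  with weights $V_i^{-1}$. This is the right model after a *random* split,
  because every study then estimates the same population parameters and
  all between-study variation is sampling error. Pooling the per-chunk
  estimates this way reproduces the full-data estimator up to numerical
  and rounding differences, which is what makes chunked estimation on
  out-of-core data trustworthy.
* **random-effects**: $y_i \sim N(\gamma, V_i + T^2)$, with the
  between-study covariance $T^2$ estimated by REML (default) or ML. This
  matches a *stratified* split, where strata (countries, waves, years)
  plausibly have their own population parameters.
* **mixed-effects**: $y_{ji} = \gamma_{j0} + \gamma_{j1} x_i + u_{ji} +
  e_{ji}$ per effect dimension $j$, with stratum-level moderators $x_i$
  predicting the effects and $T^2$ now a residual covariance.

Heterogeneity is reported per effect as
$I^2_j = \hat T^2_{jj} / (\hat T^2_{jj} + \bar V_{jj})$ and moderation as
$R^2_j = \max(0, 1 - \hat T^2_{jj}(\text{moderated}) /
\hat T^2_{jj}(\text{baseline}))$, both clamped to $[0, 1]$.

Key assumptions: per-study samples large enough that the estimates are
approximately multivariate normal with known covariance (the default
minimum study size of 100 exists for this reason); independent studies
(each row lands in exactly one study); and, for the random/mixed models,
normally distributed true effects across strata.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_study_size` | 100 rows | studies smaller than this after listwise deletion are dropped with a warning; below ~100 the normal-with-known-covariance approximation for effect sizes degrades |
| `chunk_rows` | 10000 | rows per streaming CSV/SQLite read; memory is bounded by `chunk_rows × p` |
| `tau2_structure` | `full` | `full` (unstructured), `diagonal`, or `zero`; `zero` reduces the random model exactly to fixed-effects pooling |
| `estimator` | `REML` | `ML` is available for likelihood-ratio comparisons between nested mean structures |
| `center` | `TRUE` | moderators are mean-centered; this affects only the meaning of intercepts, never slopes, `T²`, or `R²` |
| `typical` (in `i_squared`) | `higgins` | the "typical" within-study variance $\bar V$: the Q-based Higgins–Thompson value $(k-1)\sum w / ((\sum w)^2 - \sum w^2)$, $w = 1/V_{i,jj}$; a harmonic-mean option exists. With equal per-study variances both reduce to that common variance |
| `transform` (alpha) | `raw` | pool raw coefficient alpha with variance $2p(1-\alpha)^2 / ((p-1)(n-2))$; `bonett` pools $\ln(1-\alpha)$ with variance $2p/((p-1)(n-2))$ and is preferable when alphas approach 1 |
| `ci` (stage 2) | `wald` | profile-discrepancy intervals (`profile`) find where the profiled WLS discrepancy rises by the $\chi^2_1$ critical value; slower but asymmetric-aware |

## Design choices where the design was open

* **Missing data.** Rows with missing values in any analysis variable are
  dropped listwise *within* each study after the split, and the deletion
  count is logged per study. Listwise deletion is the simplest policy
  compatible with treating $V_i$ as known; model-based alternatives would
  couple the stages.
* **Intercept pooling.** Per-study regression intercepts are estimated but
  excluded from the pooled effect vector by default: under a stratified
  split intercepts absorb stratum-level location differences that are
  usually not the estimand. `include_intercept = TRUE` switches this.
* **Mediation covariance.** The a-path and the (b, c′) regression are
  separate fits; their cross-covariance is set to zero, which is the
  asymptotic value under the recursive model. The delta-method variance
  $b^2\mathrm{Var}(a) + a^2\mathrm{Var}(b)$ is first-order; the tests
  verify it against the Monte-Carlo SD of $\hat a\hat b$ at $n = 500$.
* **Correlation covariances.** Normal-theory (Olkin–Siotani) asymptotic
  covariances, each element scaled by $1/n$, in a fixed column-major
  lower-triangle order (`(2,1), (3,1), …`) asserted everywhere. A
  distribution-free weight matrix is out of scope.
* **Stage-1 $T^2$ is diagonal by default.** An unstructured $T^2$ over
  $q = p(p-1)/2$ correlations has $q(q+1)/2$ parameters (21 already for
  four variables) and is fragile at realistic study counts; the diagonal
  default is the established choice for pooling correlations. `full` is
  exposed for small $q$.
* **Stage-2 chi-square convention.** The WLS weight matrix is the
  covariance of the *pooled* correlations, which already carries the total
  precision of stage 1, so the minimized discrepancy is itself the
  chi-square statistic. Users comparing against single-sample SEM
  chi-squares (where the discrepancy is multiplied by $N-1$) should use
  the reported `total_n` to translate conventions.
* **Heywood cases** (communality above one) are reported and flagged, not
  constrained away; a flagged solution is a model-misfit signal the user
  should see.
* **Ellipses.** The 95% confidence ellipse is centered at the pooled
  estimates with shape $\hat T^2$ — it depicts the dispersion of *true
  study effects*. Adding the sampling covariance of $\hat\gamma$
  (`include_gamma_cov = TRUE`) turns it into a predictive region.
* **Crossed mixed models** are random-intercepts only (month/day/airport
  style structure); random slopes are out of scope. Estimation delegates
  to lme4's REML machinery; single-level factors are dropped to the
  residual with a warning rather than silently absorbed.
* **No multiplicity correction** is applied; Wald z statistics are
  reported per coefficient and readers can adjust as their field requires.

## Numerical choices

$T^2$ is parameterized through its Cholesky factor with an exponentiated
diagonal (log-SD scale for the diagonal structure), which enforces
positive semi-definiteness without constraints and removes sign
ambiguity. Starting values are $0.1\times$ the between-study variance of
each effect; log-SDs are bounded in $[-20, 20]$, so a boundary solution
($T^2 \to 0$) is representable to numerical zero and is flagged
(`boundary = TRUE`) when a diagonal entry falls below $10^{-6}$ of the
typical sampling variance. The profiled (restricted) deviance is
minimized with `nlminb` at a relative tolerance of $10^{-10}$, 500
iterations maximum; non-convergence is an error carrying the last
iterate, and "false convergence" is downgraded to a warning with
`converged = FALSE`. The GLS solve uses Cholesky factorizations
throughout; a non-positive-definite $V_i + T^2$ during search returns an
infinite objective rather than crashing. Stage-2 loadings are bounded in
$[-2, 2]$, started at 0.5, and sign-canonicalized so each factor's
loading sum is positive; standard errors come from the analytic WLS
information $(J' W J)^{-1}$ rather than a numerical Hessian. Degenerate
inputs (constant columns, zero scale variance, collinear designs,
singular $V_i$ in fixed pooling, singular ellipse shapes) raise classed
errors naming the offending column or study.

## What the generators emulate — and what they do not

The simulators produce strata-labelled raw data matching the pooling
models' own data-generating process: per-stratum coefficient vectors
drawn as $\beta_i \sim N(\gamma + \Gamma x_i, T^2)$ with standard-normal
(optionally compound-symmetric correlated) predictors and normal errors;
per-stratum factor loadings perturbed around population values;
per-stratum mediation paths; crossed random intercepts with chosen
variance components. Every generator requires a seed, is byte-reproducible,
and emits a JSON truth record next to the CSV so recovery tests never
re-derive truth from the code paths under test.

They deliberately do **not** emulate: ordinal/Likert response formats,
survey weights, informative missingness, non-normal effect distributions,
or unequal real-world stratum-size distributions (a range of sizes is
supported, but sizes are drawn uniformly). Passing recovery tests
therefore demonstrates correctness of the estimators *under their own
assumptions*, not robustness to violations of them.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` exercise, among others:
split-versus-full-data agreement on $N = 200{,}000$ rows with 5
predictors at $k \in \{1, 5, 10, 50\}$ (slopes within $10^{-3}$, SEs
within 2%); bivariate random-effects recovery at $k = 200$, $n = 500$
over 25 replicates (bias below 0.02 on $\gamma$ and $T^2$); moderator
$R^2$ at $k = 300$ averaged over 4 replicates (within 0.1 of the
constructed 0.5); one-factor recovery at $k = 50$, $n = 500$ (loadings
within 0.02 of truth) and null calibration of the stage-2 chi-square
over 200 replicates at $k = 20$, $n = 150$ (mean within 30% of its df);
delta-method and Bonett variances against 2000-replicate and
1000-resample oracles (5% and 10%, the bootstrap ratio averaged over 6
independent samples); crossed variance-component recovery
at $n = 6000$ over 20 replicates (bias below 0.1); and 95%-ellipse
coverage over $10^5$ draws ($\pm 1$ point). These sizes were chosen so
each property is measured well inside its Monte-Carlo error.

## Known limitations

* Fixed-effects pooling assumes exchangeable rows; applying it after a
  stratified split conflates heterogeneity with sampling error (the
  reverse — random-effects after a random split — is merely conservative).
* $V_i$ is treated as known; with very small studies its own sampling
  error propagates into $\hat T^2$.
* The factor models are independent-cluster with orthogonal unit-variance
  factors; no rotation, correlated factors, mean structures, or general
  SEM path models.
* GLMs, ordinal models, and cluster/latent-class per-study models are out
  of scope, as are streaming/cumulative updating of an existing pooled
  fit and distributed (cluster) execution.
* The two-pass CSV reader bounds memory per chunk but materializes each
  study's block; a stratum larger than memory would require a further
  within-stratum split.
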