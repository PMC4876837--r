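# Two-stage SEM on correlation-matrix effect sizes: stage 1 pools the
# per-study correlations under a random-effects model; stage 2 fits a
# factor model to the pooled correlations by weighted least squares with
# the pooled estimates' asymptotic covariance as the weight matrix.

#' Specify a confirmatory factor model
#'
#' Independent-cluster factor model with orthogonal factors of unit
#' variance (the identification constraint) and free error variances
#' implied by the unit diagonal of a correlation matrix.
#'
#' @param vars Observed variable names, in the order used by the
#'   correlation studies.
#' @param loading_pattern Named character vector mapping each variable to
#'   its factor; default puts every variable on a single factor `"F1"`.
#' @return A `sam_factor_spec`.
#' @export
factor_model_spec <- function(vars, loading_pattern = NULL) {
  p <- length(vars)
  if (p < 2) sam_abort("invalid_argument", "factor model needs at least 2 variables")
  if (is.null(loading_pattern))
    loading_pattern <- setNames(rep("F1", p), vars)
  if (!all(vars %in% names(loading_pattern)))
    sam_abort("invalid_argument", "every variable must load on a factor")
  loading_pattern <- loading_pattern[vars]
  q <- (p * (p - 1L)) %/% 2L
  df <- q - p
  if (df < 0)
    sam_abort("invalid_argument",
              sprintf("model not identified: %d correlations < %d free loadings", q, p))
  structure(list(vars = vars, p = p, loading_pattern = loading_pattern,
                 factors = unique(unname(loading_pattern)), q = q, df = df),
            class = "sam_factor_spec")
}

#' Stage 1: pool correlation matrices
#'
#' Multivariate random-effects meta-analysis of the vectorized
#' lower-triangle correlations, with each study's normal-theory asymptotic
#' covariance as the known sampling covariance. The between-study
#' covariance is diagonal by default (the established default for pooling
#' correlations, and much more stable than an unstructured matrix on
#' `q(q+1)/2` parameters); set `tau2_structure = "full"` to relax this.
#'
#' @param corr_studies List of `sam_corr_study` from [correlation_study()],
#'   identical variable set and order.
#' @param tau2_structure `"diagonal"` (default) or `"full"`.
#' @param estimator `"REML"` (default) or `"ML"`.
#' @return A `sam_stage1` with `r_pooled`, `acov_pooled`, `tau2_diag`,
#'   `pooled_R` (the reconstructed correlation matrix), `total_n`, `k`,
#'   `vars`, and the underlying `fit`.
#' @export
tssem_stage1 <- function(corr_studies, tau2_structure = c("diagonal", "full"),
                         estimator = c("REML", "ML")) {
  tau2_structure <- match.arg(tau2_structure)
  estimator <- match.arg(estimator)
  if (length(corr_studies) < 2)
    sam_abort("insufficient_studies", "stage 1 needs at least 2 studies")
  vars <- corr_studies[[1]]$vars
  for (cs in corr_studies) {
    if (!identical(cs$vars, vars))
      sam_abort("schema", sprintf("study %s has a different variable set/order", cs$study_id))
  }
  effects <- lapply(corr_studies, corr_study_to_effect_set)
  spec <- meta_model_spec("random", tau2_structure = tau2_structure,
                          estimator = estimator)
  fit <- meta_random(effects, spec)
  p <- length(vars)
  r_pooled <- fit$gamma
  if (any(abs(r_pooled) >= 1))
    sam_abort("convergence", "pooled correlation outside (-1, 1)")
  pooled_R <- unvech_corr(as.numeric(r_pooled), p)
  dimnames(pooled_R) <- list(vars, vars)
  structure(list(r_pooled = r_pooled, acov_pooled = fit$cov_gamma,
                 tau2_diag = diag(fit$tau2), pooled_R = pooled_R,
                 total_n = fit$total_n, k = fit$k, vars = vars,
                 converged = fit$converged, fit = fit),
            class = "sam_stage1")
}

#' @export
print.sam_stage1 <- function(x, ...) {
  cat(sprintf("<sam_stage1> pooled correlations from k = %d studies, total n = %d\n",
              x$k, x$total_n))
  print(round(x$pooled_R, 4))
  invisible(x)
}

# Model-implied off-diagonal correlations and their Jacobian for an
# independent-cluster pattern with Phi = I: rho(i,j) = lambda_i lambda_j
# when i and j share a factor, 0 otherwise.
model_rho <- function(lambda, spec, pairs) {
  same <- spec$loading_pattern[pairs[, 1]] == spec$loading_pattern[pairs[, 2]]
  rho <- ifelse(same, lambda[pairs[, 1]] * lambda[pairs[, 2]], 0)
  as.numeric(rho)
}

model_jacobian <- function(lambda, spec, pairs) {
  q <- nrow(pairs); p <- spec$p
  J <- matrix(0, q, p)
  same <- spec$loading_pattern[pairs[, 1]] == spec$loading_pattern[pairs[, 2]]
  for (s in which(same)) {
    i <- pairs[s, 1]; j <- pairs[s, 2]
    J[s, i] <- lambda[j]
    J[s, j] <- lambda[i]
  }
  J
}

#' Stage 2: fit the factor model to the pooled correlations
#'
#' Minimizes the weighted-least-squares discrepancy
#' `F(lambda) = (r - rho(lambda))' acov_pooled^-1 (r - rho(lambda))` where
#' `rho(lambda)` holds the model-implied correlations. Because the weight
#' matrix is the asymptotic covariance of the *pooled* correlations
#' (already carrying the total precision), the minimized discrepancy is
#' itself the chi-square statistic; `rmsea = sqrt(max(chi2 - df, 0) /
#' (df * total_n))` and `srmr` is the root mean squared residual
#' correlation. Standard errors come from the inverse WLS information
#' `(J' W J)^-1`; confidence intervals are Wald by default, or
#' profile-discrepancy (`ci = "profile"`, the slower likelihood-based
#' style: the loading value where the profiled discrepancy rises by the
#' chi-square(1) critical value).
#'
#' @param stage1 A `sam_stage1` from [tssem_stage1()].
#' @param spec A [factor_model_spec()] over the same variables.
#' @param ci `"wald"` or `"profile"`.
#' @param level CI level.
#' @return A `sam_stage2` with `loadings`, `se`, `ci_lower`/`ci_upper`,
#'   `error_variances`, `F_min`, `chi2`, `df`, `p_value`, `rmsea`, `srmr`,
#'   `residuals`, `heywood`, `converged`.
#' @export
tssem_stage2 <- function(stage1, spec, ci = c("wald", "profile"), level = 0.95) {
  ci <- match.arg(ci)
  if (!inherits(stage1, "sam_stage1")) sam_abort("schema", "stage1 must be a sam_stage1")
  if (!identical(stage1$vars, spec$vars))
    sam_abort("schema", "stage-1 variables do not match the factor model spec")
  if (!stage1$converged) sam_abort("convergence", "stage 1 did not converge")
  p <- spec$p
  pairs <- vech_pairs(p)
  r <- as.numeric(stage1$r_pooled)
  W <- tryCatch(solve(stage1$acov_pooled),
                error = function(e) sam_abort("conditioning",
                                              "pooled acov is singular"))
  discrepancy <- function(lambda) {
    d <- r - model_rho(lambda, spec, pairs)
    as.numeric(d %*% W %*% d)
  }
  opt <- stats::nlminb(rep(0.5, p), discrepancy,
                       lower = rep(-2, p), upper = rep(2, p),
                       control = list(rel.tol = 1e-14, iter.max = 500))
  if (!opt$convergence %in% 0:1 ||
      (opt$convergence == 1 && !grepl("convergence", opt$message %||% "")))
    sam_abort("convergence", sprintf("stage 2 did not converge: %s",
                                     opt$message %||% ""), last_par = opt$par)
  lambda <- opt$par
  # sign indeterminacy: canonicalize each factor to a positive loading sum
  for (f in spec$factors) {
    on_f <- spec$loading_pattern == f
    if (sum(lambda[on_f]) < 0) lambda[on_f] <- -lambda[on_f]
  }
  F_min <- discrepancy(lambda)
  J <- model_jacobian(lambda, spec, pairs)
  info <- t(J) %*% W %*% J
  cov_lambda <- tryCatch(solve(info), error = function(e) matrix(NA, p, p))
  se <- sqrt(pmax(diag(cov_lambda), 0))
  resid <- r - model_rho(lambda, spec, pairs)
  chi2 <- F_min
  df <- spec$df
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * stage1$total_n)) else 0
  srmr <- sqrt(mean(resid^2))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  lower <- lambda - zc * se
  upper <- lambda + zc * se
  if (ci == "profile") {
    crit <- stats::qchisq(level, df = 1)
    for (j in seq_len(p)) {
      prof <- profile_ci_loading(j, lambda, F_min, crit, spec, pairs, r, W)
      lower[j] <- prof[1]; upper[j] <- prof[2]
    }
  }
  names(lambda) <- names(se) <- names(lower) <- names(upper) <- spec$vars
  communality <- vapply(seq_len(p), function(i) lambda[i]^2, numeric(1))
  structure(list(loadings = lambda, se = se, ci_lower = lower, ci_upper = upper,
                 ci_type = ci, level = level,
                 error_variances = setNames(1 - communality, spec$vars),
                 F_min = F_min, chi2 = chi2, df = df,
                 p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_,
                 rmsea = rmsea, srmr = srmr, residuals = resid,
                 heywood = any(communality > 1 + 1e-8),
                 converged = TRUE, total_n = stage1$total_n),
            class = "sam_stage2")
}

# Profile-discrepancy CI for one loading: the values on either side of the
# optimum where min-over-the-other-loadings of F equals F_min + crit.
profile_ci_loading <- function(j, lambda, F_min, crit, spec, pairs, r, W) {
  p <- length(lambda)
  prof <- function(lj) {
    if (p == 1) return(sum((r - model_rho(lj, spec, pairs)) * (W %*% (r - model_rho(lj, spec, pairs)))))
    fn <- function(rest) {
      full <- numeric(p); full[j] <- lj; full[-j] <- rest
      d <- r - model_rho(full, spec, pairs)
      as.numeric(d %*% W %*% d)
    }
    stats::nlminb(lambda[-j], fn, lower = rep(-2, p - 1), upper = rep(2, p - 1),
                  control = list(rel.tol = 1e-12))$objective
  }
  target <- F_min + crit
  find_side <- function(dir) {
    step <- 0.01
    x <- lambda[j]
    for (iter in 1:60) {
      x2 <- x + dir * step
      if (prof(x2) >= target) {
        return(stats::uniroot(function(z) prof(z) - target,
                              lower = min(x, x2), upper = max(x, x2),
                              tol = 1e-7)$root)
      }
      x <- x2
      step <- step * 1.6
    }
    dir * Inf
  }
  c(find_side(-1), find_side(1))
}

#' @export
print.sam_stage2 <- function(x, ...) {
  cat(sprintf("<sam_stage2> chi2(%d) = %.4f, RMSEA = %.4f, SRMR = %.4f\n",
              x$df, x$chi2, x$rmsea, x$srmr))
  tab <- cbind(loading = x$loadings, se = x$se,
               lower = x$ci_lower, upper = x$ci_upper,
               err_var = x$error_variances)
  print(round(tab, 4))
  if (x$heywood) cat("warning: Heywood case (communality > 1)\n")
  invisible(x)
}
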