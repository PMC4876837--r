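#' Per-study crossed random-intercepts mixed model
#'
#' Fits a linear mixed model with fixed-effect slopes and crossed random
#' intercepts for each factor in `random_factors`, by REML via
#' [lme4::lmer()]. The fixed-effect slopes and their REML covariance form
#' the effect size passed downstream; the variance components, residual
#' variance, restricted log-likelihood, and convergence state are returned
#' alongside. Factors with a single observed level carry no information
#' about a variance component and are dropped to the residual with a
#' warning; if none remain the model reduces to [fit_ols_study()].
#'
#' @inheritParams fit_ols_study
#' @param random_factors Character vector of grouping-factor names.
#' @return An [effect_set()] (fixed-effect slopes, REML covariance) with an
#'   extra field `lmm`: a list with `fixed` (all fixed coefficients),
#'   `fixed_cov`, `varcomps` (named, >= 0), `sigma2`, `converged`,
#'   `boundary`, `reml_loglik`, `dropped_factors`.
#' @export
fit_crossed_lmm_study <- function(frame, outcome, predictors, random_factors,
                                  include_intercept = FALSE,
                                  moderators = numeric(0)) {
  data <- frame_data(frame)
  miss <- setdiff(c(outcome, predictors, random_factors), names(data))
  if (length(miss))
    sam_abort("schema", paste("variables absent from frame:", paste(miss, collapse = ", ")))
  n <- nrow(data)
  if (n <= length(predictors) + length(random_factors) + 1)
    sam_abort("insufficient_data", "too few rows for the requested model")

  dropped <- character(0)
  keep_factors <- character(0)
  for (f in random_factors) {
    if (length(unique(data[[f]])) < 2) {
      sam_warn("single_level_factor",
               sprintf("random factor '%s' has one observed level; dropped to residual", f))
      dropped <- c(dropped, f)
    } else keep_factors <- c(keep_factors, f)
  }
  if (!length(keep_factors)) {
    es <- fit_ols_study(data, outcome, predictors,
                        include_intercept = include_intercept,
                        moderators = moderators)
    es$study_id <- frame_id(frame)
    es$lmm <- list(fixed = es$coefficients, fixed_cov = NULL,
                   varcomps = setNames(numeric(0), character(0)),
                   sigma2 = es$sigma2, converged = TRUE, boundary = FALSE,
                   reml_loglik = NA_real_, dropped_factors = dropped)
    return(es)
  }

  # Aliasing of a factor with the fixed design surfaces as rank deficiency
  # of the fixed part; check it the same way the OLS path does.
  X <- design_matrix(data, predictors)
  if (qr(X)$rank < ncol(X))
    sam_abort("singular_design", "fixed-effect design is rank deficient")

  df <- data
  for (f in keep_factors) df[[f]] <- factor(df[[f]])
  fixed_part <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(
    outcome, "~", fixed_part, "+",
    paste(sprintf("(1 | %s)", keep_factors), collapse = " + ")))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      fml, data = df, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore"))),
    error = function(e) sam_abort("convergence", paste("lmm fit failed:", conditionMessage(e)))
  )
  converged <- length(fit@optinfo$conv$lme4) == 0 && fit@optinfo$conv$opt == 0
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  varcomps <- setNames(vc$vcov[match(keep_factors, vc$grp)], keep_factors)
  fixed <- lme4::fixef(fit)
  fc <- as.matrix(stats::vcov(fit))
  dimnames(fc) <- list(names(fixed), names(fixed))
  keep <- if (include_intercept) names(fixed) else predictors
  es <- effect_set(frame_id(frame), fixed[keep], fc[keep, keep, drop = FALSE],
                   n, effect_names = keep, moderators = moderators)
  es$coefficients <- fixed
  es$lmm <- list(fixed = fixed, fixed_cov = fc, varcomps = varcomps,
                 sigma2 = sigma2, converged = converged,
                 boundary = any(varcomps < 1e-8 * sigma2),
                 reml_loglik = as.numeric(stats::logLik(fit)),
                 dropped_factors = dropped)
  if (!converged)
    sam_warn("convergence", sprintf("lmm for study %s did not fully converge", es$study_id))
  es
}
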