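# The "analyze" stage: fit a model to one study frame and return effect
# sizes with their known sampling covariance matrix.

frame_data <- function(frame) {
  if (inherits(frame, "sam_study_frame")) frame$data else as.data.frame(frame)
}

frame_id <- function(frame, default = "study") {
  if (inherits(frame, "sam_study_frame")) frame$study_id else default
}

design_matrix <- function(data, predictors) {
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  X
}

#' Per-study multiple regression
#'
#' Fits an ordinary least-squares regression inside one pseudo-study and
#' returns the slope estimates as a multivariate effect size with their
#' sampling covariance `sigma2 * (X'X)^-1`. The intercept is estimated but
#' excluded from the effect vector by default, since pooling normally
#' targets the slopes; set `include_intercept = TRUE` to pool it too.
#'
#' @param frame A `sam_study_frame` or data frame.
#' @param outcome Name of the outcome variable.
#' @param predictors Character vector of predictor names.
#' @param include_intercept Include the intercept in the effect vector?
#' @param moderators Named numeric vector of study-level moderators to
#'   carry on the resulting effect set.
#' @return An [effect_set()] with extra fields `coefficients` (all
#'   coefficients including intercept) and `sigma2` (residual variance,
#'   `RSS / (n - p - 1)`).
#' @export
fit_ols_study <- function(frame, outcome, predictors, include_intercept = FALSE,
                          moderators = numeric(0)) {
  data <- frame_data(frame)
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss))
    sam_abort("schema", paste("variables absent from frame:", paste(miss, collapse = ", ")))
  y <- as.numeric(data[[outcome]])
  X <- design_matrix(data, predictors)
  n <- length(y); pc <- ncol(X)
  if (n <= pc + 1)
    sam_abort("insufficient_data",
              sprintf("n = %d too small for %d coefficients", n, pc))
  fit <- stats::lm.fit(X, y)
  if (fit$rank < pc) {
    aliased <- colnames(X)[fit$qr$pivot[(fit$rank + 1L):pc]]
    sam_abort("singular_design",
              paste("design is rank deficient; collinear column(s):",
                    paste(aliased, collapse = ", ")))
  }
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - pc)
  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  V <- sigma2 * XtXinv
  keep <- if (include_intercept) colnames(X) else predictors
  es <- effect_set(frame_id(frame), fit$coefficients[keep],
                   V[keep, keep, drop = FALSE], n,
                   effect_names = keep, moderators = moderators)
  es$coefficients <- fit$coefficients[colnames(X)]
  es$sigma2 <- sigma2
  es
}

#' Per-study mediation analysis
#'
#' Estimates the simple mediation model `x -> m -> y` from two OLS
#' regressions (`m ~ x` giving the a-path; `y ~ m + x` giving the b-path
#' and the direct effect c') and returns the indirect effect `a*b` and
#' direct effect `c'` as a bivariate effect size. The sampling variance of
#' the indirect effect uses the first-order delta method,
#' `Var(ab) = b^2 Var(a) + a^2 Var(b)`, and
#' `Cov(ab, c') = a Cov(b, c')`; the covariance between the a-path and the
#' second regression is taken as zero (separate regressions, asymptotically
#' independent under the recursive model).
#'
#' @inheritParams fit_ols_study
#' @param x,m,y Names of the predictor, mediator, and outcome (distinct).
#' @return An [effect_set()] with effects `indirect` and `direct` and an
#'   extra field `mediation` holding the path coefficients.
#' @export
fit_mediation_study <- function(frame, x, m, y, moderators = numeric(0)) {
  if (anyDuplicated(c(x, m, y)))
    sam_abort("invalid_argument", "x, m and y must be distinct variables")
  data <- frame_data(frame)
  n <- nrow(data)
  if (n < 10) sam_abort("insufficient_data", "mediation fit needs n >= 10")
  for (v in c(x, m)) {
    if (stats::var(as.numeric(data[[v]])) == 0)
      sam_abort("degenerate_data", sprintf("variable '%s' has zero variance", v))
  }
  f1 <- fit_ols_study(data, outcome = m, predictors = x, include_intercept = TRUE)
  a <- unname(f1$y[x]); var_a <- f1$V[x, x]
  f2 <- fit_ols_study(data, outcome = y, predictors = c(m, x), include_intercept = TRUE)
  b <- unname(f2$y[m]); cprime <- unname(f2$y[x])
  var_b <- f2$V[m, m]; var_c <- f2$V[x, x]; cov_bc <- f2$V[m, x]
  indirect <- a * b
  V2 <- matrix(c(b^2 * var_a + a^2 * var_b, a * cov_bc,
                 a * cov_bc, var_c), 2, 2)
  es <- effect_set(frame_id(frame), c(indirect = indirect, direct = cprime),
                   V2, n, effect_names = c("indirect", "direct"),
                   moderators = moderators)
  es$mediation <- list(a_path = a, b_path = b, c_prime = cprime,
                       var_a = var_a, var_b = var_b)
  es
}

#' Per-study coefficient alpha
#'
#' Internal-consistency reliability of a multi-item scale,
#' `alpha = p/(p-1) * (1 - tr(S)/sum(S))` from the item covariance matrix,
#' with the large-sample sampling variance
#' `Var(alpha) = 2 p (1 - alpha)^2 / ((p - 1)(n - 2))`. With
#' `transform = "bonett"` the effect is `ln(1 - alpha)` with variance
#' `2 p / ((p - 1)(n - 2))`, for pooling on the transformed scale.
#'
#' @inheritParams fit_ols_study
#' @param items Character vector of at least two item names.
#' @param transform `"raw"` (default) or `"bonett"`.
#' @return An [effect_set()] with a single effect (`alpha` or
#'   `ln1m_alpha`) and extra fields `alpha`, `var_alpha`, `p_items`.
#' @export
estimate_alpha_study <- function(frame, items, transform = c("raw", "bonett"),
                                 moderators = numeric(0)) {
  transform <- match.arg(transform)
  data <- frame_data(frame)
  p <- length(items)
  if (p < 2) sam_abort("invalid_argument", "need at least two items")
  n <- nrow(data)
  if (n < p + 2) sam_abort("insufficient_data", "alpha needs n >= p_items + 2")
  S <- stats::cov(as.matrix(data[, items, drop = FALSE]))
  total <- sum(S)
  if (total <= 0) sam_abort("degenerate_data", "scale total has zero variance")
  alpha <- p / (p - 1) * (1 - sum(diag(S)) / total)
  var_alpha <- 2 * p * (1 - alpha)^2 / ((p - 1) * (n - 2))
  es <- if (transform == "raw") {
    effect_set(frame_id(frame), c(alpha = alpha), matrix(var_alpha), n,
               effect_names = "alpha", moderators = moderators)
  } else {
    if (alpha >= 1) sam_abort("degenerate_data", "alpha = 1: log transform undefined")
    effect_set(frame_id(frame), c(ln1m_alpha = log(1 - alpha)),
               matrix(2 * p / ((p - 1) * (n - 2))), n,
               effect_names = "ln1m_alpha", moderators = moderators)
  }
  es$alpha <- alpha
  es$var_alpha <- var_alpha
  es$p_items <- p
  es
}

# Normal-theory (Olkin-Siotani) asymptotic covariance of the q = p(p-1)/2
# sample correlations, in the package's fixed column-major lower-triangle
# order, each element scaled by 1/n.
cor_acov <- function(R, n) {
  pairs <- vech_pairs(nrow(R))
  q <- nrow(pairs)
  acov <- matrix(0, q, q)
  for (s in seq_len(q)) {
    for (t in s:q) {
      i <- pairs[s, 1]; j <- pairs[s, 2]
      k <- pairs[t, 1]; l <- pairs[t, 2]
      val <- 0.5 * R[i, j] * R[k, l] *
        (R[i, k]^2 + R[i, l]^2 + R[j, k]^2 + R[j, l]^2) +
        R[i, k] * R[j, l] + R[i, l] * R[j, k] -
        R[i, j] * (R[j, k] * R[j, l] + R[i, k] * R[i, l]) -
        R[k, l] * (R[j, k] * R[i, k] + R[j, l] * R[i, l])
      acov[s, t] <- acov[t, s] <- val / n
    }
  }
  acov
}

#' Per-study correlation matrix with asymptotic covariance
#'
#' Computes the Pearson correlation matrix of the named variables together
#' with the normal-theory (Olkin-Siotani) asymptotic covariance matrix of
#' its lower-triangle correlations, the effect-size input for two-stage
#' SEM. The vectorization order is column-major over the lower triangle
#' excluding the diagonal: (2,1), (3,1), ..., (p,1), (3,2), ...
#'
#' @inheritParams fit_ols_study
#' @param vars Character vector of at least two variable names.
#' @return A `sam_corr_study` with fields `study_id`, `R`, `n`, `acov`,
#'   `vars`.
#' @export
correlation_study <- function(frame, vars, moderators = numeric(0)) {
  data <- frame_data(frame)
  p <- length(vars)
  if (p < 2) sam_abort("invalid_argument", "need at least two variables to correlate")
  n <- nrow(data)
  if (n < p + 2) sam_abort("insufficient_data", "correlation study needs n >= p + 2")
  M <- as.matrix(data[, vars, drop = FALSE])
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    sam_abort("degenerate_data",
              paste("constant column(s):", paste(vars[sds == 0], collapse = ", ")))
  R <- stats::cor(M)
  structure(list(study_id = frame_id(frame), R = R, n = n,
                 acov = cor_acov(R, n), vars = vars, moderators = moderators),
            class = "sam_corr_study")
}

#' @export
print.sam_corr_study <- function(x, ...) {
  cat("<sam_corr_study>", x$study_id, " n =", x$n, "\n")
  print(round(x$R, 3))
  invisible(x)
}

# Correlation study as a generic effect set (vectorized lower triangle with
# its acov as known V), the form consumed by the meta engine in stage 1.
corr_study_to_effect_set <- function(cs) {
  pairs <- vech_pairs(length(cs$vars))
  nm <- paste0("r_", cs$vars[pairs[, 1]], "_", cs$vars[pairs[, 2]])
  effect_set(cs$study_id, vech_offdiag(cs$R), cs$acov, cs$n,
             effect_names = nm, moderators = cs$moderators)
}
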