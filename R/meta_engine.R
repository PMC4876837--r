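# The "meta-analyze" stage: pool effect sets under multivariate fixed-,
# random-, or mixed-effects models with known per-study sampling
# covariances, quantify heterogeneity (I^2) and moderation (R^2), and
# summarize bivariate effects with confidence ellipses.

#' Specify a meta-analytic model
#'
#' @param model `"fixed"`, `"random"`, or `"mixed"`.
#' @param moderators Character vector of moderator names (mixed model
#'   only); each effect set must carry them.
#' @param tau2_structure Between-study covariance structure: `"full"`
#'   (unstructured, Cholesky-parameterized), `"diagonal"`, or `"zero"`.
#' @param estimator `"REML"` (default) or `"ML"`.
#' @param tol Convergence tolerance on the (restricted) deviance.
#' @param max_iter Maximum optimizer iterations.
#' @param center Mean-center moderators? (Affects only the meaning of the
#'   intercepts.)
#' @return A `sam_meta_spec` object.
#' @export
meta_model_spec <- function(model = c("random", "fixed", "mixed"),
                            moderators = character(0),
                            tau2_structure = c("full", "diagonal", "zero"),
                            estimator = c("REML", "ML"),
                            tol = 1e-8, max_iter = 500L, center = TRUE) {
  model <- match.arg(model)
  tau2_structure <- match.arg(tau2_structure)
  estimator <- match.arg(estimator)
  if (model == "mixed" && !length(moderators))
    sam_abort("invalid_argument", "mixed model needs at least one moderator")
  if (model == "fixed") tau2_structure <- "zero"
  structure(list(model = model, moderators = as.character(moderators),
                 tau2_structure = tau2_structure, estimator = estimator,
                 tol = tol, max_iter = as.integer(max_iter), center = isTRUE(center)),
            class = "sam_meta_spec")
}

# ---- T^2 parameterization -------------------------------------------------

n_theta <- function(p, structure) {
  switch(structure, zero = 0L, diagonal = p, full = (p * (p + 1L)) %/% 2L)
}

# theta -> T^2. Full: lower-triangular Cholesky factor with exponentiated
# diagonal (first p entries are log-sds, the rest the below-diagonal
# entries column-major). Diagonal: p log-sds.
theta_to_tau2 <- function(theta, p, structure) {
  if (structure == "zero") return(matrix(0, p, p))
  if (structure == "diagonal") return(diag(exp(2 * theta), p))
  L <- diag(exp(theta[seq_len(p)]), p)
  if (p > 1) L[lower.tri(L)] <- theta[-seq_len(p)]
  L %*% t(L)
}

theta_start <- function(effects, p, structure) {
  if (structure == "zero") return(numeric(0))
  Y <- do.call(rbind, lapply(effects, `[[`, "y"))
  v <- pmax(0.1 * apply(Y, 2, stats::var), 1e-8)
  if (structure == "diagonal") return(0.5 * log(v))
  c(0.5 * log(v), rep(0, (p * (p - 1L)) %/% 2L))
}

theta_bounds <- function(p, structure) {
  if (structure == "zero") return(list(lower = numeric(0), upper = numeric(0)))
  nt <- n_theta(p, structure)
  lower <- rep(-Inf, nt); upper <- rep(Inf, nt)
  lower[seq_len(p)] <- -20  # sd >= ~2e-9: effectively tau^2 = 0
  upper[seq_len(p)] <- 20
  list(lower = lower, upper = upper)
}

# ---- likelihood core ------------------------------------------------------

# Design matrix for one study: identity (one intercept per effect) for the
# random model, kron(I_p, c(1, x_i)) for the mixed model. gamma ordering is
# effect-major: (intercept_1, slopes_1..., intercept_2, ...).
build_design <- function(p, xi = NULL) {
  if (is.null(xi)) diag(p) else kronecker(diag(p), matrix(c(1, xi), nrow = 1))
}

# Profiled -2 log-(restricted-)likelihood and GLS solution at a given T^2.
# Returns Inf for T^2 making some Sigma_i non-PD.
gls_at_tau2 <- function(tau2, ylist, Vlist, Xlist, restricted = TRUE) {
  q <- ncol(Xlist[[1]])
  S <- matrix(0, q, q); b <- numeric(q)
  logdet <- 0; yWy <- 0; N <- 0
  for (i in seq_along(ylist)) {
    Sig <- Vlist[[i]] + tau2
    R <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    logdet <- logdet + 2 * sum(log(diag(R)))
    Xi <- Xlist[[i]]; yi <- ylist[[i]]
    Z <- backsolve(R, cbind(Xi, yi), transpose = TRUE)
    WX <- Z[, seq_len(q), drop = FALSE]; wy <- Z[, q + 1L]
    S <- S + crossprod(WX)
    b <- b + crossprod(WX, wy)[, 1]
    yWy <- yWy + sum(wy^2)
    N <- N + length(yi)
  }
  RS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(RS)) return(NULL)
  gamma <- backsolve(RS, backsolve(RS, b, transpose = TRUE))
  quad <- yWy - sum(gamma * b)
  neg2ll <- if (restricted) {
    (N - q) * log(2 * pi) + logdet + 2 * sum(log(diag(RS))) + quad
  } else {
    N * log(2 * pi) + logdet + quad
  }
  list(neg2ll = neg2ll, gamma = gamma, cov_gamma = chol2inv(RS), S = S, N = N)
}

fit_meta_core <- function(effects, spec, Xlist, gamma_names) {
  nm <- check_effects_conformable(effects)
  p <- length(nm)
  ylist <- lapply(effects, `[[`, "y")
  Vlist <- lapply(effects, `[[`, "V")
  restricted <- spec$estimator == "REML"
  k <- length(effects)
  total_n <- sum(vapply(effects, `[[`, integer(1), "n"))

  if (spec$tau2_structure != "zero" && k < 2)
    sam_abort("insufficient_studies",
              "between-study variance estimation needs at least 2 studies")

  obj <- function(theta) {
    tau2 <- theta_to_tau2(theta, p, spec$tau2_structure)
    res <- gls_at_tau2(tau2, ylist, Vlist, Xlist, restricted)
    if (is.null(res)) return(1e10)
    res$neg2ll
  }

  converged <- TRUE
  iterations <- 0L
  if (spec$tau2_structure == "zero") {
    # Known covariances: GLS in closed form. A singular V_i is an error
    # here (nothing to regularize it).
    for (i in seq_along(Vlist)) {
      ok <- tryCatch({ chol(Vlist[[i]]); TRUE }, error = function(e) FALSE)
      if (!ok)
        sam_abort("conditioning",
                  sprintf("sampling covariance of study %s is singular",
                          effects[[i]]$study_id))
    }
    theta_hat <- numeric(0)
  } else {
    start <- theta_start(effects, p, spec$tau2_structure)
    bd <- theta_bounds(p, spec$tau2_structure)
    opt <- stats::nlminb(start, obj, lower = bd$lower, upper = bd$upper,
                         control = list(iter.max = spec$max_iter,
                                        eval.max = 10L * spec$max_iter,
                                        rel.tol = min(spec$tol * 1e-2, 1e-10)))
    theta_hat <- opt$par
    iterations <- opt$iterations
    msg <- opt$message %||% ""
    if (opt$convergence != 0 &&
        !grepl("relative convergence|X-convergence|both X|singular convergence", msg)) {
      if (grepl("false convergence", msg)) {
        converged <- FALSE
        sam_warn("convergence", sprintf("optimizer reported: %s", msg))
      } else {
        sam_abort("convergence",
                  sprintf("meta model did not converge after %d iterations (%s)",
                          opt$iterations, msg), last_theta = theta_hat)
      }
    }
  }
  tau2 <- theta_to_tau2(theta_hat, p, spec$tau2_structure)
  dimnames(tau2) <- list(nm, nm)
  res <- gls_at_tau2(tau2, ylist, Vlist, Xlist, restricted)
  if (is.null(res)) sam_abort("convergence", "likelihood undefined at the optimum")
  gamma <- setNames(res$gamma, gamma_names)
  cov_gamma <- res$cov_gamma
  dimnames(cov_gamma) <- list(gamma_names, gamma_names)
  # zero-boundary detection relative to the typical sampling variance
  vbar <- colMeans(do.call(rbind, lapply(Vlist, diag)))
  boundary <- spec$tau2_structure != "zero" && any(diag(tau2) < 1e-6 * vbar)
  structure(
    list(gamma = gamma, cov_gamma = cov_gamma, se = sqrt(diag(cov_gamma)),
         tau2 = tau2, loglik = -0.5 * res$neg2ll, estimator = spec$estimator,
         tau2_structure = spec$tau2_structure, converged = converged,
         boundary = boundary, iterations = iterations, k = k,
         total_n = total_n, effect_names = nm, i2 = NULL, r2 = NULL,
         moderators = spec$moderators, moderator_means = NULL, model = spec$model),
    class = "sam_meta_fit")
}

# ---- user-facing pooling --------------------------------------------------

#' Fixed-effects multivariate pooling
#'
#' Inverse-variance-weighted (GLS) pooling assuming a single common
#' population effect vector: `gamma = (sum V_i^-1)^-1 sum V_i^-1 y_i`,
#' `cov(gamma) = (sum V_i^-1)^-1`. Appropriate after a random split, where
#' all between-study differences are sampling error.
#'
#' @param effects List of [effect_set()] objects sharing effect names.
#' @return A `sam_meta_fit` with `tau2 = 0`.
#' @export
meta_fixed <- function(effects) {
  nm <- check_effects_conformable(effects)
  spec <- meta_model_spec(model = "fixed")
  fit_meta_core(effects, spec, lapply(effects, function(e) diag(length(nm))), nm)
}

#' Random-effects multivariate pooling
#'
#' Fits the marginal model `y_i ~ Normal(gamma, V_i + T^2)` with the
#' between-study covariance `T^2` estimated by REML (default) or ML on a
#' Cholesky (full) or log-sd (diagonal) parameterization, then solves for
#' `gamma` by GLS at the estimate. Appropriate after a stratified split,
#' where strata have their own population parameters. Per-effect I^2 is
#' filled using the Higgins-Thompson typical sampling variance.
#'
#' @inheritParams meta_fixed
#' @param spec A [meta_model_spec()]; the default fits a full-`T^2` REML
#'   random-effects model.
#' @return A `sam_meta_fit`; `boundary = TRUE` flags a `T^2` estimate on
#'   the zero boundary.
#' @export
meta_random <- function(effects, spec = meta_model_spec("random")) {
  nm <- check_effects_conformable(effects)
  spec$model <- if (spec$tau2_structure == "zero") spec$model else "random"
  fit <- fit_meta_core(effects, spec, lapply(effects, function(e) diag(length(nm))), nm)
  fit$model <- "random"
  fit$i2 <- i_squared(fit, effects)
  fit
}

#' Mixed-effects multivariate meta-regression
#'
#' Random-effects pooling with study-level moderators predicting each
#' effect: `y_ji = gamma_j0 + gamma_j1 x_i + ... + u_ji + e_ji`.
#' Moderators are mean-centered by default (set `center = FALSE` in the
#' spec for the raw scale; this changes only the intercept meaning). When
#' a baseline random-effects fit on the same effects is supplied (or
#' computable), per-effect R^2 — the proportional reduction in the
#' heterogeneity variance — is filled in.
#'
#' @inheritParams meta_fixed
#' @param moderators Character vector of moderator names; every effect set
#'   must carry them.
#' @param spec A [meta_model_spec()] (model forced to `"mixed"`).
#' @param baseline Optional `sam_meta_fit` from [meta_random()] on the same
#'   effects, for R^2; fitted automatically when `NULL`.
#' @return A `sam_meta_fit` with moderator slopes in `gamma` and `r2`
#'   filled per effect.
#' @export
meta_mixed <- function(effects, moderators,
                       spec = meta_model_spec("mixed", moderators = moderators),
                       baseline = NULL) {
  nm <- check_effects_conformable(effects)
  p <- length(nm)
  spec$model <- "mixed"
  spec$moderators <- moderators
  M <- vapply(effects, function(e) {
    if (!all(moderators %in% names(e$moderators)))
      sam_abort("schema", sprintf("study %s is missing moderator(s): %s", e$study_id,
                                  paste(setdiff(moderators, names(e$moderators)),
                                        collapse = ", ")))
    as.numeric(e$moderators[moderators])
  }, numeric(length(moderators)))
  M <- matrix(M, nrow = length(moderators))
  for (j in seq_along(moderators)) {
    if (stats::var(M[j, ]) == 0)
      sam_abort("degenerate_moderator",
                sprintf("moderator '%s' is constant across studies", moderators[j]))
  }
  mod_means <- rowMeans(M)
  if (spec$center) M <- M - mod_means
  Xlist <- lapply(seq_along(effects), function(i) build_design(p, M[, i]))
  gamma_names <- as.vector(vapply(nm, function(e) c(paste0(e, ":intrcpt"),
                                                    paste0(e, ":", moderators)),
                                  character(1 + length(moderators))))
  fit <- fit_meta_core(effects, spec, Xlist, gamma_names)
  fit$moderator_means <- setNames(mod_means, moderators)
  if (is.null(baseline)) {
    base_spec <- spec
    base_spec$model <- "random"; base_spec$moderators <- character(0)
    baseline <- meta_random(effects, base_spec)
  }
  fit$r2 <- r_squared(baseline, fit)
  fit$baseline_tau2 <- baseline$tau2
  fit
}

# ---- heterogeneity & moderation statistics --------------------------------

#' Per-effect I-squared
#'
#' Proportion of total variance attributable to between-study
#' heterogeneity, `I2_j = tau2_jj / (tau2_jj + Vbar_jj)`, where `Vbar_jj`
#' is the typical within-study sampling variance. The default is the
#' Higgins-Thompson Q-based value
#' `(k - 1) sum(w) / ((sum w)^2 - sum(w^2))` with `w = 1 / V_i,jj`; the
#' harmonic mean `k / sum(w)` is available as an alternative.
#'
#' @param fit A `sam_meta_fit` from [meta_random()].
#' @param effects The effect sets the fit was computed from.
#' @param typical `"higgins"` (default) or `"harmonic"`.
#' @return Named numeric vector of per-effect I^2 values in \[0, 1\].
#' @export
i_squared <- function(fit, effects, typical = c("higgins", "harmonic")) {
  typical <- match.arg(typical)
  nm <- fit$effect_names
  k <- length(effects)
  vapply(seq_along(nm), function(j) {
    w <- vapply(effects, function(e) 1 / e$V[j, j], numeric(1))
    vbar <- if (typical == "higgins") {
      (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
    } else k / sum(w)
    t2 <- fit$tau2[j, j]
    if (t2 <= 0) 0 else t2 / (t2 + vbar)
  }, numeric(1)) -> i2
  setNames(pmin(pmax(i2, 0), 1), nm)
}

#' Per-effect R-squared of a moderator
#'
#' Proportional reduction of the between-study heterogeneity variance when
#' moderators are added: `R2_j = max(0, 1 - tau2_jj(moderated) /
#' tau2_jj(baseline))`, reported as 0 when the baseline heterogeneity is
#' already 0.
#'
#' @param baseline `sam_meta_fit` without moderators.
#' @param moderated `sam_meta_fit` with moderators, same effects and
#'   `tau2_structure`.
#' @return Named numeric vector of per-effect R^2 values in \[0, 1\].
#' @export
r_squared <- function(baseline, moderated) {
  if (!identical(baseline$effect_names, moderated$effect_names))
    sam_abort("schema", "fits have different effect names")
  if (!identical(baseline$tau2_structure, moderated$tau2_structure))
    sam_abort("schema", "fits have different tau2 structures")
  nm <- baseline$effect_names
  r2 <- vapply(seq_along(nm), function(j) {
    t0 <- baseline$tau2[j, j]; t1 <- moderated$tau2[j, j]
    if (t0 <= 0) 0 else max(0, min(1, 1 - t1 / t0))
  }, numeric(1))
  setNames(r2, nm)
}

# ---- confidence ellipse ---------------------------------------------------

#' Confidence ellipse for a pair of pooled effects
#'
#' Describes the bivariate normal region containing `level` of the
#' distribution of true study effects for two effect dimensions: centered
#' at the pooled estimates with shape given by the corresponding `T^2`
#' sub-matrix. With `include_gamma_cov = TRUE` the sampling covariance of
#' the pooled estimates is added to the shape (a predictive region for the
#' pooled effect rather than the spread of true effects).
#'
#' @param fit A `sam_meta_fit` from [meta_random()] or [meta_mixed()].
#' @param pair Two effect indices or names.
#' @param level Coverage level in (0, 1).
#' @param include_gamma_cov Add `cov(gamma)` to the shape?
#' @return A `sam_ellipse`: `center`, `shape`, `level`, and `boundary(theta)`
#'   returning the boundary point at angle `theta` (satisfying
#'   `(x - center)' shape^-1 (x - center) = qchisq(level, 2)`).
#' @export
confidence_ellipse <- function(fit, pair = c(1, 2), level = 0.95,
                               include_gamma_cov = FALSE) {
  if (!fit$model %in% c("random", "mixed"))
    sam_abort("invalid_argument", "ellipse needs a random- or mixed-effects fit")
  if (is.character(pair)) pair <- match(pair, fit$effect_names)
  if (length(pair) != 2 || anyNA(pair))
    sam_abort("invalid_argument", "`pair` must select two effects")
  nm <- fit$effect_names[pair]
  # centre on the per-effect intercepts (for a mixed fit, gamma also holds
  # moderator slopes)
  cn <- if (fit$model == "mixed") paste0(nm, ":intrcpt") else nm
  center <- setNames(as.numeric(fit$gamma[cn]), nm)
  shape <- fit$tau2[pair, pair]
  if (include_gamma_cov) shape <- shape + fit$cov_gamma[cn, cn]
  ok <- tryCatch({ chol(shape); TRUE }, error = function(e) FALSE)
  if (!ok || det(shape) <= 0)
    sam_abort("degenerate_ellipse",
              "T^2 sub-matrix is singular; report a point or interval summary instead")
  A <- t(chol(shape))
  r <- sqrt(stats::qchisq(level, df = 2))
  boundary <- function(theta) {
    pts <- center + r * (A %*% rbind(cos(theta), sin(theta)))
    t(pts)
  }
  structure(list(center = center, shape = shape, level = level,
                 boundary = boundary),
            class = "sam_ellipse")
}

#' Sample the boundary of an ellipse
#'
#' @param ellipse A `sam_ellipse` from [confidence_ellipse()].
#' @param n Number of boundary points.
#' @return Data frame of `n` boundary points (two columns named after the
#'   effects), suitable for CSV export and plotting.
#' @export
ellipse_points <- function(ellipse, n = 180L) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  pts <- ellipse$boundary(theta)
  df <- as.data.frame(pts)
  names(df) <- names(ellipse$center)
  df
}

#' @export
print.sam_meta_fit <- function(x, ...) {
  cat(sprintf("<sam_meta_fit> %s-effects model (%s, tau2 %s), k = %d, total n = %d\n",
              x$model, x$estimator, x$tau2_structure, x$k, x$total_n))
  z <- x$gamma / x$se
  tab <- cbind(estimate = x$gamma, se = x$se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  print(round(tab, 4))
  if (!is.null(x$i2)) { cat("I^2:\n"); print(round(x$i2, 4)) }
  if (!is.null(x$r2)) { cat("R^2:\n"); print(round(x$r2, 4)) }
  if (x$tau2_structure != "zero") { cat("T^2:\n"); print(round(x$tau2, 5)) }
  if (x$boundary) cat("note: T^2 estimate on the zero boundary\n")
  invisible(x)
}
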