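# Generators for strata-labelled raw data with known population structure,
# so every pipeline stage is testable without external data. Each
# generator is seed-deterministic and returns a machine-readable truth
# record alongside the data; recovery tests read the truth record, never
# the code paths under test.

new_simulation <- function(data, truth) {
  structure(list(data = data, truth = truth), class = "sam_simulation")
}

#' @export
print.sam_simulation <- function(x, ...) {
  cat("<sam_simulation>", nrow(x$data), "rows x", ncol(x$data), "cols;",
      "truth fields:", paste(names(x$truth), collapse = ", "), "\n")
  invisible(x)
}

draw_n_per_stratum <- function(n_per_stratum, k) {
  if (length(n_per_stratum) == 1) return(rep(as.integer(n_per_stratum), k))
  if (length(n_per_stratum) == 2)
    return(sample(seq(n_per_stratum[1], n_per_stratum[2]), k, replace = TRUE))
  sam_abort("invalid_argument", "n_per_stratum must be a scalar or a range")
}

#' Specify a regression simulation
#'
#' Generating parameters for strata-labelled regression data: per stratum
#' `i` the coefficient vector is drawn as
#' `beta_i ~ Normal(gamma_true + moderator_slopes * x_i, tau2_true)` where
#' `x_i ~ Normal(0, 1)` is a stratum-level moderator, and rows follow
#' `y = beta0 + X beta_i + Normal(0, sigma^2)`.
#'
#' @param k Number of strata.
#' @param n_per_stratum Rows per stratum: a constant or a `c(min, max)`
#'   range sampled uniformly.
#' @param gamma_true Population-mean slope vector (one per predictor).
#' @param tau2_true Between-stratum covariance of the slopes (PSD matrix,
#'   or a scalar/vector for a diagonal).
#' @param moderator_slopes Optional per-slope effect of the stratum-level
#'   moderator; `NULL` for no moderator structure.
#' @param beta0 Common intercept.
#' @param predictor_cor Compound-symmetric correlation among predictors
#'   (default 0; a nonzero value exercises the off-diagonals of V_i).
#' @param sigma Residual standard deviation.
#' @param seed Integer seed (mandatory).
#' @return A `sam_sim_spec`.
#' @export
meta_sim_spec <- function(k, n_per_stratum, gamma_true, tau2_true,
                          moderator_slopes = NULL, beta0 = 0,
                          predictor_cor = 0, sigma = 1, seed) {
  p <- length(gamma_true)
  if (is.null(dim(tau2_true))) {
    tau2_true <- diag(rep(tau2_true, length.out = p), p)
  }
  check_symmetric_psd(tau2_true, "tau2_true")
  if (!is.null(moderator_slopes) && length(moderator_slopes) != p)
    sam_abort("invalid_argument", "moderator_slopes must match gamma_true in length")
  if (abs(predictor_cor) >= 1)
    sam_abort("invalid_argument", "predictor_cor must be in (-1, 1)")
  seed <- stopifnot_scalar_int(seed, "seed")
  structure(list(k = as.integer(k), n_per_stratum = n_per_stratum,
                 gamma_true = gamma_true, tau2_true = tau2_true,
                 moderator_slopes = moderator_slopes, beta0 = beta0,
                 predictor_cor = predictor_cor, sigma = sigma, seed = seed,
                 p = p),
            class = "sam_sim_spec")
}

#' Simulate strata-labelled regression data
#'
#' @param spec A [meta_sim_spec()].
#' @return A `sam_simulation`: `data` with columns `stratum`, `moderator`,
#'   `x1..xp`, `y`; `truth` records the spec, the per-stratum coefficient
#'   draws, and the moderator values.
#' @export
simulate_regression_dataset <- function(spec) {
  if (!inherits(spec, "sam_sim_spec")) sam_abort("invalid_argument", "need a sam_sim_spec")
  p <- spec$p
  with_seed(spec$seed, {
    ns <- draw_n_per_stratum(spec$n_per_stratum, spec$k)
    x_mod <- stats::rnorm(spec$k)
    U <- MASS::mvrnorm(spec$k, mu = rep(0, p), Sigma = spec$tau2_true)
    U <- matrix(U, nrow = spec$k)
    beta <- matrix(rep(spec$gamma_true, each = spec$k), spec$k, p) + U
    if (!is.null(spec$moderator_slopes))
      beta <- beta + outer(x_mod, spec$moderator_slopes)
    Rx <- matrix(spec$predictor_cor, p, p); diag(Rx) <- 1
    Lx <- chol(Rx)
    blocks <- vector("list", spec$k)
    for (i in seq_len(spec$k)) {
      X <- matrix(stats::rnorm(ns[i] * p), ns[i], p) %*% Lx
      y <- spec$beta0 + as.numeric(X %*% beta[i, ]) +
        stats::rnorm(ns[i], sd = spec$sigma)
      blocks[[i]] <- data.frame(stratum = sprintf("s%04d", i),
                                moderator = x_mod[i], X, y = y)
    }
    data <- do.call(rbind, blocks)
    names(data)[2 + seq_len(p)] <- paste0("x", seq_len(p))
    rownames(data) <- NULL
    truth <- list(generator = "regression", k = spec$k, n_per_stratum = ns,
                  gamma_true = spec$gamma_true,
                  tau2_true = spec$tau2_true,
                  moderator_slopes = spec$moderator_slopes,
                  beta0 = spec$beta0, predictor_cor = spec$predictor_cor,
                  sigma = spec$sigma, seed = spec$seed,
                  beta_by_stratum = beta, moderator = x_mod)
    new_simulation(data, truth)
  })
}

#' Simulate strata-labelled one-factor (or clustered-factor) item data
#'
#' Per stratum the loadings are perturbed around the population values,
#' clipped into (0.02, 0.98) with a warning if the heterogeneity pushes
#' them outside, and multivariate-normal rows are drawn from
#' `Sigma_i = Lambda_i Lambda_i' + diag(1 - lambda_i^2)`.
#'
#' @param k Number of strata.
#' @param n Rows per stratum (constant or range).
#' @param loadings Population loadings in (0, 1), length >= 2.
#' @param loading_heterogeneity_sd Between-stratum SD of each loading.
#' @param seed Integer seed.
#' @return A `sam_simulation`: item columns `v1..vp` plus `stratum`.
#' @export
simulate_factor_dataset <- function(k, n, loadings, loading_heterogeneity_sd = 0,
                                    seed) {
  p <- length(loadings)
  if (p < 2) sam_abort("invalid_argument", "need at least 2 items (p = 1 has no correlations to pool)")
  if (any(loadings <= 0 | loadings >= 1))
    sam_abort("invalid_argument", "loadings must lie in (0, 1)")
  if (loading_heterogeneity_sd < 0)
    sam_abort("invalid_argument", "loading_heterogeneity_sd must be >= 0")
  seed <- stopifnot_scalar_int(seed, "seed")
  with_seed(seed, {
    ns <- draw_n_per_stratum(n, k)
    lam <- matrix(rep(loadings, each = k), k, p) +
      matrix(stats::rnorm(k * p, sd = loading_heterogeneity_sd), k, p)
    if (any(lam <= 0.02 | lam >= 0.98)) {
      sam_warn("clipped_loadings", "perturbed loadings clipped into (0.02, 0.98)")
      lam <- pmin(pmax(lam, 0.02), 0.98)
    }
    blocks <- vector("list", k)
    for (i in seq_len(k)) {
      Sig <- tcrossprod(lam[i, ]) + diag(1 - lam[i, ]^2, p)
      M <- MASS::mvrnorm(ns[i], mu = rep(0, p), Sigma = Sig)
      blocks[[i]] <- data.frame(stratum = sprintf("s%04d", i), M)
    }
    data <- do.call(rbind, blocks)
    names(data)[1 + seq_len(p)] <- paste0("v", seq_len(p))
    rownames(data) <- NULL
    truth <- list(generator = "factor", k = k, n_per_stratum = ns,
                  loadings = loadings,
                  loading_heterogeneity_sd = loading_heterogeneity_sd,
                  loadings_by_stratum = lam, seed = seed)
    new_simulation(data, truth)
  })
}

#' Simulate strata-labelled mediation data
#'
#' Per stratum the path coefficients `(a_i, b_i, c'_i)` are drawn around
#' the population values with the given heterogeneity SDs, then rows
#' follow the recursive chain `x ~ N(0,1)`, `m = a_i x + e1`,
#' `y = b_i m + c'_i x + e2` with unit normal errors.
#'
#' @param k Number of strata.
#' @param n Rows per stratum (constant or range).
#' @param a,b,c_prime Population path coefficients.
#' @param heterogeneity Named numeric vector of between-stratum SDs, any of
#'   `a`, `b`, `c_prime` (missing entries default to 0).
#' @param seed Integer seed.
#' @return A `sam_simulation` with columns `stratum`, `x`, `m`, `y`.
#' @export
simulate_mediation_dataset <- function(k, n, a, b, c_prime,
                                       heterogeneity = c(a = 0, b = 0, c_prime = 0),
                                       seed) {
  het <- c(a = 0, b = 0, c_prime = 0)
  het[names(heterogeneity)] <- heterogeneity
  if (any(het < 0)) sam_abort("invalid_argument", "heterogeneity SDs must be >= 0")
  seed <- stopifnot_scalar_int(seed, "seed")
  with_seed(seed, {
    ns <- draw_n_per_stratum(n, k)
    ai <- a + stats::rnorm(k, sd = het["a"])
    bi <- b + stats::rnorm(k, sd = het["b"])
    ci <- c_prime + stats::rnorm(k, sd = het["c_prime"])
    blocks <- vector("list", k)
    for (i in seq_len(k)) {
      x <- stats::rnorm(ns[i])
      m <- ai[i] * x + stats::rnorm(ns[i])
      y <- bi[i] * m + ci[i] * x + stats::rnorm(ns[i])
      blocks[[i]] <- data.frame(stratum = sprintf("s%04d", i), x = x, m = m, y = y)
    }
    data <- do.call(rbind, blocks)
    rownames(data) <- NULL
    truth <- list(generator = "mediation", k = k, n_per_stratum = ns,
                  a = a, b = b, c_prime = c_prime,
                  indirect = a * b, heterogeneity = as.list(het),
                  a_by_stratum = ai, b_by_stratum = bi, c_by_stratum = ci,
                  seed = seed)
    new_simulation(data, truth)
  })
}

#' Simulate data with crossed random-intercept structure
#'
#' Rows carry standard-normal predictors, uniformly assigned levels of
#' each crossed grouping factor, and outcome
#' `y = beta0 + X beta + sum_f u_f[level] + e`, with
#' `u_f ~ N(0, varcomps[f])` and `e ~ N(0, sigma2)`.
#'
#' @param n Total rows.
#' @param fixed_beta Named slope vector (predictors `x1..xp`).
#' @param factor_levels Named integer vector: number of levels per crossed
#'   factor (a factor with 1 level is legal here; the model fit drops it
#'   with a warning).
#' @param varcomps Named variance components, same names as
#'   `factor_levels`.
#' @param sigma2 Residual variance.
#' @param beta0 Intercept.
#' @param seed Integer seed.
#' @return A `sam_simulation` with predictors, factor columns, and `y`.
#' @export
simulate_crossed_dataset <- function(n, fixed_beta, factor_levels, varcomps,
                                     sigma2 = 1, beta0 = 0, seed) {
  if (!identical(sort(names(factor_levels)), sort(names(varcomps))))
    sam_abort("invalid_argument", "factor_levels and varcomps must share names")
  if (any(varcomps < 0)) sam_abort("invalid_argument", "varcomps must be >= 0")
  seed <- stopifnot_scalar_int(seed, "seed")
  p <- length(fixed_beta)
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    y <- beta0 + as.numeric(X %*% fixed_beta)
    fac <- list()
    u_record <- list()
    for (f in names(factor_levels)) {
      L <- as.integer(factor_levels[[f]])
      lev <- sample.int(L, n, replace = TRUE)
      u <- stats::rnorm(L, sd = sqrt(varcomps[[f]]))
      y <- y + u[lev]
      fac[[f]] <- sprintf("%s%03d", f, lev)
      u_record[[f]] <- u
    }
    y <- y + stats::rnorm(n, sd = sqrt(sigma2))
    data <- data.frame(X, fac, y = y)
    names(data)[seq_len(p)] <- paste0("x", seq_len(p))
    rownames(data) <- NULL
    truth <- list(generator = "crossed", n = n, fixed_beta = fixed_beta,
                  beta0 = beta0, factor_levels = as.list(factor_levels),
                  varcomps = as.list(varcomps), sigma2 = sigma2,
                  u_by_factor = u_record, seed = seed)
    new_simulation(data, truth)
  })
}

#' Write a simulation to disk
#'
#' Emits the raw table as RFC-4180 CSV in exactly the schema the reader
#' consumes, the truth record as JSON next to it, and optionally the same
#' table into a SQLite database.
#'
#' @param sim A `sam_simulation`.
#' @param csv_path Output CSV path.
#' @param truth_path Output JSON path; default replaces the CSV extension
#'   with `_truth.json`.
#' @param sqlite_path Optional SQLite database path.
#' @param table Table name for the SQLite copy.
#' @return Invisibly, the CSV path.
#' @export
write_simulation <- function(sim, csv_path,
                             truth_path = sub("\\.csv$", "_truth.json", csv_path),
                             sqlite_path = NULL, table = "data") {
  if (!inherits(sim, "sam_simulation")) sam_abort("invalid_argument", "need a sam_simulation")
  utils::write.csv(sim$data, csv_path, row.names = FALSE)
  truth <- sim$truth
  truth <- lapply(truth, function(x) if (is.matrix(x)) apply(x, 1, identity, simplify = FALSE) else x)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(sqlite_path)) {
    con <- DBI::dbConnect(RSQLite::SQLite(), sqlite_path)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    DBI::dbWriteTable(con, table, sim$data, overwrite = TRUE)
  }
  invisible(csv_path)
}
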