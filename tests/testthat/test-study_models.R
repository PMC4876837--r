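test_that("ols study recovers a noiseless line with zero residual variance", {
  x <- seq_len(50)
  es <- fit_ols_study(data.frame(x = x, y = 2 * x), "y", "x")
  expect_equal(unname(es$y["x"]), 2, tolerance = 1e-12)
  expect_equal(es$sigma2, 0, tolerance = 1e-20)
})

test_that("orthogonal predictors give a diagonal sampling covariance", {
  X <- make_exact_cov_data(200, diag(2), seed = 3)  # exactly uncorrelated, unit variance
  withr::with_seed(4, {
    y <- 0.5 * X$v1 - 0.25 * X$v2 + rnorm(200)
  })
  es <- fit_ols_study(cbind(X, y = y), "y", c("v1", "v2"))
  expect_lt(abs(es$V[1, 2]), 1e-12)
})

test_that("ols matches an independently coded normal-equations solver", {
  withr::with_seed(11, {
    n <- 200
    X <- matrix(rnorm(n * 3), n, 3)
    beta <- c(1, -2, 0.5)
    y <- 2 + X %*% beta + rnorm(n)
  })
  df <- data.frame(X, y = as.numeric(y))
  names(df)[1:3] <- c("a", "b", "c")
  es <- fit_ols_study(df, "y", c("a", "b", "c"), include_intercept = TRUE)
  # oracle: brute-force normal equations
  Xd <- cbind(1, X)
  bh <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  s2 <- sum((y - Xd %*% bh)^2) / (n - 4)
  Vh <- s2 * solve(t(Xd) %*% Xd)
  expect_equal(unname(es$y), as.numeric(bh), tolerance = 1e-10)
  expect_equal(unname(es$V), unname(Vh), tolerance = 1e-10)
})

test_that("rescaling a predictor rescales its slope and SE exactly", {
  withr::with_seed(12, {
    df <- data.frame(x1 = rnorm(300), x2 = rnorm(300))
    df$y <- 1 + 0.3 * df$x1 - 0.1 * df$x2 + rnorm(300)
  })
  es1 <- fit_ols_study(df, "y", c("x1", "x2"))
  df2 <- df
  df2$x2 <- df2$x2 * 1000
  es2 <- fit_ols_study(df2, "y", c("x1", "x2"))
  expect_equal(unname(es2$y["x2"] * 1000), unname(es1$y["x2"]), tolerance = 1e-12)
  expect_equal(sqrt(es2$V["x2", "x2"]) * 1000, sqrt(es1$V["x2", "x2"]),
               tolerance = 1e-12)
  expect_equal(unname(es2$y["x1"]), unname(es1$y["x1"]), tolerance = 1e-12)
})

test_that("ols rejects collinear designs naming the culprit and tiny samples", {
  df <- data.frame(x1 = rnorm(50))
  df$x2 <- 2 * df$x1
  df$y <- rnorm(50)
  err <- tryCatch(fit_ols_study(df, "y", c("x1", "x2")), error = identity)
  expect_s3_class(err, "sammeta_singular_design")
  expect_match(conditionMessage(err), "x2")
  expect_error(fit_ols_study(df[1:3, ], "y", c("x1", "x2")),
               class = "sammeta_insufficient_data")
})

test_that("mediation satisfies the exact total-effect decomposition a*b + c' = total", {
  withr::with_seed(21, {
    x <- rnorm(400)
    m <- 0.5 * x + rnorm(400)
    y <- 0.4 * m + 0.3 * x + rnorm(400)
  })
  df <- data.frame(x = x, m = m, y = y)
  es <- fit_mediation_study(df, "x", "m", "y")
  total <- fit_ols_study(df, "y", "x")$y[["x"]]
  expect_equal(unname(es$y["indirect"] + es$y["direct"]), total, tolerance = 1e-10)
  expect_equal(es$mediation$a_path * es$mediation$b_path,
               unname(es$y["indirect"]), tolerance = 1e-14)
})

test_that("mediation indirect effect vanishes when the b path is exactly zero", {
  # construct m orthogonal to the y residual space: y depends only on x,
  # and m is built orthogonal to y after partialling x, so b-hat = 0
  withr::with_seed(22, {
    x <- rnorm(200)
    y <- 0.7 * x + rnorm(200)
    z <- rnorm(200)
  })
  rx <- residuals(lm(z ~ x))
  ry <- residuals(lm(y ~ x))
  m_orth <- x * 0.4 + (rx - sum(rx * ry) / sum(ry^2) * ry)  # orthogonal to ry
  es <- fit_mediation_study(data.frame(x = x, m = m_orth, y = y), "x", "m", "y")
  expect_lt(abs(es$y[["indirect"]]), 1e-10)
})

test_that("mediation recovers generator truth within delta-method error", {
  sim <- simulate_mediation_dataset(k = 1, n = 1e4, a = 0.5, b = 0.4,
                                    c_prime = 0.3, seed = 23)
  es <- fit_mediation_study(sim$data, "x", "m", "y")
  expect_lt(abs(es$y[["indirect"]] - 0.2), 3 * sqrt(es$V[1, 1]))
  expect_error(fit_mediation_study(sim$data, "x", "x", "y"),
               class = "sammeta_invalid_argument")
})

test_that("coefficient alpha matches the parallel-items closed form", {
  # 4 parallel items, pairwise correlation exactly 0.5:
  # alpha = p r / (1 + (p-1) r) = 2/2.5 = 0.8
  df <- make_exact_cov_data(300, cs_corr(4, 0.5), seed = 31)
  es <- estimate_alpha_study(df, paste0("v", 1:4))
  expect_equal(es$alpha, 0.8, tolerance = 1e-12)
  expect_equal(es$var_alpha, 2 * 4 * (1 - 0.8)^2 / (3 * 298), tolerance = 1e-12)
})

test_that("perfectly correlated items give alpha 1 with zero variance", {
  base <- rnorm(100)
  df <- data.frame(v1 = base, v2 = base, v3 = base)
  es <- estimate_alpha_study(df, c("v1", "v2", "v3"))
  expect_equal(es$alpha, 1, tolerance = 1e-12)
  expect_equal(es$var_alpha, 0, tolerance = 1e-20)
  expect_error(estimate_alpha_study(df, c("v1", "v2", "v3"), transform = "bonett"),
               class = "sammeta_degenerate_data")
})

test_that("bonett transform pools on the log scale with its own variance", {
  df <- make_exact_cov_data(300, cs_corr(4, 0.5), seed = 32)
  es <- estimate_alpha_study(df, paste0("v", 1:4), transform = "bonett")
  expect_equal(unname(es$y[1]), log(1 - 0.8), tolerance = 1e-10)
  expect_equal(es$V[1, 1], 2 * 4 / (3 * 298), tolerance = 1e-12)
})

test_that("bivariate correlation study reproduces the classical variance of r", {
  df <- make_exact_cov_data(250, cs_corr(2, 0.6), seed = 41)
  cs <- correlation_study(df, c("v1", "v2"))
  expect_equal(dim(cs$acov), c(1L, 1L))
  expect_equal(cs$acov[1, 1], (1 - 0.6^2)^2 / 250, tolerance = 1e-12)
})

test_that("correlation study reproduces an imposed sample correlation exactly", {
  R <- matrix(c(1, 0.3, 0.5, 0.3, 1, -0.2, 0.5, -0.2, 1), 3, 3)
  df <- make_exact_cov_data(120, R, seed = 42)
  cs <- correlation_study(df, paste0("v", 1:3))
  expect_equal(unname(cs$R), R, tolerance = 1e-12)
  expect_error(correlation_study(transform(df, v3 = 1), paste0("v", 1:3)),
               class = "sammeta_degenerate_data")
})

test_that("correlation acov matches the Monte-Carlo variance of r", {
  # oracle: empirical variance of the sample correlation over replicates
  reps <- 800
  n <- 500
  rs <- withr::with_seed(43, vapply(seq_len(reps), function(i) {
    x <- MASS::mvrnorm(n, c(0, 0), cs_corr(2, 0.6))
    cor(x)[1, 2]
  }, numeric(1)))
  acov <- sammeta:::cor_acov(cs_corr(2, 0.6), n)
  expect_lt(abs(acov[1, 1] / var(rs) - 1), 0.15)
})

test_that("every estimator returns a symmetric PSD sampling covariance", {
  sim <- simulate_regression_dataset(meta_sim_spec(
    k = 4, n_per_stratum = 200, gamma_true = c(0.5, -1, 0.2),
    tau2_true = diag(0.02, 3), predictor_cor = 0.3, seed = 51))
  frames <- suppressMessages(split_study_frames(
    sim$data, split_plan("stratified", strata = "stratum", seed = 1)))
  msim <- simulate_mediation_dataset(k = 2, n = 300, a = 0.5, b = 0.4,
                                     c_prime = 0.3, seed = 52)
  mframes <- suppressMessages(split_study_frames(
    msim$data, split_plan("stratified", strata = "stratum", seed = 1)))
  vs <- c(
    lapply(frames, function(f) fit_ols_study(f, "y", c("x1", "x2", "x3"))$V),
    lapply(mframes, function(f) fit_mediation_study(f, "x", "m", "y")$V),
    lapply(frames, function(f) correlation_study(f, c("x1", "x2", "y"))$acov)
  )
  for (V in vs) {
    expect_lt(max(abs(V - t(V))), 1e-10)
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})
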