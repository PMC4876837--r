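test_that("fixed-effects pooling of a single study is the identity", {
  es <- effect_set("only", c(a = 0.3, b = -0.1),
                   matrix(c(0.01, 0.002, 0.002, 0.02), 2), 100)
  fit <- meta_fixed(list(es))
  expect_equal(unname(fit$gamma), unname(es$y), tolerance = 1e-12)
  expect_equal(unname(fit$cov_gamma), unname(es$V), tolerance = 1e-12)
})

test_that("fixed-effects pooling matches hand inverse-variance weighting", {
  # weights 100 and 25: pooled = (100*0.4 + 25*0.6)/125 = 0.44, SE = 1/sqrt(125)
  effs <- make_univariate_effects(c(0.4, 0.6), c(0.01, 0.04))
  fit <- meta_fixed(effs)
  expect_equal(unname(fit$gamma), 0.44, tolerance = 1e-12)
  expect_equal(unname(fit$se), sqrt(1 / 125), tolerance = 1e-12)
})

test_that("fixed pooling rejects singular sampling covariances naming the study", {
  effs <- list(effect_set("good", c(a = 1), matrix(0.1), 50),
               effect_set("bad", c(a = 2), matrix(0), 50))
  err <- tryCatch(meta_fixed(effs), error = identity)
  expect_s3_class(err, "sammeta_conditioning")
  expect_match(conditionMessage(err), "bad")
  expect_error(
    meta_fixed(list(effect_set("a", c(x = 1), matrix(0.1), 10),
                    effect_set("b", c(z = 1), matrix(0.1), 10))),
    class = "sammeta_schema")
})

test_that("equal-variance REML heterogeneity matches the closed form", {
  # with equal known v, REML tau2 = max(0, sample variance of y - v)
  effs <- make_univariate_effects(c(0, 1, 2), 0.5)
  fit <- meta_random(effs, meta_model_spec("random", tau2_structure = "diagonal"))
  expect_equal(fit$tau2[1, 1], 0.5, tolerance = 1e-6)
  expect_equal(unname(fit$gamma), 1.0, tolerance = 1e-6)
  expect_equal(unname(fit$se), sqrt(1 / 3), tolerance = 1e-6)
})

test_that("identical effects collapse to zero heterogeneity and the fixed fit", {
  effs <- make_univariate_effects(rep(0.7, 5), 0.02)
  rf <- meta_random(effs, meta_model_spec("random", tau2_structure = "diagonal"))
  ff <- meta_fixed(effs)
  expect_lt(rf$tau2[1, 1], 1e-6)
  expect_true(rf$boundary)
  expect_equal(unname(rf$gamma), unname(ff$gamma), tolerance = 1e-8)
  expect_equal(unname(rf$se), unname(ff$se), tolerance = 1e-6)
})

test_that("random model with zero structure reduces exactly to fixed pooling", {
  withr::with_seed(71, {
    effs <- lapply(1:6, function(i) {
      A <- matrix(rnorm(4), 2) / 10
      effect_set(paste0("s", i), c(a = rnorm(1), b = rnorm(1)),
                 crossprod(A) + diag(0.01, 2), 100)
    })
  })
  rf <- meta_random(effs, meta_model_spec("random", tau2_structure = "zero"))
  ff <- meta_fixed(effs)
  expect_equal(rf$gamma, ff$gamma, tolerance = 1e-12)
  expect_equal(rf$cov_gamma, ff$cov_gamma, tolerance = 1e-12)
})

test_that("full-tau2 REML agrees with metafor on a bivariate pooled fit", {
  skip_if_not_installed("metafor")
  sim <- simulate_regression_dataset(meta_sim_spec(
    k = 40, n_per_stratum = 300, gamma_true = c(0.5, -1),
    tau2_true = matrix(c(0.04, 0.01, 0.01, 0.09), 2), seed = 72))
  frames <- suppressMessages(split_study_frames(
    sim$data, split_plan("stratified", strata = "stratum", seed = 1)))
  effs <- lapply(frames, fit_ols_study, outcome = "y", predictors = c("x1", "x2"))
  ours <- meta_random(effs)
  k <- length(effs)
  dat <- data.frame(y = as.vector(t(do.call(rbind, lapply(effs, `[[`, "y")))),
                    eff = factor(rep(c("x1", "x2"), k)),
                    study = rep(seq_len(k), each = 2))
  Vb <- as.matrix(Matrix::bdiag(lapply(effs, `[[`, "V")))
  mf <- metafor::rma.mv(y ~ eff - 1, V = Vb, random = ~ eff | study,
                        struct = "UN", data = dat, method = "REML")
  expect_equal(unname(ours$gamma), unname(coef(mf)), tolerance = 1e-4)
  expect_equal(unname(ours$se), unname(mf$se), tolerance = 1e-3)
  expect_equal(unname(diag(ours$tau2)), unname(mf$tau2), tolerance = 1e-3)
  expect_equal(ours$tau2[1, 2], mf$rho * sqrt(prod(mf$tau2)), tolerance = 1e-3)
})

test_that("REML estimates are location-equivariant and leave tau2 unchanged", {
  withr::with_seed(73, {
    effs <- lapply(1:20, function(i)
      effect_set(paste0("s", i),
                 c(a = rnorm(1, 0.5, 0.2), b = rnorm(1, -1, 0.3)),
                 diag(c(0.01, 0.02)), 100))
  })
  spec <- meta_model_spec("random")
  f0 <- meta_random(effs, spec)
  shifted <- lapply(effs, function(e) {
    effect_set(e$study_id, e$y + c(10, 0), e$V, e$n, effect_names = e$effect_names)
  })
  f1 <- meta_random(shifted, spec)
  expect_equal(unname(f1$gamma), unname(f0$gamma) + c(10, 0), tolerance = 1e-5)
  expect_equal(f1$tau2, f0$tau2, tolerance = 1e-5)
})

test_that("restricted likelihood at the REML optimum is at least the zero-tau2 value", {
  withr::with_seed(74, {
    effs <- make_univariate_effects(rnorm(15, 1, 0.5), 0.05)
  })
  rf <- meta_random(effs, meta_model_spec("random", tau2_structure = "diagonal"))
  zf <- meta_random(effs, meta_model_spec("random", tau2_structure = "zero"))
  expect_gte(rf$loglik, zf$loglik - 1e-8)
})

test_that("i-squared uses the Higgins-Thompson typical variance", {
  # equal sampling variances: Vbar reduces to v exactly, so tau2 = v -> 0.5
  effs <- make_univariate_effects(c(0, 1, 2, 1, 0.5), 0.3)
  fit <- meta_random(effs, meta_model_spec("random", tau2_structure = "diagonal"))
  fit$tau2 <- matrix(0.3, dimnames = list("eff", "eff"))
  expect_equal(unname(i_squared(fit, effs)), 0.5, tolerance = 1e-12)
  fit$tau2 <- matrix(0, dimnames = list("eff", "eff"))
  expect_equal(unname(i_squared(fit, effs)), 0)
  # unequal variances: Q-based formula computed by hand
  v <- c(0.1, 0.2, 0.4)
  effs2 <- lapply(1:3, function(i)
    effect_set(paste0("s", i), c(eff = i), matrix(v[i]), 50))
  w <- 1 / v
  vbar <- (3 - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  fit2 <- meta_random(effs2, meta_model_spec("random", tau2_structure = "diagonal"))
  expect_equal(unname(i_squared(fit2, effs2)),
               fit2$tau2[1, 1] / (fit2$tau2[1, 1] + vbar), tolerance = 1e-10)
})

test_that("moderator R2 handles the trivial endpoints", {
  withr::with_seed(75, {
    effs <- lapply(1:30, function(i) {
      w <- rnorm(1)
      effect_set(paste0("s", i), c(a = 0.5 + 0.3 * w + rnorm(1, 0, 0.05)),
                 matrix(0.01), 100, moderators = c(w = w))
    })
  })
  base <- meta_random(effs, meta_model_spec("random", tau2_structure = "diagonal"))
  mixed <- meta_mixed(effs, "w",
                      meta_model_spec("mixed", moderators = "w",
                                      tau2_structure = "diagonal"),
                      baseline = base)
  expect_equal(unname(r_squared(base, base)), 0)
  zero_fit <- base
  zero_fit$tau2 <- matrix(0, dimnames = dimnames(base$tau2))
  expect_equal(unname(r_squared(base, zero_fit)), 1)
  expect_true(mixed$r2 >= 0 && mixed$r2 <= 1)
  # moderator explains most of the built-in heterogeneity
  expect_gt(unname(mixed$r2), 0.5)
})

test_that("a constant or missing moderator is rejected", {
  effs <- lapply(1:5, function(i)
    effect_set(paste0("s", i), c(a = i / 10), matrix(0.01), 50,
               moderators = c(w = 1)))
  expect_error(meta_mixed(effs, "w"), class = "sammeta_degenerate_moderator")
  effs[[3]]$moderators <- numeric(0)
  expect_error(meta_mixed(effs, "w"), class = "sammeta_schema")
})

test_that("null moderation yields near-zero slope and R2", {
  withr::with_seed(76, {
    effs <- lapply(1:150, function(i) {
      effect_set(paste0("s", i), c(a = 0.5 + rnorm(1, 0, 0.2)),
                 matrix(0.01), 100, moderators = c(w = rnorm(1)))
    })
  })
  fit <- meta_mixed(effs, "w", meta_model_spec("mixed", moderators = "w",
                                               tau2_structure = "diagonal"))
  expect_lt(abs(fit$gamma[["a:w"]]), 3 * fit$se[["a:w"]])
  expect_lt(unname(fit$r2), 0.1)
})

test_that("confidence ellipse boundary satisfies the chi-square quantile equation", {
  withr::with_seed(77, {
    effs <- lapply(1:30, function(i)
      effect_set(paste0("s", i),
                 c(a = rnorm(1, 0.5, 0.2), b = rnorm(1, -1, 0.25)),
                 diag(c(0.01, 0.01)), 100))
  })
  fit <- meta_random(effs)
  ell <- confidence_ellipse(fit, level = 0.95)
  pts <- ell$boundary(seq(0, 2 * pi, length.out = 37))
  quad <- apply(pts, 1, function(x) {
    d <- x - ell$center
    as.numeric(d %*% solve(ell$shape) %*% d)
  })
  expect_equal(quad, rep(qchisq(0.95, 2), 37), tolerance = 1e-8)
  # circular special case: radius tau * sqrt(chi2 quantile)
  fit2 <- fit
  fit2$tau2 <- diag(0.04, 2)
  dimnames(fit2$tau2) <- dimnames(fit$tau2)
  ell2 <- confidence_ellipse(fit2)
  r <- sqrt(sum((ell2$boundary(1.1)[1, ] - ell2$center)^2))
  expect_equal(r, 0.2 * sqrt(qchisq(0.95, 2)), tolerance = 1e-8)
  # level scaling of boundary radii
  ell50 <- confidence_ellipse(fit2, level = 0.50)
  r50 <- sqrt(sum((ell50$boundary(1.1)[1, ] - ell50$center)^2))
  expect_equal(r / r50, sqrt(qchisq(0.95, 2) / qchisq(0.50, 2)), tolerance = 1e-8)
  # degenerate shape is an error
  fit3 <- fit
  fit3$tau2 <- matrix(0, 2, 2, dimnames = dimnames(fit$tau2))
  expect_error(confidence_ellipse(fit3), class = "sammeta_degenerate_ellipse")
})

test_that("effect sets round-trip losslessly through the flat CSV", {
  withr::with_seed(78, {
    effs <- lapply(1:4, function(i) {
      A <- matrix(rnorm(4), 2) / 8
      effect_set(paste0("s", i), c(a = rnorm(1), b = rnorm(1)),
                 crossprod(A) + diag(0.02, 2), 100 + i,
                 moderators = c(wave = i))
    })
  })
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_effects_csv(effs, tmp)
  back <- read_effects_csv(tmp)
  for (i in seq_along(effs)) {
    expect_equal(back[[i]]$y, effs[[i]]$y, tolerance = 1e-12)
    expect_equal(back[[i]]$V, effs[[i]]$V, tolerance = 1e-12)
    expect_identical(back[[i]]$study_id, effs[[i]]$study_id)
    expect_equal(back[[i]]$moderators, effs[[i]]$moderators)
  }
})
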