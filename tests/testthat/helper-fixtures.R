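# Shared fixture builders. All randomness is seed-scoped so tests are
# order-independent.

# Data whose *sample* covariance equals Sigma exactly (whiten the draws,
# then color by chol(Sigma)); column means are exactly zero.
make_exact_cov_data <- function(n, Sigma, seed = 1) {
  p <- ncol(Sigma)
  X <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  X <- scale(X, center = TRUE, scale = FALSE)
  S <- cov(X)
  Xw <- X %*% solve(chol(S))
  Xc <- Xw %*% chol(Sigma)
  colnames(Xc) <- paste0("v", seq_len(p))
  as.data.frame(Xc)
}

# Compound-symmetric covariance with unit variances.
cs_corr <- function(p, rho) {
  R <- matrix(rho, p, p)
  diag(R) <- 1
  R
}

# Quick study frame from a data frame.
frame_of <- function(data, id = "s1") {
  sammeta:::study_frame(id, data)
}

# k identical correlation studies over one population matrix.
make_corr_studies <- function(R, k, n, ids = sprintf("s%02d", seq_len(k))) {
  vars <- colnames(R)
  if (is.null(vars)) vars <- paste0("v", seq_len(ncol(R)))
  lapply(seq_len(k), function(i) {
    structure(list(study_id = ids[i], R = R, n = n,
                   acov = sammeta:::cor_acov(R, n),
                   vars = vars, moderators = numeric(0)),
              class = "sam_corr_study")
  })
}

# Synthetic univariate effect sets with known truth, for meta-engine tests.
make_univariate_effects <- function(y, v, n = 100) {
  lapply(seq_along(y), function(i) {
    effect_set(sprintf("s%02d", i), c(eff = y[i]),
               matrix(v[min(i, length(v))]), n)
  })
}
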