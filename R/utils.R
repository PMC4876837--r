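# Internal helpers shared across modules.

# Classed condition so callers can distinguish failure modes
# (invalid_split, singular_design, convergence, schema, ...).
sam_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("sammeta_", class), "sammeta_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

sam_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(paste0("sammeta_", class), "sammeta_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stopifnot_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x))
    sam_abort("invalid_argument", sprintf("`%s` must be a single integer", name))
  if (!is.null(min) && x < min)
    sam_abort("invalid_argument", sprintf("`%s` must be >= %s", name, min))
  as.integer(x)
}

# Column-major lower-triangle (excluding diagonal) vectorization of a
# symmetric matrix; the fixed ordering convention used for correlation
# effect sizes throughout: (2,1),(3,1),...,(p,1),(3,2),...
vech_offdiag <- function(R) {
  R[lower.tri(R)]
}

# Pair indices (i, j), i > j, in the same column-major order as vech_offdiag().
vech_pairs <- function(p) {
  idx <- which(lower.tri(diag(p)), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

# Inverse of vech_offdiag() for a correlation matrix (unit diagonal).
unvech_corr <- function(v, p) {
  R <- diag(p)
  R[lower.tri(R)] <- v
  R[upper.tri(R)] <- t(R)[upper.tri(R)]
  R
}

is_psd <- function(M, tol = 1e-10) {
  if (max(abs(M - t(M))) > 1e-8) return(FALSE)
  min(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values) >= -tol
}

check_symmetric_psd <- function(M, what, tol = 1e-10) {
  if (max(abs(M - t(M))) > 1e-8)
    sam_abort("invalid_argument", sprintf("%s must be symmetric", what))
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol)
    sam_abort("invalid_argument",
              sprintf("%s must be positive semi-definite (min eigenvalue %.3e)", what, min(ev)))
  invisible(TRUE)
}

# Seed-scoped evaluation: runs expr under the given seed and restores the
# caller's RNG state, so generators are deterministic without clobbering
# the session RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
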