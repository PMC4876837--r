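#' Construct an effect set
#'
#' The universal currency between the analyze and meta-analyze stages: a
#' study's effect-size vector together with its known sampling covariance
#' matrix, sample size, and any study-level moderator values.
#'
#' @param study_id Character label, unique within a run.
#' @param y Numeric effect-size vector.
#' @param V Symmetric positive semi-definite sampling covariance matrix of
#'   `y`, with strictly positive diagonal.
#' @param n Study sample size.
#' @param effect_names Labels for the entries of `y`; defaults to
#'   `names(y)`.
#' @param moderators Named numeric vector of study-level moderator values
#'   (e.g. `c(wave = 4)`), possibly empty.
#'
#' @return An object of class `sam_effect_set`.
#' @export
effect_set <- function(study_id, y, V, n, effect_names = names(y),
                       moderators = numeric(0)) {
  effect_names <- effect_names  # force before names are stripped below
  y <- as.numeric(y)
  p <- length(y)
  V <- as.matrix(V)
  if (is.null(effect_names)) effect_names <- paste0("effect", seq_len(p))
  if (length(effect_names) != p || !all(dim(V) == p))
    sam_abort("schema", "y, V and effect_names must have matching dimensions")
  if (max(abs(V - t(V))) > 1e-10)
    sam_abort("invalid_argument", "V must be symmetric (tolerance 1e-10)")
  if (any(diag(V) < 0))
    sam_abort("invalid_argument", "diagonal of V must be non-negative")
  check_symmetric_psd(V, "V")
  if (length(moderators) && is.null(names(moderators)))
    sam_abort("schema", "moderators must be named")
  dimnames(V) <- list(effect_names, effect_names)
  structure(
    list(study_id = as.character(study_id), y = setNames(y, effect_names),
         V = V, n = as.integer(n), effect_names = effect_names,
         moderators = moderators),
    class = "sam_effect_set"
  )
}

#' @export
print.sam_effect_set <- function(x, ...) {
  cat("<sam_effect_set> study", x$study_id, " (n =", x$n, ")\n")
  est <- cbind(estimate = x$y, se = sqrt(diag(x$V)))
  print(round(est, 4))
  if (length(x$moderators))
    cat("moderators:", paste(names(x$moderators), "=", x$moderators, collapse = ", "), "\n")
  invisible(x)
}

check_effects_conformable <- function(effects) {
  if (!length(effects)) sam_abort("schema", "no effect sets supplied")
  if (!all(vapply(effects, inherits, logical(1), "sam_effect_set")))
    sam_abort("schema", "all elements must be sam_effect_set objects")
  nm <- effects[[1]]$effect_names
  for (e in effects) {
    if (!identical(e$effect_names, nm))
      sam_abort("schema", sprintf("effect_names mismatch in study %s", e$study_id))
  }
  ids <- vapply(effects, `[[`, character(1), "study_id")
  if (anyDuplicated(ids))
    sam_abort("schema", "duplicated study_id among effect sets")
  invisible(nm)
}

#' Write or read effect sets as a flat CSV
#'
#' One row per study: `study_id`, `n`, one `est_<name>` column per effect,
#' the lower-triangle-with-diagonal of V in column-major order as
#' `v_<row>_<col>` columns, and one `mod_<name>` column per moderator. The
#' layout round-trips losslessly so the analyze and meta-analyze stages can
#' run as separate invocations.
#'
#' @param effects List of [effect_set()] objects.
#' @param path Output CSV path.
#' @return `write_effects_csv()` returns `path` invisibly;
#'   `read_effects_csv()` returns a list of `sam_effect_set`.
#' @export
write_effects_csv <- function(effects, path) {
  check_effects_conformable(effects)
  p <- length(effects[[1]]$y)
  nm <- effects[[1]]$effect_names
  vidx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  vcols <- paste0("v_", vidx[, 1], "_", vidx[, 2])
  mods <- names(effects[[1]]$moderators)
  rows <- lapply(effects, function(e) {
    out <- c(list(study_id = e$study_id, n = e$n),
             setNames(as.list(e$y), paste0("est_", nm)),
             setNames(as.list(e$V[vidx]), vcols))
    if (length(mods))
      out <- c(out, setNames(as.list(e$moderators[mods]), paste0("mod_", mods)))
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  attr(df, "effect_names") <- nm
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effects_csv
#' @export
read_effects_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  est_cols <- grep("^est_", names(df), value = TRUE)
  nm <- sub("^est_", "", est_cols)
  p <- length(nm)
  vidx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  vcols <- paste0("v_", vidx[, 1], "_", vidx[, 2])
  if (!all(vcols %in% names(df)))
    sam_abort("schema", "effects CSV is missing sampling-covariance columns")
  mod_cols <- grep("^mod_", names(df), value = TRUE)
  lapply(seq_len(nrow(df)), function(i) {
    V <- matrix(0, p, p)
    V[vidx] <- as.numeric(df[i, vcols])
    V[upper.tri(V)] <- t(V)[upper.tri(V)]
    mods <- setNames(as.numeric(df[i, mod_cols]), sub("^mod_", "", mod_cols))
    effect_set(df$study_id[i], as.numeric(df[i, est_cols]), V, df$n[i],
               effect_names = nm, moderators = mods)
  })
}
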