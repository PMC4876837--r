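# Configuration-driven orchestration of split -> analyze -> meta-analyze,
# with a plain-text run log and machine- plus human-readable reports.

ANALYZE_MODELS <- c("regression", "mediation", "alpha", "cfa", "crossed_lmm")

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path, a YAML/JSON string, or an already-parsed
#' list; checks the whole configuration and reports *all* problems at
#' once. Defaults are filled in (`min_study_size = 100`, `chunk_rows =
#' 10000`, REML, full `T^2`, mean-centered moderators).
#'
#' @param config Path, text, or list.
#' @return A validated `sam_run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
  }
  if (!is.list(config)) sam_abort("config", "config must be a list or YAML/JSON text")
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  unlist_chr <- function(x) if (is.null(x)) x else as.character(unlist(x))
  src <- config$source %||% list()
  src$variables <- unlist_chr(src$variables)
  if (is.null(src$locator)) note("source.locator is required")
  if (!length(src$variables)) note("source.variables must be non-empty")
  src$chunk_rows <- src$chunk_rows %||% 10000L
  src$missing_codes <- src$missing_codes %||% list()

  sp <- config$split %||% list()
  sp$strata <- unlist_chr(sp$strata)
  sp$method <- sp$method %||% "random"
  if (!sp$method %in% c("random", "stratified"))
    note("split.method must be 'random' or 'stratified'")
  if (identical(sp$method, "random")) {
    if (is.null(sp$k) || !is.numeric(sp$k) || sp$k < 1) note("split.k must be >= 1")
  } else if (!length(sp$strata)) {
    note("split.strata must be non-empty for a stratified split")
  }
  sp$seed <- sp$seed %||% 1L
  sp$min_study_size <- sp$min_study_size %||% 100L
  if (sp$min_study_size < 2) note("split.min_study_size must be >= 2")

  an <- config$analyze %||% list()
  for (f in c("outcome", "predictors", "x", "m", "y", "items", "vars", "random_factors"))
    an[[f]] <- unlist_chr(an[[f]])
  if (is.null(an$model) || !an$model %in% ANALYZE_MODELS) {
    note(paste("analyze.model must be one of:", paste(ANALYZE_MODELS, collapse = ", ")))
  } else {
    have <- function(field) {
      v <- an[[field]]
      if (!length(v)) note(sprintf("analyze.%s is required for model '%s'", field, an$model))
      v
    }
    vars_used <- switch(an$model,
      regression  = c(have("outcome"), have("predictors")),
      mediation   = { x <- have("x"); m <- have("m"); y <- have("y")
                      if (anyDuplicated(c(x, m, y))) note("analyze roles x, m, y must be distinct")
                      c(x, m, y) },
      alpha       = have("items"),
      cfa         = have("vars"),
      crossed_lmm = c(have("outcome"), have("predictors"), have("random_factors")))
    bad <- setdiff(vars_used, src$variables %||% character(0))
    if (length(bad))
      note(paste("analyze references variables missing from source.variables:",
                 paste(bad, collapse = ", ")))
  }

  me <- config$meta %||% list()
  me$moderators <- unlist_chr(me$moderators)
  me$model <- me$model %||% if (identical(sp$method, "random")) "fixed" else "random"
  if (!me$model %in% c("fixed", "random", "mixed"))
    note("meta.model must be 'fixed', 'random' or 'mixed'")
  me$tau2_structure <- me$tau2_structure %||% "full"
  me$estimator <- me$estimator %||% "REML"
  me$moderators <- me$moderators %||% character(0)
  if (identical(me$model, "mixed") && !length(me$moderators))
    note("meta.model 'mixed' needs meta.moderators")
  if (length(me$moderators)) {
    if (!identical(sp$method, "stratified"))
      note("stratum-level moderators require a stratified split")
    bad <- setdiff(me$moderators, src$variables %||% character(0))
    if (length(bad))
      note(paste("meta.moderators missing from source.variables:",
                 paste(bad, collapse = ", ")))
  }

  out <- config$output %||% list()
  out$dir <- out$dir %||% "sam_output"

  if (length(errs))
    sam_abort("config", paste0("invalid configuration:\n  - ",
                               paste(errs, collapse = "\n  - ")))
  structure(list(source = src, split = sp, analyze = an, meta = me,
                 output = out, log_level = config$log_level %||% "info"),
            class = "sam_run_config")
}

study_moderators <- function(frame, moderators) {
  if (!length(moderators)) return(numeric(0))
  vapply(moderators, function(mv) mean(as.numeric(frame$data[[mv]])), numeric(1))
}

analyze_frames <- function(frames, an, moderators) {
  lapply(frames, function(fr) {
    mods <- study_moderators(fr, moderators)
    switch(an$model,
      regression  = fit_ols_study(fr, an$outcome, an$predictors,
                                  include_intercept = isTRUE(an$include_intercept),
                                  moderators = mods),
      mediation   = fit_mediation_study(fr, an$x, an$m, an$y, moderators = mods),
      alpha       = estimate_alpha_study(fr, an$items,
                                         transform = an$transform %||% "raw",
                                         moderators = mods),
      cfa         = correlation_study(fr, an$vars, moderators = mods),
      crossed_lmm = fit_crossed_lmm_study(fr, an$outcome, an$predictors,
                                          an$random_factors, moderators = mods))
  })
}

meta_fit_report <- function(fit) {
  z <- fit$gamma / fit$se
  coef_tab <- data.frame(parameter = names(fit$gamma),
                         estimate = as.numeric(fit$gamma),
                         se = as.numeric(fit$se),
                         z = as.numeric(z),
                         p = 2 * stats::pnorm(-abs(z)))
  p <- length(fit$effect_names)
  tl <- which(lower.tri(fit$tau2, diag = TRUE), arr.ind = TRUE)
  het_tab <- data.frame(
    component = sprintf("tau2_%s_%s", fit$effect_names[tl[, 1]],
                        fit$effect_names[tl[, 2]]),
    value = fit$tau2[tl])
  if (!is.null(fit$i2))
    het_tab <- rbind(het_tab, data.frame(
      component = paste0("i2_", names(fit$i2)), value = as.numeric(fit$i2)))
  if (!is.null(fit$r2))
    het_tab <- rbind(het_tab, data.frame(
      component = paste0("r2_", names(fit$r2)), value = as.numeric(fit$r2)))
  list(coefficients = coef_tab, heterogeneity = het_tab)
}

meta_fit_json <- function(fit) {
  list(model = fit$model, estimator = fit$estimator,
       tau2_structure = fit$tau2_structure,
       k = fit$k, total_n = fit$total_n,
       gamma = as.list(fit$gamma), se = as.list(setNames(fit$se, names(fit$gamma))),
       tau2 = apply(fit$tau2, 1, identity, simplify = FALSE),
       i2 = if (is.null(fit$i2)) NULL else as.list(fit$i2),
       r2 = if (is.null(fit$r2)) NULL else as.list(fit$r2),
       loglik = fit$loglik, converged = fit$converged,
       boundary = fit$boundary)
}

#' Run the full split/analyze/meta-analyze pipeline
#'
#' Executes the three stages described by a validated configuration and
#' writes a report bundle into `output.dir`: the per-study effect sizes as
#' a flat CSV (re-runnable through the meta stage alone), the pooled fit
#' as JSON plus coefficient and heterogeneity CSV tables, optional
#' confidence-ellipse boundary points, and a run log recording the seed,
#' the number of studies, per-study sizes, dropped studies, and
#' convergence flags. Identical configurations produce identical bundles.
#'
#' @param config Path, text, or list accepted by [validate_config()].
#' @return Invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$output$dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("sam pipeline run",
                 sprintf("seed: %d", cfg$split$seed),
                 sprintf("split: %s", cfg$split$method),
                 sprintf("analyze: %s", cfg$analyze$model),
                 sprintf("meta: %s (%s, tau2 %s)", cfg$meta$model,
                         cfg$meta$estimator, cfg$meta$tau2_structure))
  dropped <- character(0)
  src <- tabular_source(cfg$source$locator, unlist(cfg$source$variables),
                        missing_codes = cfg$source$missing_codes,
                        chunk_rows = cfg$source$chunk_rows,
                        table = cfg$source$table, query = cfg$source$query)
  plan <- split_plan(cfg$split$method, k = cfg$split$k,
                     strata = unlist(cfg$split$strata), seed = cfg$split$seed,
                     min_study_size = cfg$split$min_study_size)
  frames <- withCallingHandlers(
    suppressMessages(iter_study_frames(src, plan)),
    sammeta_small_study = function(w) {
      dropped <<- c(dropped, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  log_lines <- c(log_lines, sprintf("studies kept: %d", length(frames)),
                 sprintf("study %s: n = %d (dropped %d missing rows)",
                         names(frames), vapply(frames, `[[`, integer(1), "n"),
                         vapply(frames, `[[`, integer(1), "n_dropped")),
                 if (length(dropped)) paste("dropped:", dropped))

  results <- analyze_frames(frames, cfg$analyze, cfg$meta$moderators)
  paths <- list()
  bundle <- list(config = cfg, frames_n = vapply(frames, `[[`, integer(1), "n"))

  if (identical(cfg$analyze$model, "cfa")) {
    stage1 <- tssem_stage1(results,
                           tau2_structure = cfg$meta$stage1_tau2 %||% "diagonal",
                           estimator = cfg$meta$estimator)
    fspec <- factor_model_spec(unlist(cfg$analyze$vars),
                               loading_pattern = cfg$analyze$loading_pattern)
    stage2 <- tssem_stage2(stage1, fspec, ci = cfg$analyze$ci %||% "wald")
    paths$pooled_R <- file.path(cfg$output$dir, "pooled_correlations.csv")
    utils::write.csv(as.data.frame(stage1$pooled_R), paths$pooled_R)
    paths$stage2_json <- file.path(cfg$output$dir, "stage2.json")
    jsonlite::write_json(
      list(loadings = as.list(stage2$loadings), se = as.list(stage2$se),
           ci_lower = as.list(stage2$ci_lower), ci_upper = as.list(stage2$ci_upper),
           chi2 = stage2$chi2, df = stage2$df, rmsea = stage2$rmsea,
           srmr = stage2$srmr, heywood = stage2$heywood,
           tau2_diag = as.list(setNames(stage1$tau2_diag,
                                        names(stage1$r_pooled)))),
      paths$stage2_json, auto_unbox = TRUE, digits = NA)
    log_lines <- c(log_lines,
                   sprintf("stage1 converged: %s; stage2 chi2(%d) = %.4f",
                           stage1$converged, stage2$df, stage2$chi2))
    bundle$stage1 <- stage1; bundle$stage2 <- stage2
  } else {
    paths$effects_csv <- file.path(cfg$output$dir, "effects.csv")
    write_effects_csv(results, paths$effects_csv)
    spec <- meta_model_spec(cfg$meta$model, moderators = unlist(cfg$meta$moderators),
                            tau2_structure = cfg$meta$tau2_structure,
                            estimator = cfg$meta$estimator)
    fit <- switch(cfg$meta$model,
                  fixed  = meta_fixed(results),
                  random = meta_random(results, spec),
                  mixed  = meta_mixed(results, unlist(cfg$meta$moderators), spec))
    rep_ <- meta_fit_report(fit)
    paths$coefficients_csv <- file.path(cfg$output$dir, "coefficients.csv")
    utils::write.csv(rep_$coefficients, paths$coefficients_csv, row.names = FALSE)
    paths$heterogeneity_csv <- file.path(cfg$output$dir, "heterogeneity.csv")
    utils::write.csv(rep_$heterogeneity, paths$heterogeneity_csv, row.names = FALSE)
    paths$meta_json <- file.path(cfg$output$dir, "meta_fit.json")
    jsonlite::write_json(meta_fit_json(fit), paths$meta_json,
                         auto_unbox = TRUE, digits = NA)
    log_lines <- c(log_lines, sprintf("meta converged: %s (k = %d, total n = %d)",
                                      fit$converged, fit$k, fit$total_n))
    if (!is.null(cfg$meta$ellipse) && fit$model %in% c("random", "mixed")) {
      ell <- confidence_ellipse(fit, pair = unlist(cfg$meta$ellipse))
      paths$ellipse_csv <- file.path(cfg$output$dir, "ellipse.csv")
      utils::write.csv(ellipse_points(ell), paths$ellipse_csv, row.names = FALSE)
      bundle$ellipse <- ell
    }
    bundle$fit <- fit
  }
  paths$log <- file.path(cfg$output$dir, "run_log.txt")
  writeLines(log_lines, paths$log)
  bundle$effects <- results
  bundle$paths <- paths
  invisible(bundle)
}
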