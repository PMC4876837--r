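#' Describe a tabular data source
#'
#' Points at a rectangular data source — an RFC-4180 CSV file with a header
#' row, or a SQLite database (table name or SELECT query) — and names the
#' analysis variables to load. Only the named variables are ever read, and
#' CSV sources are read in chunks of `chunk_rows` rows so memory use stays
#' bounded regardless of file size.
#'
#' @param locator Path to the CSV file or SQLite database.
#' @param variables Character vector of column names to load (non-empty).
#' @param missing_codes Named list mapping a variable to the values that
#'   should be treated as missing (e.g. `list(A170 = c(-1, -2))`), applied
#'   before listwise deletion.
#' @param chunk_rows Rows per streaming read (>= 1).
#' @param table SQLite table name (SQLite backend only).
#' @param query SQLite SELECT query, alternative to `table`.
#' @param backend `"auto"` (from file extension), `"csv"`, or `"sqlite"`.
#' @return A `sam_tabular_source` object.
#' @export
tabular_source <- function(locator, variables, missing_codes = list(),
                           chunk_rows = 10000L, table = NULL, query = NULL,
                           backend = c("auto", "csv", "sqlite")) {
  backend <- match.arg(backend)
  if (!length(variables)) sam_abort("invalid_argument", "`variables` must be non-empty")
  chunk_rows <- stopifnot_scalar_int(chunk_rows, "chunk_rows", min = 1)
  if (backend == "auto") {
    backend <- if (grepl("\\.(sqlite|db|sqlite3)$", locator, ignore.case = TRUE) ||
                   !is.null(table) || !is.null(query)) "sqlite" else "csv"
  }
  if (backend == "sqlite" && is.null(table) && is.null(query))
    sam_abort("invalid_argument", "SQLite source needs `table` or `query`")
  if (length(missing_codes) && is.null(names(missing_codes)))
    sam_abort("invalid_argument", "`missing_codes` must be a named list")
  src <- structure(
    list(locator = locator, variables = as.character(variables),
         missing_codes = missing_codes, chunk_rows = chunk_rows,
         table = table, query = query, backend = backend),
    class = "sam_tabular_source"
  )
  src
}

#' Describe how to split rows into pseudo-studies
#'
#' @param method `"random"` (rows dealt into `k` near-equal studies after a
#'   seeded permutation) or `"stratified"` (one study per observed
#'   combination of the `strata` variables).
#' @param k Number of studies (random method).
#' @param strata Character vector of stratum variable names (stratified
#'   method).
#' @param seed Integer seed; recorded in all outputs.
#' @param min_study_size Studies smaller than this after listwise deletion
#'   are dropped with a warning. The default of 100 reflects the usual
#'   requirement that per-study estimates be approximately normal.
#' @return A `sam_split_plan` object.
#' @export
split_plan <- function(method = c("random", "stratified"), k = NULL,
                       strata = NULL, seed = 1L, min_study_size = 100L) {
  method <- match.arg(method)
  seed <- stopifnot_scalar_int(seed, "seed")
  min_study_size <- stopifnot_scalar_int(min_study_size, "min_study_size", min = 2)
  if (method == "random") {
    if (is.null(k)) sam_abort("invalid_argument", "random split needs `k`")
    k <- stopifnot_scalar_int(k, "k", min = 1)
  } else {
    if (!length(strata)) sam_abort("invalid_argument", "stratified split needs `strata`")
    strata <- as.character(strata)
  }
  structure(list(method = method, k = k, strata = strata, seed = seed,
                 min_study_size = min_study_size),
            class = "sam_split_plan")
}

#' Random assignment of rows to near-equal studies
#'
#' Deals the rows into `k` studies after a seeded permutation: study sizes
#' differ by at most one, with remainder rows going to the lowest-numbered
#' studies. The same seed always reproduces the same assignment.
#'
#' @param n_rows Number of rows.
#' @param k Number of studies, `1 <= k <= n_rows`.
#' @param seed Integer seed.
#' @return Integer vector of length `n_rows` with study indices in `1:k`.
#' @export
make_random_split <- function(n_rows, k, seed) {
  n_rows <- stopifnot_scalar_int(n_rows, "n_rows", min = 1)
  k <- stopifnot_scalar_int(k, "k", min = 1)
  if (k > n_rows)
    sam_abort("invalid_split", sprintf("k = %d exceeds n_rows = %d", k, n_rows))
  sizes <- rep(n_rows %/% k, k) + c(rep(1L, n_rows %% k), rep(0L, k - n_rows %% k))
  perm <- with_seed(seed, sample.int(n_rows))
  assignment <- integer(n_rows)
  assignment[perm] <- rep.int(seq_len(k), sizes)
  assignment
}

#' Stratified assignment of rows to studies
#'
#' One study per observed unique combination of stratum values; the study
#' label joins the values with `"__"` (e.g. `"Chile__4"`).
#'
#' @param stratum_table Data frame (or matrix) of stratum values, one
#'   column per stratum variable.
#' @return Character vector of study labels, one per row.
#' @export
make_stratified_split <- function(stratum_table) {
  stratum_table <- as.data.frame(stratum_table)
  if (!ncol(stratum_table)) sam_abort("invalid_split", "no stratum columns supplied")
  for (j in names(stratum_table)) {
    if (all(is.na(stratum_table[[j]])))
      sam_abort("invalid_split", sprintf("stratum column '%s' is entirely missing", j))
  }
  do.call(paste, c(lapply(stratum_table, as.character), sep = "__"))
}

study_frame <- function(study_id, data, stratum_values = list(), n_dropped = 0L) {
  structure(list(study_id = as.character(study_id),
                 stratum_values = stratum_values,
                 data = data, n = nrow(data), n_dropped = as.integer(n_dropped)),
            class = "sam_study_frame")
}

#' @export
print.sam_study_frame <- function(x, ...) {
  cat("<sam_study_frame>", x$study_id, " n =", x$n,
      " vars:", paste(names(x$data), collapse = ", "), "\n")
  invisible(x)
}

# Apply missing codes, then listwise deletion over the analysis variables.
clean_block <- function(df, variables, missing_codes) {
  for (v in intersect(names(missing_codes), names(df))) {
    df[[v]][df[[v]] %in% missing_codes[[v]]] <- NA
  }
  keep <- stats::complete.cases(df[, variables, drop = FALSE])
  list(data = df[keep, , drop = FALSE], n_dropped = sum(!keep))
}

finalize_frames <- function(blocks, stratum_values, plan) {
  frames <- list()
  for (id in names(blocks)) {
    b <- blocks[[id]]
    if (b$n_dropped > 0)
      message(sprintf("study %s: dropped %d row(s) with missing values", id, b$n_dropped))
    if (nrow(b$data) < plan$min_study_size) {
      sam_warn("small_study",
               sprintf("study %s skipped: n = %d < min_study_size = %d",
                       id, nrow(b$data), plan$min_study_size))
      next
    }
    frames[[id]] <- study_frame(id, b$data, stratum_values[[id]] %||% list(),
                                n_dropped = b$n_dropped)
  }
  if (!length(frames))
    sam_abort("empty_split", "no studies survived the split and size filter")
  frames
}

random_ids <- function(k) sprintf("study_%0*d", max(3L, nchar(k)), seq_len(k))

#' Split a source into per-study data frames
#'
#' Realizes the splitting stage: reads the source (in bounded-memory chunks
#' for CSV, one query per study group for SQLite), assigns rows to
#' pseudo-studies per the plan, applies missing-value codes and listwise
#' deletion within each study, and drops studies smaller than
#' `min_study_size` with a warning naming the study and its size.
#'
#' Stratified studies are returned in lexicographic order of their labels;
#' random-split studies in index order. Identical `(source, plan)` always
#' yield an identical sequence of frames.
#'
#' @param source A [tabular_source()].
#' @param plan A [split_plan()].
#' @param assignment_path Optional path: writes the row-to-study assignment
#'   as a two-column CSV (`row_index`, `study_id`).
#' @return Named list of `sam_study_frame` objects.
#' @export
iter_study_frames <- function(source, plan, assignment_path = NULL) {
  if (!inherits(source, "sam_tabular_source"))
    sam_abort("invalid_argument", "`source` must be a sam_tabular_source")
  if (!inherits(plan, "sam_split_plan"))
    sam_abort("invalid_argument", "`plan` must be a sam_split_plan")
  need <- source$variables
  if (plan$method == "stratified") need <- union(need, plan$strata)
  df <- switch(source$backend,
               csv = read_csv_chunked(source, need),
               sqlite = read_sqlite_all(source, need))
  split_study_frames(df, plan, variables = source$variables,
                     missing_codes = source$missing_codes,
                     assignment_path = assignment_path)
}

#' Split an in-memory data frame into study frames
#'
#' Same semantics as [iter_study_frames()] for data already in memory;
#' used internally for both file backends and convenient for simulated
#' data.
#'
#' @inheritParams iter_study_frames
#' @param data Data frame holding at least `variables` (plus the stratum
#'   columns for a stratified plan).
#' @param variables Analysis variables subject to listwise deletion.
#' @param missing_codes As in [tabular_source()].
#' @return Named list of `sam_study_frame` objects.
#' @export
split_study_frames <- function(data, plan, variables = names(data),
                               missing_codes = list(), assignment_path = NULL) {
  miss <- setdiff(variables, names(data))
  if (length(miss))
    sam_abort("schema", paste("variables absent from source:", paste(miss, collapse = ", ")))
  if (plan$method == "random") {
    assignment <- make_random_split(nrow(data), plan$k, plan$seed)
    ids <- random_ids(plan$k)
    labels <- ids[assignment]
    order_ids <- ids
    stratum_values <- setNames(rep(list(list()), plan$k), ids)
  } else {
    miss_s <- setdiff(plan$strata, names(data))
    if (length(miss_s))
      sam_abort("schema", paste("stratum variables absent:", paste(miss_s, collapse = ", ")))
    labels <- make_stratified_split(data[, plan$strata, drop = FALSE])
    order_ids <- sort(unique(labels))
    stratum_values <- lapply(order_ids, function(id) {
      row <- data[match(id, labels), plan$strata, drop = FALSE]
      as.list(row)
    })
    names(stratum_values) <- order_ids
  }
  if (!is.null(assignment_path)) {
    utils::write.csv(data.frame(row_index = seq_along(labels), study_id = labels),
                     assignment_path, row.names = FALSE)
  }
  blocks <- lapply(order_ids, function(id) {
    block <- data[labels == id, , drop = FALSE]
    rownames(block) <- NULL
    clean_block(block, variables, missing_codes)
  })
  names(blocks) <- order_ids
  finalize_frames(blocks, stratum_values, plan)
}

read_csv_chunked <- function(source, need) {
  if (!file.exists(source$locator))
    sam_abort("io", sprintf("cannot read CSV source '%s'", source$locator))
  header <- names(data.table::fread(source$locator, nrows = 0L, header = TRUE))
  miss <- setdiff(need, header)
  if (length(miss))
    sam_abort("schema", paste("variables absent from CSV header:", paste(miss, collapse = ", ")))
  chunks <- list()
  skip <- 1L  # header line consumed
  repeat {
    ch <- tryCatch(
      data.table::fread(source$locator, skip = skip, nrows = source$chunk_rows,
                        header = FALSE, col.names = header, data.table = FALSE,
                        showProgress = FALSE),
      error = function(e) {
        # fread errors (rather than returning 0 rows) when skip lands at EOF
        if (grepl("input only has|skip=", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(ch) || !nrow(ch)) break
    chunks[[length(chunks) + 1L]] <- ch[, need, drop = FALSE]
    skip <- skip + nrow(ch)
    if (nrow(ch) < source$chunk_rows) break
  }
  if (!length(chunks)) sam_abort("io", "CSV source has no data rows")
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}

read_sqlite_all <- function(source, need) {
  if (!file.exists(source$locator))
    sam_abort("io", sprintf("cannot read SQLite source '%s'", source$locator))
  con <- DBI::dbConnect(RSQLite::SQLite(), source$locator,
                        flags = RSQLite::SQLITE_RO)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  sql <- source$query %||%
    sprintf("SELECT %s FROM %s",
            paste(sprintf('"%s"', need), collapse = ", "), source$table)
  res <- DBI::dbSendQuery(con, sql)
  on.exit(DBI::dbClearResult(res), add = TRUE, after = FALSE)
  chunks <- list()
  repeat {
    ch <- DBI::dbFetch(res, n = source$chunk_rows)
    if (!nrow(ch)) break
    chunks[[length(chunks) + 1L]] <- ch
  }
  if (!length(chunks)) sam_abort("io", "SQLite query returned no rows")
  out <- do.call(rbind, chunks)
  miss <- setdiff(need, names(out))
  if (length(miss))
    sam_abort("schema", paste("variables absent from SQLite result:",
                              paste(miss, collapse = ", ")))
  rownames(out) <- NULL
  out[, need, drop = FALSE]
}
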