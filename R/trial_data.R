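# Reading, validating and writing trial-level datasets.
#
# One row per trial, in ascending trial order within each subject-by-condition
# block. Required columns: rt (seconds), response (0/1; 1 = option tied to the
# upper decision boundary), split_by (condition), subj_idx, feedback, q_init.
# Extra numeric columns are carried along and may serve as trial-wise
# regressors.

REQUIRED_COLS <- c("rt", "response", "split_by", "subj_idx", "feedback", "q_init")

#' Load a trial-level dataset
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the header line) with
#' one row per trial in ascending trial order, validates it, and returns a
#' `trial_table`. Row order is preserved exactly as in the file; the trial
#' index is implicit.
#'
#' @param path Path to a comma- or tab-delimited file with a header row.
#' @param require_rt Require an `rt` column. Set to `FALSE` only for the
#'   softmax-only choice model, which ignores response times.
#' @return A `trial_table` (a validated `data.frame`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_trials(simulate_rlddm_dataset(2, pst_schedule(10), seed = 1), f)
#' head(load_trials(f))
#' @seealso [validate_trials()], [write_trials()]
#' @export
load_trials <- function(path, require_rt = TRUE) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t"
         else if (grepl(",", header, fixed = TRUE)) ","
         else abort_schema(
           "cannot detect delimiter: header contains neither a comma nor a tab")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_trials(df, require_rt = require_rt)
}

#' Validate a trial-level data frame
#'
#' Checks the required column set and the per-trial invariants: `rt > 0`,
#' `response` in \{0, 1\}, non-negative integer `subj_idx`, no missing values
#' in required columns, and a constant `q_init` within each
#' subject-by-condition block. `q_init` values that differ across conditions
#' of the same subject are allowed but flagged with a warning.
#'
#' @param df A data frame with one row per trial in ascending trial order.
#' @inheritParams load_trials
#' @return The same data (classed as `trial_table`).
#' @export
validate_trials <- function(df, require_rt = TRUE) {
  required <- if (require_rt) REQUIRED_COLS else setdiff(REQUIRED_COLS, "rt")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    abort_schema(sprintf("missing required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  for (col in intersect(required, names(df))) {
    if (anyNA(df[[col]]))
      abort_validation(sprintf("column '%s' contains missing values (first at row %d)",
                               col, which(is.na(df[[col]]))[1]))
  }
  if ("rt" %in% names(df)) {
    if (!is.numeric(df$rt)) abort_validation("column 'rt' must be numeric")
    bad <- which(df$rt <= 0)
    if (length(bad) > 0)
      abort_validation(sprintf("rt must be > 0; violated at row %d (rt = %g)",
                               bad[1], df$rt[bad[1]]))
  } else if (require_rt) {
    abort_schema("missing required column(s): rt")
  }
  if (!all(df$response %in% c(0, 1)))
    abort_validation(sprintf("response must be 0 or 1; violated at row %d",
                             which(!df$response %in% c(0, 1))[1]))
  if (!is.numeric(df$subj_idx) || any(df$subj_idx < 0) ||
      any(df$subj_idx != round(df$subj_idx)))
    abort_validation("subj_idx must be non-negative integers")
  if (!is.numeric(df$feedback)) abort_validation("feedback must be numeric")
  if (!is.numeric(df$q_init)) abort_validation("q_init must be numeric")
  # q_init constant within each subject-by-condition block
  key <- paste(df$subj_idx, df$split_by, sep = "\r")
  q_by_block <- tapply(df$q_init, key, function(x) length(unique(x)))
  if (any(q_by_block > 1)) {
    bad_key <- names(q_by_block)[q_by_block > 1][1]
    parts <- strsplit(bad_key, "\r", fixed = TRUE)[[1]]
    abort_validation(sprintf(
      "q_init must be constant within a subject-by-condition block (subject %s, condition %s)",
      parts[1], parts[2]))
  }
  # heterogeneous q_init across conditions of one subject: allowed, flagged
  q_by_subj <- tapply(df$q_init, df$subj_idx, function(x) length(unique(x)))
  if (any(q_by_subj > 1))
    warning(sprintf("q_init differs across conditions for subject(s): %s",
                    paste(names(q_by_subj)[q_by_subj > 1], collapse = ", ")),
            call. = FALSE)
  # canonical storage types: real-valued columns as doubles, ids as integers
  for (col in intersect(c("rt", "feedback", "q_init"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  df$response <- as.integer(df$response)
  df$subj_idx <- as.integer(df$subj_idx)
  structure(df, class = c("trial_table", "data.frame"),
            has_rt = "rt" %in% names(df))
}

#' Confirm that regressor columns exist and are numeric
#'
#' @param table A `trial_table`.
#' @param terms Non-empty character vector of covariate names. Interaction
#'   terms (`"x:y"`) are decomposed into their components; the reserved latent
#'   name `"conflict"` is skipped (it is computed from the model, not read
#'   from the data).
#' @return The table, unchanged.
#' @export
validate_regressor_columns <- function(table, terms) {
  if (length(terms) == 0) abort_precondition("terms must be non-empty")
  vars <- setdiff(unique(unlist(strsplit(terms, ":", fixed = TRUE))), "conflict")
  for (v in vars) {
    if (!v %in% names(table))
      abort_schema(sprintf("regressor column '%s' not found in data", v))
    col <- table[[v]]
    if (!is.numeric(col))
      abort_validation(sprintf("regressor column '%s' is not numeric", v))
    if (anyNA(col))
      abort_validation(sprintf("regressor column '%s' has a missing value at row %d",
                               v, which(is.na(col))[1]))
  }
  table
}

#' Write a trial table to disk
#'
#' Writes in the same CSV/TSV dialect that [load_trials()] reads, preserving
#' row order and full double precision, so that a write/load round trip
#' reproduces the records exactly.
#'
#' @param table A `trial_table` (or plain data frame).
#' @param path Output file path.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(table, path, sep = ",") {
  if (!sep %in% c(",", "\t")) abort_domain("sep must be ',' or a tab")
  out <- as.data.frame(table)
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Integer block index (subject-by-condition, in order of first appearance).
block_index <- function(df) {
  key <- paste(df$subj_idx, df$split_by, sep = "\r")
  match(key, unique(key))
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("trial_table: %d trials, %d subject(s), %d condition(s)%s\n",
              nrow(x), length(unique(x$subj_idx)),
              length(unique(x$split_by)),
              if (isTRUE(attr(x, "has_rt"))) "" else " (no rt column)"))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
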