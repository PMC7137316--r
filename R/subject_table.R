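# Canonical column order for the subject-level data layout.
SUBJECT_COLS <- c("id", "x1", "x2", "u1", "u2", "y1", "y2", "pi1", "pi2",
                  "in_survey", "in_ehr", "linked", "w1", "w2")

#' Subject-level table for the union of the two samples
#'
#' A data frame holding one row per subject in the survey, the record
#' source, or both. Columns:
#'
#' * `id` — subject identifier;
#' * `x1` (binary), `x2` (real) — outcome-model covariates;
#' * `u1` (binary), `u2` (real) — sampling design factors;
#' * `y1` — gold-standard outcome, present iff `in_survey`;
#' * `y2` — record-source outcome, present iff `in_ehr`;
#' * `pi1`, `pi2` — inclusion probabilities where known;
#' * `in_survey`, `in_ehr`, `linked` — membership flags (`linked` implies
#'   both memberships);
#' * `w1`, `w2` — survey and post-stratified record-source weights.
#'
#' `subject_table()` validates the structural invariants and returns the
#' data frame with class `subject_table` prepended.
#'
#' @param df A data frame with the columns above (missing values as `NA`).
#' @return A validated `subject_table`.
#' @export
subject_table <- function(df) {
  missing_cols <- setdiff(SUBJECT_COLS, names(df))
  if (length(missing_cols)) {
    stop("subject table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, SUBJECT_COLS]
  for (fl in c("in_survey", "in_ehr", "linked")) {
    df[[fl]] <- as.logical(df[[fl]])
    if (any(is.na(df[[fl]]))) stop("flag column '", fl, "' contains NA")
  }
  validate_subject_table(df)
  class(df) <- c("subject_table", "data.frame")
  df
}

validate_subject_table <- function(df) {
  bad <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx)) {
      stop(msg, " (subject ids: ",
           paste(head(df$id[idx], 5L), collapse = ", "),
           if (length(idx) > 5L) ", ..." else "", ")", call. = FALSE)
    }
  }
  bad(df$linked & !(df$in_survey & df$in_ehr),
      "linked subjects must be in both sources")
  bad(df$in_survey & (is.na(df$y1) | is.na(df$w1)),
      "survey subjects must have y1 and w1")
  bad(!df$in_survey & !is.na(df$y1),
      "y1 must be missing outside the survey")
  bad(df$in_ehr & is.na(df$y2), "record-source subjects must have y2")
  bad(!df$in_ehr & !is.na(df$y2),
      "y2 must be missing outside the record source")
  bad(!is.na(df$y1) & !df$y1 %in% c(0, 1), "y1 must be binary 0/1")
  bad(!is.na(df$y2) & !df$y2 %in% c(0, 1), "y2 must be binary 0/1")
  bad(!is.na(df$w1) & df$w1 < 0, "weights w1 must be nonnegative")
  bad(!is.na(df$w2) & df$w2 < 0, "weights w2 must be nonnegative")
  bad(!is.na(df$pi1) & (df$pi1 <= 0 | df$pi1 >= 1),
      "inclusion probabilities pi1 must lie in (0, 1)")
  bad(!is.na(df$pi2) & (df$pi2 <= 0 | df$pi2 >= 1),
      "inclusion probabilities pi2 must lie in (0, 1)")
  invisible(df)
}

#' @export
print.subject_table <- function(x, ...) {
  cat(sprintf(
    "<subject_table> %d subjects: %d survey, %d record-source, %d linked\n",
    nrow(x), sum(x$in_survey), sum(x$in_ehr), sum(x$linked)))
  NextMethod()
}

#' Read / write a subject table as CSV
#'
#' The on-disk layout has header exactly
#' `id,x1,x2,u1,u2,y1,y2,pi1,pi2,in_survey,in_ehr,linked,w1,w2`, missing
#' values as empty fields and flags as 0/1.
#'
#' @param path File path.
#' @return `read_subject_table()` returns a validated [subject_table()];
#'   `write_subject_table()` returns `path` invisibly.
#' @export
read_subject_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!identical(names(df), SUBJECT_COLS)) {
    stop("subject table CSV must have header exactly '",
         paste(SUBJECT_COLS, collapse = ","), "'; got '",
         paste(names(df), collapse = ","), "' in ", path)
  }
  # an all-empty column reads back as logical NA; keep the schema numeric
  for (cl in setdiff(SUBJECT_COLS, c("id", "in_survey", "in_ehr", "linked"))) {
    df[[cl]] <- as.numeric(df[[cl]])
  }
  subject_table(df)
}

#' @param t A [subject_table()].
#' @rdname read_subject_table
#' @export
write_subject_table <- function(t, path) {
  out <- as.data.frame(t)
  for (fl in c("in_survey", "in_ehr", "linked")) out[[fl]] <- as.integer(out[[fl]])
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
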