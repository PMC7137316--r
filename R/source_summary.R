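#' One source's published prevalence summary
#'
#' Container for the aggregate-mode input: a prevalence estimate with its
#' 95% confidence interval on the probability scale, as printed in a report
#' or paper, plus an optional sample size kept for display.
#'
#' @param label Short name of the source (e.g. `"survey"`, `"ehr"`).
#' @param p_hat Point estimate, in (0, 1).
#' @param ci_lower,ci_upper Confidence-interval endpoints in (0, 1)
#'   bracketing `p_hat`.
#' @param n Optional positive integer sample size (informational only).
#' @return An object of class `source_summary`.
#' @examples
#' source_summary("survey", 0.190, 0.166, 0.216, n = 1135)
#' @export
source_summary <- function(label, p_hat, ci_lower, ci_upper, n = NA_integer_) {
  stopifnot(is.character(label), length(label) == 1L)
  for (v in c(p_hat = p_hat, ci_lower = ci_lower, ci_upper = ci_upper)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1) {
      stop("source_summary proportions must be single values in (0, 1)")
    }
  }
  if (!(ci_lower <= p_hat && p_hat <= ci_upper)) {
    stop("source_summary requires ci_lower <= p_hat <= ci_upper; got (",
         ci_lower, ", ", p_hat, ", ", ci_upper, ")")
  }
  if (!is.na(n) && (n != round(n) || n <= 0)) stop("n must be a positive integer")
  structure(
    list(label = label, p_hat = p_hat, ci_lower = ci_lower,
         ci_upper = ci_upper, n = as.integer(n)),
    class = "source_summary"
  )
}

#' @export
print.source_summary <- function(x, ...) {
  cat(sprintf("<source_summary> %s: %.1f%% (95%% CI %.1f, %.1f)%s\n",
              x$label, 100 * x$p_hat, 100 * x$ci_lower, 100 * x$ci_upper,
              if (is.na(x$n)) "" else sprintf(", n = %d", x$n)))
  invisible(x)
}

#' Read source summaries from CSV
#'
#' Expects the header `label,p_hat,ci_lower,ci_upper,n` with proportions as
#' decimals in (0, 1); `n` may be empty.
#'
#' @param path Path to a CSV file.
#' @return A list of [source_summary()] objects, one per row.
#' @export
read_source_summaries <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("label", "p_hat", "ci_lower", "ci_upper", "n")
  if (!identical(names(df), need)) {
    stop("source summary CSV must have header exactly '",
         paste(need, collapse = ","), "'; got '",
         paste(names(df), collapse = ","), "' in ", path)
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tryCatch(
      source_summary(row$label, row$p_hat, row$ci_lower, row$ci_upper,
                     if (is.na(row$n)) NA_integer_ else row$n),
      error = function(e) stop("row ", i, " of ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  })
}

#' Write source summaries to CSV
#'
#' @param summaries A list of [source_summary()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_source_summaries <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(label = s$label, p_hat = s$p_hat, ci_lower = s$ci_lower,
               ci_upper = s$ci_upper, n = s$n)
  }))
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
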