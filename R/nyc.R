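#' Packaged NYC aggregate fixture
#'
#' Returns the published prevalence estimates and 95% CIs for six adult
#' health indicators in New York City from the gold-standard examination
#' survey (NYC HANES 2013-14) and the post-stratified EHR surveillance
#' system (NYC Macroscope 2013), as a named list of
#' `(survey, ehr)` [source_summary()] pairs.
#'
#' @return A named list, one element per indicator.
#' @export
nyc_table4 <- function() {
  path <- system.file("extdata", "nyc_table4.csv", package = "prevpool",
                      mustWork = TRUE)
  rows <- read_source_summaries(path)
  labs <- vapply(rows, `[[`, "", "label")
  indicators <- unique(sub("_(survey|ehr)$", "", labs))
  out <- lapply(indicators, function(ind) {
    list(survey = rows[[which(labs == paste0(ind, "_survey"))]],
         ehr = rows[[which(labs == paste0(ind, "_ehr"))]])
  })
  names(out) <- indicators
  out
}

# Indicators whose printed inputs are rounded coarsely enough that the
# pooled estimate's last printed digit can shift.
NYC_ROUNDING_SENSITIVE <- c("diabetes", "smoking", "obesity")

#' Pooled estimates for the six NYC indicators
#'
#' Runs the Mosteller pooling on each packaged indicator pair and returns
#' (and prints) a table of pooled estimates, 95% credibility intervals and
#' relative source weights. Indicators where the coarse rounding of the
#' printed inputs can shift the last displayed digit are flagged.
#'
#' @param quiet Suppress printing (default `FALSE`).
#' @return A data frame, invisibly when printed.
#' @export
nyc_demo <- function(quiet = FALSE) {
  pairs <- nyc_table4()
  rows <- lapply(names(pairs), function(ind) {
    e <- pool(pairs[[ind]]$survey, pairs[[ind]]$ehr)
    data.frame(
      indicator = ind,
      survey_pct = 100 * pairs[[ind]]$survey$p_hat,
      ehr_pct = 100 * pairs[[ind]]$ehr$p_hat,
      pooled_pct = round(100 * e$p_hat, 1),
      ci_lower_pct = round(100 * e$ci_prob[[1]], 1),
      ci_upper_pct = round(100 * e$ci_prob[[2]], 1),
      weight_survey = round(e$rel_weights[[1]], 3),
      weight_ehr = round(e$rel_weights[[2]], 3),
      input_rounding_sensitive = ind %in% NYC_ROUNDING_SENSITIVE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!quiet) {
    cat("Pooled prevalence for six NYC health indicators (percent):\n")
    print(out, row.names = FALSE)
    cat("input_rounding_sensitive: printed-input rounding may shift the",
        "last digit\n")
  }
  invisible(out)
}
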