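#' Mosteller pooled prevalence estimator
#'
#' Pools a gold-standard survey estimate with a potentially biased
#' record-source estimate on the log-odds scale. With `y1 = logit(p1)`,
#' `y2 = logit(p2)`, logit-scale standard errors `sigma1`, `sigma2` and the
#' squared estimated bias `tau2 = (y1 - y2)^2`, the pooled log-odds is the
#' precision-weighted average
#' \deqn{\hat\phi = (k_1 y_1 + k_2 y_2) / (k_1 + k_2),\quad
#'       k_1 = 1/\sigma_1^2,\ k_2 = 1/(\tau^2 + \sigma_2^2),}
#' which minimises MSE in this family and equals the posterior mean under a
#' flat prior on the true log-odds and a zero-mean normal prior with
#' variance `tau2` on the bias of the second source. The biased source is
#' thus discounted exactly by how far it disagrees with the gold standard.
#'
#' Standard errors default to [se_logit_from_ci()] applied to the printed
#' intervals; explicit logit-scale SEs (e.g. design-based ones from
#' microdata) take precedence when supplied.
#'
#' @param survey,ehr [source_summary()] objects for the gold-standard and
#'   the record source.
#' @param se_survey,se_ehr Optional explicit logit-scale standard errors
#'   overriding the CI-derived ones.
#' @param level Level of the reported credibility interval (default 0.95).
#' @return A `pooled_estimate` with components `y1`, `y2`, `sigma1`,
#'   `sigma2`, `tau2`, `k1`, `k2`, `phi_hat`, `post_sd`, `ci_logit`,
#'   `p_hat`, `ci_prob`, and `rel_weights` (survey, record source; sum 1).
#' @examples
#' s <- source_summary("survey", 0.190, 0.166, 0.216, 1135)
#' e <- source_summary("ehr", 0.083, 0.083, 0.084, 716076)
#' pool(s, e)  # pooled estimate 18.9%
#' @export
pool <- function(survey, ehr, se_survey = NULL, se_ehr = NULL, level = 0.95) {
  stopifnot(inherits(survey, "source_summary"), inherits(ehr, "source_summary"))
  y1 <- logit(survey$p_hat)
  y2 <- logit(ehr$p_hat)
  sigma1 <- if (is.null(se_survey)) se_logit_from_ci(survey) else se_survey
  sigma2 <- if (is.null(se_ehr)) se_logit_from_ci(ehr) else se_ehr
  if (!is.finite(y1) || !is.finite(y2)) stop("non-finite logit estimate")
  if (sigma1 <= 0 || sigma2 <= 0) stop("standard errors must be positive")
  pool_logit(y1, y2, sigma1, sigma2, level = level)
}

# Core pooling arithmetic on the logit scale; shared by aggregate-mode and
# subject-level front ends.
pool_logit <- function(y1, y2, sigma1, sigma2, level = 0.95) {
  tau2 <- (y1 - y2)^2
  k1 <- 1 / sigma1^2
  k2 <- 1 / (tau2 + sigma2^2)
  phi_hat <- (k1 * y1 + k2 * y2) / (k1 + k2)
  post_sd <- sigma1 * sqrt((sigma2^2 + tau2) / (sigma1^2 + sigma2^2 + tau2))
  e <- structure(
    list(y1 = y1, y2 = y2, sigma1 = sigma1, sigma2 = sigma2,
         tau2 = tau2, k1 = k1, k2 = k2, phi_hat = phi_hat,
         post_sd = post_sd, p_hat = expit(phi_hat),
         rel_weights = c(survey = k1, ehr = k2) / (k1 + k2),
         level = level),
    class = "pooled_estimate"
  )
  ci <- credibility_interval(e, level)
  e$ci_prob <- ci
  e$ci_logit <- logit(ci)
  e
}

#' Credibility interval of a pooled estimate
#'
#' The posterior of the true log-odds is normal with mean `phi_hat` and
#' standard deviation
#' \eqn{\sigma_1\sqrt{(\sigma_2^2+\tau^2)/(\sigma_1^2+\sigma_2^2+\tau^2)}};
#' the highest-density interval is `phi_hat` plus/minus the normal quantile
#' times that SD, back-transformed to the probability scale.
#'
#' @param e A `pooled_estimate` from [pool()].
#' @param level Credibility level in (0, 1).
#' @return Ordered probability-scale endpoints `(lower, upper)`.
#' @export
credibility_interval <- function(e, level = 0.95) {
  stopifnot(inherits(e, "pooled_estimate"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)")
  }
  z <- qnorm(1 - (1 - level) / 2)
  ci <- expit(e$phi_hat + c(-1, 1) * z * e$post_sd)
  names(ci) <- c("lower", "upper")
  ci
}

#' Pool directly from subject-level data
#'
#' Convenience composition: computes the weighted prevalence and its
#' delta-method logit-scale SE separately for the survey rows (weights
#' `w1`) and the record-source rows (weights `w2`) of a subject table,
#' then applies [pool()]'s arithmetic.
#'
#' @param t A [subject_table()] with at least two subjects and weights in
#'   each source.
#' @param level Credibility level (default 0.95).
#' @return A `pooled_estimate`.
#' @export
pool_from_subject_tables <- function(t, level = 0.95) {
  stopifnot(inherits(t, "subject_table"))
  sv <- t[t$in_survey, ]
  eh <- t[t$in_ehr, ]
  if (nrow(sv) < 2L || nrow(eh) < 2L) {
    stop("need at least two subjects with weights in each source")
  }
  if (any(is.na(eh$w2))) stop("record-source rows must carry weights w2")
  p1 <- weighted_prevalence(sv$y1, sv$w1)
  p2 <- weighted_prevalence(eh$y2, eh$w2)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    stop("all-0 or all-1 outcomes in a source; logit undefined")
  }
  pool_logit(logit(p1), logit(p2),
             weighted_prevalence_se_logit(sv$y1, sv$w1),
             weighted_prevalence_se_logit(eh$y2, eh$w2),
             level = level)
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat("<pooled_estimate>\n")
  cat(sprintf("  pooled prevalence: %.1f%% (%.0f%% CrI %.1f, %.1f)\n",
              100 * x$p_hat, 100 * x$level,
              100 * x$ci_prob[1], 100 * x$ci_prob[2]))
  cat(sprintf("  relative weights (survey : record source): %.3f : %.3f\n",
              x$rel_weights[1], x$rel_weights[2]))
  cat(sprintf("  tau^2 = %.4g, posterior SD (logit) = %.4g\n",
              x$tau2, x$post_sd))
  invisible(x)
}

# Flat named list of all numeric fields, for JSON reports.
pooled_estimate_fields <- function(e) {
  list(y1 = e$y1, y2 = e$y2, sigma1 = e$sigma1, sigma2 = e$sigma2,
       tau2 = e$tau2, k1 = e$k1, k2 = e$k2, phi_hat = e$phi_hat,
       post_sd = e$post_sd, p_hat = e$p_hat,
       ci_logit = unname(e$ci_logit), ci_prob = unname(e$ci_prob),
       rel_weight_survey = unname(e$rel_weights[1]),
       rel_weight_ehr = unname(e$rel_weights[2]))
}
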