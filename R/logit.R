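#' Logit and inverse-logit
#'
#' `logit(p)` returns `log(p / (1 - p))`; `expit(x)` is its inverse.
#' Both are vectorised. `logit` rejects values outside the open unit
#' interval rather than returning infinities, because downstream pooling
#' weights require finite log-odds.
#'
#' @param p Proportions, all strictly between 0 and 1.
#' @param x Real values.
#' @return A numeric vector of the same length as the input.
#' @examples
#' logit(0.5)          # 0
#' expit(logit(0.3))   # 0.3
#' @export
logit <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    bad <- p[!is.numeric(p) | !is.finite(p) | p <= 0 | p >= 1][1]
    stop("logit() requires values in (0, 1); got ", format(bad))
  }
  qlogis(p)
}

#' @rdname logit
#' @export
expit <- function(x) plogis(x)

#' Recover a logit-scale standard error from a printed confidence interval
#'
#' Published prevalence tables usually report an estimate and a 95% CI but
#' not a standard error. Interpreting the interval as symmetric on the
#' log-odds scale, the SE of the logit estimate is half the logit-scale
#' interval width divided by the normal quantile.
#'
#' @param s A [source_summary()] (or anything with `ci_lower`/`ci_upper`
#'   components in (0, 1)).
#' @param level Confidence level the interval was built at (default 0.95).
#' @return The positive logit-scale standard error.
#' @examples
#' s <- source_summary("survey", 0.486, 0.454, 0.518)
#' se_logit_from_ci(s)  # ~0.0654
#' @export
se_logit_from_ci <- function(s, level = 0.95) {
  lo <- s$ci_lower
  hi <- s$ci_upper
  if (!is.numeric(lo) || !is.numeric(hi) || lo <= 0 || hi >= 1) {
    stop("se_logit_from_ci() needs CI endpoints in (0, 1)")
  }
  if (lo >= hi) {
    stop("degenerate confidence interval (lower >= upper); ",
         "supply a standard error directly via the se arguments of pool()")
  }
  z <- qnorm(1 - (1 - level) / 2)
  (logit(hi) - logit(lo)) / (2 * z)
}

#' Survey-weighted prevalence
#'
#' The Horvitz-Thompson-style ratio estimator
#' \eqn{\hat p = \sum_i w_i y_i / \sum_i w_i}, design-unbiased for the
#' population prevalence when `w` are valid design weights. Invariant under
#' rescaling all weights by a positive constant.
#'
#' @param y Binary 0/1 outcome vector.
#' @param w Nonnegative weights, same length as `y`, summing to a positive
#'   value.
#' @return The weighted prevalence, in `[0, 1]`.
#' @examples
#' weighted_prevalence(c(1, 0), c(1, 3))  # 0.25
#' @export
weighted_prevalence <- function(y, w) {
  if (length(y) != length(w)) {
    stop("y and w must have the same length (got ", length(y), " and ",
         length(w), ")")
  }
  if (any(is.na(y)) || any(is.na(w))) stop("y and w must not contain NA")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (any(w < 0)) stop("weights must be nonnegative")
  sw <- sum(w)
  if (sw <= 0) stop("weights sum to zero; weighted prevalence undefined")
  sum(w * y) / sw
}

# Delta-method logit-scale SE of a weighted prevalence (ratio estimator).
# var(p-hat) ~= sum(w^2 (y - p)^2) / (sum w)^2; divide by p(1-p) for logit.
weighted_prevalence_se_logit <- function(y, w) {
  p <- weighted_prevalence(y, w)
  if (p <= 0 || p >= 1) {
    stop("weighted prevalence is exactly ", p,
         "; logit-scale SE undefined (all outcomes identical)")
  }
  v <- sum(w^2 * (y - p)^2) / sum(w)^2
  sqrt(v) / (p * (1 - p))
}

# Kish effective sample size of a weight vector.
kish_neff <- function(w) sum(w)^2 / sum(w^2)
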