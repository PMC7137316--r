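#' Combine multiply-imputed logit estimates (Rubin's rules)
#'
#' Given the M per-imputation logit-scale point estimates and their naive
#' standard errors, computes the total variance
#' `T = W + (1 + 1/M) B` (W = mean within-imputation variance, B =
#' between-imputation variance with divisor M - 1), and the Barnard-Rubin
#' small-sample degrees of freedom
#' \deqn{\nu = \left(\frac{1}{\nu_M} + \frac{1}{\nu_{obs}}\right)^{-1},\quad
#'  \nu_M = \frac{M-1}{\lambda^2},\
#'  \nu_{obs} = \frac{\nu_{com}+1}{\nu_{com}+3}\,\nu_{com}(1-\lambda),}
#' with \eqn{\lambda = (1 + 1/M) B / T} the fraction of missing
#' information. The interval uses the t quantile at those df.
#'
#' @param phi_m Numeric vector of M per-imputation logit estimates (M >= 2).
#' @param s_m Their naive logit-scale standard errors (same length).
#' @param nu_com Complete-data degrees of freedom (e.g. effective sample
#'   size minus one).
#' @param level Interval level (default 0.95).
#' @return A list with `se`, `df`, `ci_logit`, plus components `W`,
#'   `B_between`, `T`, `lambda`, and the pooled mean `phi_bar`.
#' @examples
#' rubin_combine(c(0, 1), c(1, 1), nu_com = 100)
#' @export
rubin_combine <- function(phi_m, s_m, nu_com, level = 0.95) {
  M <- length(phi_m)
  if (M < 2L) stop("need at least M = 2 imputations")
  if (length(s_m) != M) stop("phi_m and s_m must have the same length")
  if (any(!is.finite(phi_m)) || any(!is.finite(s_m)) || any(s_m < 0)) {
    stop("estimates must be finite and SEs nonnegative")
  }
  if (nu_com <= 0) stop("nu_com must be positive")
  W <- mean(s_m^2)
  B <- var(phi_m)
  Tot <- W + (1 + 1 / M) * B
  if (Tot == 0) stop("no variance information: all s_m zero and all phi_m equal")
  lambda <- (1 + 1 / M) * B / Tot
  nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
  df <- if (lambda == 0) nu_obs else {
    nu_M <- (M - 1) / lambda^2
    1 / (1 / nu_M + 1 / nu_obs)
  }
  se <- sqrt(Tot)
  phi_bar <- mean(phi_m)
  tq <- qt(1 - (1 - level) / 2, df)
  list(se = se, df = df,
       ci_logit = c(phi_bar - tq * se, phi_bar + tq * se),
       W = W, B_between = B, T = Tot, lambda = lambda, phi_bar = phi_bar)
}
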