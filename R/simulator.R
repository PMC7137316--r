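#' Generative parameters for the two-source simulation
#'
#' Describes a target population with correlated, possibly misclassified
#' binary outcomes and the unequal-probability designs of the two samples
#' drawn from it. The two outcomes follow conditional logistic models
#' `logit P(Y1 = 1 | Y2) = eta10 + phi * Y2` and
#' `logit P(Y2 = 1 | Y1) = eta01 + phi * Y1`, with linear predictors
#' `eta10 = gamma0 + gamma1*x1 + gamma2*x2` and
#' `eta01 = beta0 + beta1*x1 + beta2*x2` over covariates
#' `x1 ~ Bernoulli(0.5)` and `x2 ~ N(0, 1)`. Intercepts are calibrated so
#' the marginal prevalences hit `target_p1` and `target_p2` (see
#' [calibrate_intercepts()]); `NA` intercepts mean "calibrate for me".
#'
#' Sampling: survey and record-source inclusion are proportional to
#' `plogis(a0 + a1*u1 + a2*u2 + a3*x1)` (and `b` likewise), with
#' independent design factors `u1 ~ Bernoulli(0.5)`, `u2 ~ N(0, 1)`.
#' Because `x1` appears in both the outcome and the inclusion models, the
#' induced missingness is missing-at-random but not completely at random.
#'
#' @param N Population size (default 1e7; scalable).
#' @param phi Log odds ratio between the two outcomes (default 1.5).
#' @param gamma,beta Length-3 coefficient vectors `(intercept, x1, x2)` of
#'   the two conditional models; `NA` intercepts are calibrated. Default
#'   slopes 0.3.
#' @param target_p1,target_p2 Marginal prevalences of `y1` and `y2`.
#' @param a,b Length-4 inclusion coefficient vectors
#'   `(intercept, u1, u2, x1)`; default `(1, 1, 1, 0.187)` for both.
#' @param n1,n2 Survey and record-source sample sizes (defaults 500 and
#'   1e5).
#' @param overlap Fraction of survey subjects that must also be in the
#'   record source, in (0, 1] (default 1).
#' @param seed Base seed; replicate r of an experiment uses `seed + r`.
#' @return A validated `generative_params` list.
#' @export
generative_params <- function(N = 1e7, phi = 1.5,
                              gamma = c(NA, 0.3, 0.3),
                              beta = c(NA, 0.3, 0.3),
                              target_p1 = 0.30, target_p2 = 0.30,
                              a = c(1, 1, 1, 0.187),
                              b = c(1, 1, 1, 0.187),
                              n1 = 500L, n2 = 1e5, overlap = 1.0,
                              seed = 1L) {
  stopifnot(length(gamma) == 3L, length(beta) == 3L,
            length(a) == 4L, length(b) == 4L)
  if (N < 1000) stop("N must be at least 1000 (quartile cells unstable below)")
  for (p in c(target_p1, target_p2)) {
    if (p <= 0 || p >= 1) stop("target prevalences must be in (0, 1)")
  }
  if (overlap <= 0 || overlap > 1) stop("overlap must be in (0, 1]")
  if (n1 < 2 || n2 < 2) stop("sample sizes must be at least 2")
  structure(
    list(N = N, phi = phi, gamma = gamma, beta = beta,
         target_p1 = target_p1, target_p2 = target_p2, a = a, b = b,
         n1 = as.integer(n1), n2 = as.integer(n2), overlap = overlap,
         seed = as.integer(seed)),
    class = "generative_params"
  )
}

#' Joint probabilities of two correlated binary outcomes
#'
#' Given the conditional linear predictors `eta10`, `eta01` and the log
#' odds ratio `phi`, the joint cell probabilities are proportional to
#' `(p11 : p10 : p01 : p00) = (exp(phi + eta10 + eta01) : exp(eta10) :
#' exp(eta01) : 1)`; this parameterisation makes both conditional
#' distributions exactly the logistic models
#' `logit P(Y1 = 1 | Y2 = y) = eta10 + phi*y` and
#' `logit P(Y2 = 1 | Y1 = y) = eta01 + phi*y`. Computed with max
#' subtraction, so arbitrarily large inputs are safe.
#'
#' @param eta10,eta01 Linear predictors (vectorised).
#' @param phi Log odds ratio (scalar or vectorised).
#' @return For scalar inputs, a named vector `(p00, p01, p10, p11)`;
#'   otherwise a matrix with those columns, one row per input.
#' @examples
#' joint_probs(0, 0, 0)  # all cells 0.25
#' @export
joint_probs <- function(eta10, eta01, phi) {
  if (any(!is.finite(eta10)) || any(!is.finite(eta01)) || any(!is.finite(phi))) {
    stop("joint_probs requires finite inputs")
  }
  l <- cbind(p00 = 0, p01 = eta01, p10 = eta10, p11 = phi + eta10 + eta01)
  mx <- l[cbind(seq_len(nrow(l)), max.col(l))]
  e <- exp(l - mx)
  out <- e / rowSums(e)
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Calibrate the outcome-model intercepts to target prevalences
#'
#' Solves the two-dimensional root problem `E[P(Y1 = 1 | x)] = target_p1`,
#' `E[P(Y2 = 1 | x)] = target_p2` in the intercepts `(gamma0, beta0)`,
#' where the expectation is an exact sum over `x1` in `{0, 1}` and
#' Gauss-Hermite quadrature over `x2 ~ N(0, 1)`. Newton iterations with a
#' finite-difference Jacobian; residuals below 1e-8 required.
#'
#' @param params A [generative_params()].
#' @return Named vector `c(gamma0, beta0)`.
#' @export
calibrate_intercepts <- function(params) {
  gh <- pracma::gaussHermite(40)
  x2 <- sqrt(2) * gh$x
  wq <- gh$w / sqrt(pi)
  g <- params$gamma
  b <- params$beta
  phi <- params$phi

  marginals <- function(g0, b0) {
    p1 <- p2 <- 0
    for (x1 in c(0, 1)) {
      eta10 <- g0 + g[2] * x1 + g[3] * x2
      eta01 <- b0 + b[2] * x1 + b[3] * x2
      jp <- joint_probs(eta10, eta01, phi)
      if (is.null(dim(jp))) jp <- matrix(jp, nrow = 1)
      p1 <- p1 + 0.5 * sum(wq * (jp[, "p11"] + jp[, "p10"]))
      p2 <- p2 + 0.5 * sum(wq * (jp[, "p11"] + jp[, "p01"]))
    }
    c(p1, p2)
  }
  resid <- function(v) marginals(v[1], v[2]) - c(params$target_p1, params$target_p2)

  # damped Newton with finite-difference Jacobian; the step is halved until
  # the residual norm decreases, which keeps strongly associated outcomes
  # (large |phi|, where the system is stiff) on track
  v <- c(logit(params$target_p1) - max(phi, 0) / 2,
         logit(params$target_p2) - max(phi, 0) / 2)
  r <- resid(v)
  for (iter in 1:200) {
    if (max(abs(r)) < 1e-10) break
    h <- 1e-6
    J <- cbind((resid(v + c(h, 0)) - r) / h, (resid(v + c(0, h)) - r) / h)
    step <- tryCatch(solve(J, r), error = function(e) r)
    ok <- FALSE
    for (d in 0:40) {
      v_new <- v - step / 2^d
      r_new <- resid(v_new)
      if (sum(r_new^2) < sum(r^2)) { ok <- TRUE; break }
    }
    if (!ok) break
    v <- v_new
    r <- r_new
    if (any(abs(v) > 50)) {
      stop("no intercept solution in [-50, 50]; targets (",
           params$target_p1, ", ", params$target_p2,
           ") unattainable with these slopes")
    }
  }
  if (max(abs(resid(v))) > 1e-8) stop("intercept calibration did not converge")
  c(gamma0 = v[1], beta0 = v[2])
}

# Fill NA intercepts in a generative_params by calibration.
resolve_params <- function(params) {
  if (is.na(params$gamma[1]) || is.na(params$beta[1])) {
    ic <- calibrate_intercepts(params)
    params$gamma[1] <- ic[["gamma0"]]
    params$beta[1] <- ic[["beta0"]]
  }
  params
}

#' Draw a target population
#'
#' Generates `N` subjects with independent `x1 ~ Bernoulli(0.5)`,
#' `x2 ~ N(0, 1)`, design factors `u1 ~ Bernoulli(0.5)`, `u2 ~ N(0, 1)`,
#' and correlated outcomes `(y1, y2)` from [joint_probs()] evaluated at
#' each subject's covariates.
#'
#' @param params A [generative_params()] with calibrated (non-`NA`)
#'   intercepts.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A data frame with columns `id, x1, x2, u1, u2, y1, y2`.
#' @export
draw_population <- function(params, seed = params$seed) {
  if (is.na(params$gamma[1]) || is.na(params$beta[1])) {
    stop("intercepts not calibrated; call calibrate_intercepts() first ",
         "(or leave it to run_experiment)")
  }
  if (params$N < 1000) stop("N must be at least 1000")
  if (!is.null(seed)) set.seed(seed)
  N <- params$N
  x1 <- rbinom(N, 1L, 0.5)
  x2 <- rnorm(N)
  u1 <- rbinom(N, 1L, 0.5)
  u2 <- rnorm(N)
  g <- params$gamma
  b <- params$beta
  eta10 <- g[1] + g[2] * x1 + g[3] * x2
  eta01 <- b[1] + b[2] * x1 + b[3] * x2
  # joint cell draw via one uniform against cumulative (p11, p10, p01, p00)
  l11 <- params$phi + eta10 + eta01
  mx <- pmax(l11, eta10, eta01, 0)
  e11 <- exp(l11 - mx); e10 <- exp(eta10 - mx)
  e01 <- exp(eta01 - mx); e00 <- exp(-mx)
  tot <- e11 + e10 + e01 + e00
  c1 <- e11 / tot
  c2 <- c1 + e10 / tot
  c3 <- c2 + e01 / tot
  r <- runif(N)
  y1 <- as.integer(r < c2)
  y2 <- as.integer(r < c1 | (r >= c2 & r < c3))
  data.frame(id = seq_len(N), x1 = x1, x2 = x2, u1 = u1, u2 = u2,
             y1 = y1, y2 = y2)
}

# Fixed-size unequal-probability sample: sequential Poisson selection of n
# units with inclusion probability approximately proportional to size s.
seq_poisson_sample <- function(s, n) {
  xi <- runif(length(s)) / s
  th <- sort(xi, partial = n)[n]
  idx <- which(xi <= th)
  if (length(idx) > n) idx <- idx[seq_len(n)] # ties (measure zero)
  idx
}

# Post-stratification cells u1 x quartile(u2) x x1; breaks from population.
ps_cells <- function(u1, u2, x1, breaks) {
  bin <- cut(u2, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  paste(u1, bin, x1, sep = ".")
}

#' Draw the two overlapping study samples from a population
#'
#' The survey is a fixed-size sequential Poisson sample of `n1` subjects
#' with size measure `plogis(a0 + a1*u1 + a2*u2 + a3*x1)`; the record
#' source is drawn analogously with `b` and size `n2`. Additional
#' record-source members are then drawn uniformly among the not-yet-included
#' survey participants until the linked fraction reaches `overlap`.
#' Finally the unobservable fields are deleted: `y1` and `pi1` outside the
#' survey, `y2` outside the record source, and `pi2` everywhere. Survey
#' weights are `w1 = 1/pi1`; post-stratified weights `w2` are computed for
#' record-source subjects from the cells `u1 x quartile(u2) x x1` against
#' the realised population distribution.
#'
#' @param pop A population from [draw_population()].
#' @param params The same [generative_params()].
#' @param compute_w2 Compute post-stratified weights (default `TRUE`).
#' @return A [subject_table()] containing the union of the two samples.
#' @export
sample_sources <- function(pop, params, compute_w2 = TRUE) {
  N <- nrow(pop)
  if (params$n2 > N || params$n1 > N) stop("requested sample exceeds N")
  s1 <- plogis(params$a[1] + params$a[2] * pop$u1 + params$a[3] * pop$u2 +
                 params$a[4] * pop$x1)
  pi1 <- params$n1 * s1 / sum(s1)
  if (any(pi1 >= 1)) stop("survey inclusion probabilities reach 1; ",
                          "n1 too large for this design")
  s2 <- plogis(params$b[1] + params$b[2] * pop$u1 + params$b[3] * pop$u2 +
                 params$b[4] * pop$x1)
  pi2 <- params$n2 * s2 / sum(s2)
  if (any(pi2 >= 1)) stop("record-source inclusion probabilities reach 1; ",
                          "n2 too large for this design")

  S1 <- seq_poisson_sample(s1, params$n1)
  in_ehr_flag <- logical(N)
  in_ehr_flag[seq_poisson_sample(s2, params$n2)] <- TRUE

  n12_target <- round(params$overlap * params$n1)
  cur <- sum(in_ehr_flag[S1])
  if (cur < n12_target) {
    candidates <- S1[!in_ehr_flag[S1]]
    extra <- if (length(candidates) == 1L) candidates else {
      sample(candidates, n12_target - cur)
    }
    in_ehr_flag[extra] <- TRUE
  }
  S2 <- which(in_ehr_flag)

  ids <- sort(unique(c(S1, S2)))
  in_survey <- ids %in% S1
  in_ehr <- in_ehr_flag[ids]
  tab <- data.frame(
    id = ids,
    x1 = pop$x1[ids], x2 = pop$x2[ids],
    u1 = pop$u1[ids], u2 = pop$u2[ids],
    y1 = ifelse(in_survey, pop$y1[ids], NA_integer_),
    y2 = ifelse(in_ehr, pop$y2[ids], NA_integer_),
    pi1 = ifelse(in_survey, pi1[ids], NA_real_),
    pi2 = NA_real_, # unknown in a typical record source
    in_survey = in_survey, in_ehr = in_ehr,
    linked = in_survey & in_ehr,
    w1 = ifelse(in_survey, 1 / pi1[ids], NA_real_),
    w2 = NA_real_
  )
  if (compute_w2) {
    breaks <- quantile(pop$u2, probs = 0:4 / 4, names = FALSE)
    breaks[1] <- -Inf
    breaks[5] <- Inf
    pop_cells <- ps_cells(pop$u1, pop$u2, pop$x1, breaks)
    shares <- table(pop_cells) / N
    shares <- stats::setNames(as.numeric(shares), names(shares))
    ehr_rows <- which(tab$in_ehr)
    cells <- ps_cells(tab$u1[ehr_rows], tab$u2[ehr_rows], tab$x1[ehr_rows],
                      breaks)
    tab$w2[ehr_rows] <- post_stratify(cells, shares)
  }
  subject_table(tab)
}
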