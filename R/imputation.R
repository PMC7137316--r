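#' Configuration for the subject-level imputation estimator
#'
#' @param covariates_z Column names of the misclassification-model
#'   predictor vector z (default `c("x1", "x2")`).
#' @param design_factors_u Columns driving the survey-inclusion model
#'   (default `c("u1", "u2", "x1")`).
#' @param design_factors_v Columns driving the record-source inclusion
#'   model (default the same).
#' @param M Number of multiple imputations (default 30).
#' @param B Full-sample iterations per imputation after the initial
#'   restricted pass (default 10).
#' @param prior_scale Cauchy prior scale for all coefficients (default 2.5).
#' @param seed Root seed; imputation m uses substream `seed + m` so the M
#'   imputations are order-independent.
#' @param ci_level Interval level (default 0.95).
#' @return An `imputation_config` list.
#' @export
imputation_config <- function(covariates_z = c("x1", "x2"),
                              design_factors_u = c("u1", "u2", "x1"),
                              design_factors_v = c("u1", "u2", "x1"),
                              M = 30L, B = 10L, prior_scale = 2.5,
                              seed = 1L, ci_level = 0.95) {
  if (M < 2L) stop("M must be at least 2")
  if (B < 1L) stop("B must be at least 1")
  if (prior_scale <= 0) stop("prior_scale must be positive")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  structure(
    list(covariates_z = covariates_z, design_factors_u = design_factors_u,
         design_factors_v = design_factors_v, M = as.integer(M),
         B = as.integer(B), prior_scale = prior_scale,
         seed = as.integer(seed), ci_level = ci_level),
    class = "imputation_config"
  )
}

#' Model the survey-inclusion probability for record-source subjects
#'
#' Survey-inclusion probabilities are known (by design) for survey subjects
#' but unknown for the rest of the record source. A weighted logistic
#' regression of the survey-membership indicator on the survey design
#' factors, fitted over the record-source subjects with their
#' post-stratified weights `w2`, supplies predictions. Predicted values are
#' anchored to the known design probabilities by shifting the predicted
#' logits so they agree on average with the known values, and known values
#' always take precedence over predictions.
#'
#' @param t A [subject_table()] whose record-source rows carry `w2`.
#' @param cfg An [imputation_config()].
#' @return A list with `coef` (fitted coefficients) and `pi1` (probability
#'   for every subject in `t`).
#' @export
fit_inclusion_survey <- function(t, cfg) {
  eh <- t$in_ehr
  known <- !is.na(t$pi1)
  if (!any(t$linked) && !any(known)) {
    stop("no linked subjects and no known survey-inclusion probabilities: ",
         "the survey-inclusion model cannot be anchored")
  }
  if (!any(t$linked)) {
    stop("no linked subjects: survey membership has no variation among ",
         "record-source subjects")
  }
  df <- as.data.frame(t)[eh, c("in_survey", cfg$design_factors_u, "w2")]
  if (any(is.na(df$w2))) stop("record-source rows must carry weights w2")
  fml <- stats::reformulate(cfg$design_factors_u, response = "in_survey")
  fit <- glm(fml, family = quasibinomial(), data = df, weights = df$w2)
  if (any(fitted(fit) > 1 - 1e-8)) {
    warning("survey-inclusion model fitted probabilities at the boundary ",
            "(are all record-source subjects in the survey?)")
  }
  eta <- unname(predict(fit, newdata = as.data.frame(t), type = "link"))
  anchor <- which(known)
  shift <- mean(qlogis(t$pi1[anchor])) - mean(eta[anchor])
  pi1 <- plogis(eta + shift)
  pi1[anchor] <- t$pi1[anchor]
  list(coef = coef(fit), pi1 = pmin(pmax(pi1, 1e-12), 1 - 1e-12))
}

#' Model the record-source inclusion probability for survey subjects
#'
#' Fits a weighted logistic regression (survey weights `w1`) of the
#' record-source membership indicator — known for survey subjects through
#' linkage — on the design factors, over the survey subjects, and predicts
#' the inclusion probability for every subject. Known `pi2` values, when
#' present, take precedence.
#'
#' @inheritParams fit_inclusion_survey
#' @return A list with `coef` and `pi2` (probability for every subject).
#' @export
fit_inclusion_ehr <- function(t, cfg) {
  sv <- t$in_survey
  y <- t$in_ehr[sv]
  if (all(y) || !any(y)) {
    stop("record-source membership among survey subjects is all-",
         if (all(y)) "1 (complete overlap)" else "0 (no overlap)",
         "; inclusion model has no variation")
  }
  df <- as.data.frame(t)[sv, c("in_ehr", cfg$design_factors_v, "w1")]
  fml <- stats::reformulate(cfg$design_factors_v, response = "in_ehr")
  fit <- glm(fml, family = quasibinomial(), data = df, weights = df$w1)
  pi2 <- unname(predict(fit, newdata = as.data.frame(t), type = "response"))
  known <- !is.na(t$pi2)
  pi2[known] <- t$pi2[known]
  list(coef = coef(fit), pi2 = pmin(pmax(pi2, 1e-12), 1 - 1e-12))
}

#' Stratify subjects by quartiles of an inclusion probability
#'
#' The misclassification models are fitted separately within four strata
#' cut at the empirical quartiles of the relevant inclusion probability,
#' carrying the design information into otherwise unweighted fits. Bins are
#' right-closed with the minimum in stratum 1. Heavily tied probabilities
#' collapse to fewer strata with a warning.
#'
#' @param pi Probability vector, no missing values, length at least 8.
#' @return Integer stratum labels in `1:4`.
#' @export
assign_strata <- function(pi) {
  if (any(is.na(pi))) stop("pi must have no missing values (predict first)")
  if (length(pi) < 8L) stop("need at least 8 subjects to form strata")
  breaks <- unique(quantile(pi, probs = 0:4 / 4, names = FALSE))
  if (length(breaks) < 2L) {
    warning("all inclusion probabilities equal; stratification collapses ",
            "to a single stratum")
    return(rep(1L, length(pi)))
  }
  lab <- as.integer(cut(pi, breaks = breaks, include.lowest = TRUE,
                        labels = FALSE))
  if (length(breaks) < 5L) {
    warning("ties reduce the stratification to ", length(breaks) - 1L,
            " strata")
  }
  lab
}

# Fit one stratified misclassification model and impute the missing rows of
# `target` in place. `cond` is the conditioning outcome column (complete on
# all rows used). Returns list(values, draws) where draws is a per-stratum
# coefficient list.
impute_pass <- function(target, cond, Zmat, strata, train_idx, fill_idx,
                        prior_scale, pass_label, check_first = FALSE) {
  out <- target
  draws <- list()
  for (l in sort(unique(strata))) {
    in_l <- strata == l
    tr <- train_idx & in_l
    if (check_first) {
      if (sum(tr) < 10L) {
        stop("stratum ", l, " has only ", sum(tr), " training subjects in ",
             pass_label, "; reduce the number of strata")
      }
      if (length(unique(target[tr])) < 2L) {
        stop("single-class outcome in stratum ", l, " during ", pass_label,
             "; reduce the number of strata")
      }
    }
    X <- cbind(Zmat, cond = cond)
    b <- bayes_logistic_fit(X[tr, , drop = FALSE], target[tr],
                            prior_scale = prior_scale)
    draws[[as.character(l)]] <- b
    fi <- which(fill_idx & in_l)
    if (length(fi)) {
      eta <- b[1L] + drop(X[fi, , drop = FALSE] %*% b[-1L])
      out[fi] <- rbinom(length(fi), 1L, plogis(eta))
    }
  }
  list(values = out, draws = draws)
}

#' Subject-level iterative Bayesian multiple-imputation estimator
#'
#' Estimates the gold-standard prevalence from the full record source by
#' multiply imputing the gold-standard outcome `y1` for record-source
#' subjects who were not surveyed, using the linked subsample to identify
#' the misclassification between the two outcome measurements.
#'
#' Each of the M imputations runs an iterative chain of two stratified
#' Bayesian logistic models with Cauchy(0, `prior_scale`) priors:
#'
#' 1. model M1 (`y2 ~ z + y1`), stratified by quartiles of the
#'    record-source inclusion probability, fitted first on the linked
#'    subjects only, then used to draw the missing `y2` of survey-only
#'    subjects;
#' 2. model M2 (`y1 ~ z + y2`), stratified by quartiles of the survey
#'    inclusion probability, fitted first on the subjects with observed
#'    `y1`, then used to draw the missing `y1` of record-source subjects;
#' 3. steps 1-2 are repeated B more times on the full pooled sample,
#'    treating the latest imputations as observed.
#'
#' Observed outcomes are never overwritten. Imputation m yields the
#' `w2`-weighted prevalence of the completed `y1` over the record source
#' and its naive logit-scale SE; the M results are combined with
#' [rubin_combine()] (Barnard-Rubin degrees of freedom, complete-data df
#' set to the Kish effective record-source sample size minus one).
#'
#' @param t A [subject_table()] with a nonempty linked subset and `w2` on
#'   record-source rows.
#' @param cfg An [imputation_config()].
#' @return An `imputation_result` with per-imputation `p_m`, `s_m`, the
#'   combined `P_R`, `phi_R`, `se_phi`, `df`, `ci_prob`, variance
#'   components `W` and `B_between`, per-stratum coefficient draws and
#'   convergence diagnostics.
#' @export
run_imputation <- function(t, cfg) {
  stopifnot(inherits(t, "subject_table"), inherits(cfg, "imputation_config"))
  if (!any(t$linked)) stop("linked subset is empty; the misclassification ",
                           "models are unidentified")
  obs1 <- !is.na(t$y1)
  obs2 <- !is.na(t$y2)
  eh <- t$in_ehr
  w2 <- t$w2[eh]
  if (any(is.na(w2))) stop("record-source rows must carry weights w2")

  nothing_missing <- all(obs1) && all(obs2)

  inc1 <- fit_inclusion_survey(t, cfg)
  if (all(t$in_ehr[t$in_survey])) {
    # Complete overlap: record-source membership has no variation among
    # survey subjects, so the inclusion model is unidentified. The
    # post-stratified weight is inversely proportional to the inclusion
    # propensity within cells, so quartiles of 1/w2 (every subject has w2
    # here, S1 being a subset of S2) carry the same stratification.
    proxy <- 1 / t$w2
    inc2 <- list(coef = NULL, pi2 = proxy / (max(proxy) * (1 + 1e-9)))
  } else {
    inc2 <- fit_inclusion_ehr(t, cfg)
  }
  strata_m1 <- assign_strata(inc2$pi2)  # M1 stratified by record-source inclusion
  strata_m2 <- assign_strata(inc1$pi1)  # M2 stratified by survey inclusion

  Zmat <- as.matrix(as.data.frame(t)[, cfg$covariates_z, drop = FALSE])
  storage.mode(Zmat) <- "double"

  p_m <- s_m <- numeric(cfg$M)
  coef_draws <- vector("list", cfg$M)
  traj <- matrix(NA_real_, nrow = cfg$M, ncol = cfg$B)
  y1_obs <- t$y1
  y2_obs <- t$y2

  for (m in seq_len(cfg$M)) {
    set.seed(cfg$seed + m)
    y1w <- y1_obs
    y2w <- y2_obs
    if (!nothing_missing) {
      # initial restricted pass: M1 on linked subjects, M2 on observed y1.
      # A pass with nothing to impute (e.g. y2 complete at full overlap)
      # is skipped: its draws would influence nothing.
      p1 <- list(draws = NULL)
      if (any(!obs2)) {
        p1 <- impute_pass(y2w, y1w, Zmat, strata_m1, train_idx = t$linked,
                          fill_idx = !obs2, prior_scale = cfg$prior_scale,
                          pass_label = "the first M1 pass", check_first = TRUE)
        y2w <- p1$values
      }
      p2 <- impute_pass(y1w, y2w, Zmat, strata_m2, train_idx = obs1,
                        fill_idx = !obs1, prior_scale = cfg$prior_scale,
                        pass_label = "the first M2 pass", check_first = TRUE)
      y1w <- p2$values
      all_rows <- rep(TRUE, nrow(t))
      for (b in seq_len(cfg$B)) {
        if (any(!obs2)) {
          p1 <- impute_pass(y2w, y1w, Zmat, strata_m1, train_idx = all_rows,
                            fill_idx = !obs2, prior_scale = cfg$prior_scale,
                            pass_label = sprintf("M1 iteration %d", b))
          y2w <- p1$values
        }
        p2 <- impute_pass(y1w, y2w, Zmat, strata_m2, train_idx = all_rows,
                          fill_idx = !obs1, prior_scale = cfg$prior_scale,
                          pass_label = sprintf("M2 iteration %d", b))
        y1w <- p2$values
        traj[m, b] <- weighted_prevalence(y1w[eh], w2)
      }
      coef_draws[[m]] <- list(M1 = p1$draws, M2 = p2$draws)
      # observed values must survive every pass untouched
      stopifnot(identical(y1w[obs1], y1_obs[obs1]),
                identical(y2w[obs2], y2_obs[obs2]))
    }
    p_m[m] <- weighted_prevalence(y1w[eh], w2)
    s_m[m] <- weighted_prevalence_se_logit(y1w[eh], w2)
  }

  not_settled <- 0L
  if (!nothing_missing && cfg$B >= 3L) {
    last3 <- traj[, (cfg$B - 2L):cfg$B, drop = FALSE]
    rng <- apply(last3, 1L, function(z) diff(range(z)))
    not_settled <- sum(rng >= 0.002)
    if (not_settled > 0L) {
      warning(not_settled, " of ", cfg$M, " imputation chains moved by ",
              ">= 0.002 over the last 3 iterations; consider a larger B")
    }
  }

  nu_com <- max(kish_neff(w2) - 1, 1)
  comb <- rubin_combine(logit(p_m), s_m, nu_com = nu_com, level = cfg$ci_level)
  P_R <- mean(p_m)
  phi_R <- logit(P_R)
  tq <- qt(1 - (1 - cfg$ci_level) / 2, comb$df)
  ci_logit <- c(phi_R - tq * comb$se, phi_R + tq * comb$se)
  structure(
    list(p_m = p_m, s_m = s_m, P_R = P_R, phi_R = phi_R,
         se_phi = comb$se, df = comb$df,
         ci_logit = ci_logit, ci_prob = expit(ci_logit),
         W = comb$W, B_between = comb$B_between, lambda = comb$lambda,
         nu_com = nu_com, M = cfg$M, B = cfg$B,
         strata_m1 = strata_m1, strata_m2 = strata_m2,
         inclusion_coefs = list(survey = inc1$coef, ehr = inc2$coef),
         coef_draws = coef_draws, trajectory = traj,
         chains_not_settled = not_settled, seed = cfg$seed),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("<imputation_result>\n")
  cat(sprintf("  P_R = %.4f (%.1f%%), SE(logit) = %.4f, df = %.1f\n",
              x$P_R, 100 * x$P_R, x$se_phi, x$df))
  cat(sprintf("  95%% CrI (probability): (%.4f, %.4f)\n",
              x$ci_prob[1], x$ci_prob[2]))
  cat(sprintf("  M = %d imputations, B = %d iterations, W = %.3g, B_between = %.3g\n",
              x$M, x$B, x$W, x$B_between))
  invisible(x)
}

#' Cross-validated AUC of the misclassification model
#'
#' Diagnostic for whether the available predictors can actually model the
#' misclassification: k-fold cross-validated AUC of model M2 (observed
#' `y1` from z and `y2`) on the linked subjects, per survey-inclusion
#' stratum. Folds are assigned stratified by outcome so both classes
#' appear in each training fold; a stratum whose folds still degenerate is
#' reported as `NA`.
#'
#' @param t A [subject_table()].
#' @param cfg An [imputation_config()].
#' @param folds Number of folds (default 5).
#' @return Named numeric vector of AUCs, one per stratum.
#' @export
cv_auc_misclassification <- function(t, cfg, folds = 5L) {
  linked <- which(t$linked)
  if (length(linked) < 5L * folds) {
    stop("need at least ", 5L * folds, " linked subjects for ", folds,
         "-fold cross-validation")
  }
  inc1 <- fit_inclusion_survey(t, cfg)
  strata <- assign_strata(inc1$pi1)[linked]
  Z <- as.matrix(as.data.frame(t)[linked, cfg$covariates_z, drop = FALSE])
  X <- cbind(Z, y2 = t$y2[linked])
  y <- t$y1[linked]
  vapply(sort(unique(strata)), function(l) {
    idx <- which(strata == l)
    if (length(idx) < 2L * folds) return(NA_real_)
    yl <- y[idx]
    if (length(unique(yl)) < 2L) return(NA_real_)
    # outcome-stratified fold assignment
    fold <- integer(length(idx))
    for (cls in unique(yl)) {
      ci <- which(yl == cls)
      fold[ci] <- sample(rep_len(seq_len(folds), length(ci)))
    }
    pred <- rep(NA_real_, length(idx))
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (length(unique(yl[tr])) < 2L) next
      b <- bayes_logistic_fit(X[idx[tr], , drop = FALSE], yl[tr],
                              prior_scale = cfg$prior_scale, draw = FALSE)
      eta <- b[1L] + drop(X[idx[!tr], , drop = FALSE] %*% b[-1L])
      pred[!tr] <- plogis(eta)
    }
    keep <- !is.na(pred)
    if (length(unique(yl[keep])) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(yl[keep], pred[keep], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1), USE.NAMES = FALSE) -> aucs
  names(aucs) <- paste0("stratum", sort(unique(strata)))
  aucs
}
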