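#' Run a replicated two-source simulation experiment
#'
#' For each replicate: draw a fresh target population (or reuse a fixed
#' one), draw the overlapping survey and record-source samples, compute
#' post-stratified weights, and evaluate the selected prevalence
#' estimators. Summaries report the mean estimate and the root mean
#' squared error against the true prevalence `target_p1`.
#'
#' Replicate r uses seed `params$seed + r`, recorded in the output, so
#' individual replicates can be reproduced in isolation. An estimator that
#' fails in a replicate is recorded as `NA` and counted, never silently
#' dropped.
#'
#' @param params A [generative_params()] (intercepts calibrated here if
#'   left `NA`).
#' @param replicates Number of replicates (at least 2).
#' @param imputation_cfg An [imputation_config()]; required when
#'   `"imputation"` is among the estimators. Its seed is re-derived per
#'   replicate.
#' @param estimators Subset of
#'   `c("survey", "ehr", "mosteller", "imputation")`.
#' @param fresh_population Draw a new population each replicate (default
#'   `TRUE`); `FALSE` holds one population fixed and redraws samples only.
#' @return An `experiment_result` with `replicates` (one row per
#'   replicate: estimates and naive probability-scale SEs) and `summary`
#'   (per estimator: `mean_estimate`, `sqrt_mse`, `n_used`, `n_failed`).
#' @export
run_experiment <- function(params, replicates,
                           imputation_cfg = NULL,
                           estimators = c("survey", "ehr", "mosteller"),
                           fresh_population = TRUE) {
  stopifnot(inherits(params, "generative_params"))
  if (replicates < 2L) stop("need at least 2 replicates")
  estimators <- match.arg(estimators,
                          c("survey", "ehr", "mosteller", "imputation"),
                          several.ok = TRUE)
  if ("imputation" %in% estimators && is.null(imputation_cfg)) {
    stop("imputation estimator requested but no imputation_cfg supplied")
  }
  params <- resolve_params(params)
  need_ehr <- any(estimators %in% c("ehr", "mosteller", "imputation"))

  pop <- NULL
  if (!fresh_population) pop <- draw_population(params, seed = params$seed)

  rows <- vector("list", replicates)
  errors <- character(0)
  for (r in seq_len(replicates)) {
    rseed <- params$seed + r
    set.seed(rseed)
    if (fresh_population) pop <- draw_population(params, seed = NULL)
    est <- c(survey = NA_real_, ehr = NA_real_, mosteller = NA_real_,
             imputation = NA_real_)
    se <- est
    res <- tryCatch({
      if (need_ehr) {
        tab <- sample_sources(pop, params, compute_w2 = TRUE)
      } else {
        tab <- sample_sources_survey_only(pop, params)
      }
      sv <- tab[tab$in_survey, ]
      if ("survey" %in% estimators) {
        p <- weighted_prevalence(sv$y1, sv$w1)
        est["survey"] <- p
        se["survey"] <- weighted_prevalence_se_logit(sv$y1, sv$w1) * p * (1 - p)
      }
      if ("ehr" %in% estimators) {
        eh <- tab[tab$in_ehr, ]
        p <- weighted_prevalence(eh$y2, eh$w2)
        est["ehr"] <- p
        se["ehr"] <- weighted_prevalence_se_logit(eh$y2, eh$w2) * p * (1 - p)
      }
      if ("mosteller" %in% estimators) {
        pe <- pool_from_subject_tables(tab)
        est["mosteller"] <- pe$p_hat
        se["mosteller"] <- pe$post_sd * pe$p_hat * (1 - pe$p_hat)
      }
      if ("imputation" %in% estimators) {
        cfg <- imputation_cfg
        cfg$seed <- params$seed + 7919L * r
        ir <- suppressWarnings(run_imputation(tab, cfg))
        est["imputation"] <- ir$P_R
        se["imputation"] <- ir$se_phi * ir$P_R * (1 - ir$P_R)
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors <- c(errors, sprintf("replicate %d: %s", r, res))
    rows[[r]] <- data.frame(replicate = r, seed = rseed,
                            survey = est[["survey"]], survey_se = se[["survey"]],
                            ehr = est[["ehr"]], ehr_se = se[["ehr"]],
                            mosteller = est[["mosteller"]],
                            mosteller_se = se[["mosteller"]],
                            imputation = est[["imputation"]],
                            imputation_se = se[["imputation"]])
  }
  reps <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(estimators, function(nm) {
    x <- reps[[nm]]
    ok <- !is.na(x)
    data.frame(estimator = nm,
               mean_estimate = mean(x[ok]),
               sqrt_mse = sqrt(mean((x[ok] - params$target_p1)^2)),
               n_used = sum(ok), n_failed = sum(!ok))
  }))
  structure(
    list(replicates = reps, summary = smry, params = params,
         estimators = estimators, errors = errors,
         fresh_population = fresh_population),
    class = "experiment_result"
  )
}

# Survey-only sampling path (skips record-source draw and weights).
sample_sources_survey_only <- function(pop, params) {
  s1 <- plogis(params$a[1] + params$a[2] * pop$u1 + params$a[3] * pop$u2 +
                 params$a[4] * pop$x1)
  pi1 <- params$n1 * s1 / sum(s1)
  S1 <- seq_poisson_sample(s1, params$n1)
  tab <- data.frame(
    id = S1, x1 = pop$x1[S1], x2 = pop$x2[S1],
    u1 = pop$u1[S1], u2 = pop$u2[S1],
    y1 = pop$y1[S1], y2 = NA_integer_,
    pi1 = pi1[S1], pi2 = NA_real_,
    in_survey = TRUE, in_ehr = FALSE, linked = FALSE,
    w1 = 1 / pi1[S1], w2 = NA_real_
  )
  subject_table(tab)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d replicates (N = %s, n1 = %d, n2 = %s, p1 = %.2f, p2 = %.2f)\n",
              nrow(x$replicates), format(x$params$N, big.mark = ","),
              x$params$n1, format(x$params$n2, big.mark = ","),
              x$params$target_p1, x$params$target_p2))
  print(x$summary, row.names = FALSE)
  if (length(x$errors)) {
    cat(length(x$errors), "replicate-level failures recorded\n")
  }
  invisible(x)
}
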