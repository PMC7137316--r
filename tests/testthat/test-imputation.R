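test_that("stratum assignment follows quartiles with sane tie handling", {
  expect_identical(assign_strata(seq(0.1, 0.8, by = 0.1)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_warning(lab <- assign_strata(rep(0.3, 20)), "single stratum")
  expect_identical(lab, rep(1L, 20))
  set.seed(9)
  lab <- assign_strata(runif(10000))
  expect_identical(as.integer(table(lab)), rep(2500L, 4))
  expect_error(assign_strata(runif(5)), "at least 8")
})

test_that("Cauchy-prior logistic posterior mode concentrates at the MLE", {
  set.seed(21)
  # intercept-only, large n
  y <- rbinom(10000, 1, 0.3)
  b <- bayes_logistic_fit(matrix(numeric(0), nrow = 10000, ncol = 0), y,
                          draw = FALSE)
  expect_lt(abs(b[["intercept"]] - logit(mean(y))), 0.05)
  # slope recovery
  x <- matrix(rnorm(20000), ncol = 1, dimnames = list(NULL, "x"))
  y <- rbinom(20000, 1, plogis(-0.5 + 1.0 * x))
  b <- bayes_logistic_fit(x, y, draw = FALSE)
  expect_lt(abs(b[["x"]] - 1.0), 3 * 0.02) # analytic SE ~0.02 at this n
})

test_that("the Cauchy prior keeps separated fits finite", {
  set.seed(2)
  x <- matrix(rnorm(200), ncol = 1)
  y <- as.integer(x > 0)
  b <- bayes_logistic_fit(x, y, draw = FALSE)
  expect_true(all(is.finite(b)))
  expect_true(all(abs(b) < 50))
})

test_that("posterior draws are reproducible and centred at the mode", {
  set.seed(33)
  x <- matrix(rnorm(1000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(500, 1, plogis(x %*% c(1, -1)))
  set.seed(4); d1 <- bayes_logistic_fit(x, y)
  set.seed(4); d2 <- bayes_logistic_fit(x, y)
  expect_identical(d1, d2)
  set.seed(5)
  draws <- t(replicate(300, bayes_logistic_fit(x, y)))
  mode <- attr(d1, "mode")
  expect_equal(unname(colMeans(draws)), unname(mode), tolerance = 0.1)
})

test_that("Rubin combination matches a textbook transcription to 1e-10", {
  # independent oracle: literal step-by-step Rubin / Barnard-Rubin formulas
  oracle <- function(q, u, k) {
    m <- length(q)
    qbar <- sum(q) / m
    ubar <- sum(u^2) / m
    bvar <- sum((q - qbar)^2) / (m - 1)
    tvar <- ubar + (1 + 1 / m) * bvar
    gamma <- (1 + 1 / m) * bvar / tvar
    nu_old <- (m - 1) / gamma^2
    nu_obs <- ((k + 1) / (k + 3)) * k * (1 - gamma)
    list(se = sqrt(tvar), df = (nu_old * nu_obs) / (nu_old + nu_obs))
  }
  set.seed(14)
  for (i in 1:25) {
    M <- sample(2:40, 1)
    phi <- rnorm(M)
    s <- runif(M, 0.01, 1)
    nu_com <- runif(1, 5, 5000)
    got <- rubin_combine(phi, s, nu_com)
    want <- oracle(phi, s, nu_com)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
  }
  # worked arithmetic
  got <- rubin_combine(c(0, 1), c(1, 1), nu_com = 100)
  expect_equal(got$W, 1)
  expect_equal(got$B_between, 0.5)
  expect_equal(got$se, 1.32287565553, tolerance = 1e-10)
  # degenerate: no between-imputation variance
  same <- rubin_combine(rep(0.2, 5), rep(0.1, 5), nu_com = 50)
  expect_equal(same$se, 0.1, tolerance = 1e-12)
  expect_equal(same$df, (51 / 53) * 50, tolerance = 1e-10)
  expect_error(rubin_combine(rep(1, 3), rep(0, 3), 10), "no variance")
})

test_that("inclusion models recover the design and respect known values", {
  # record source covering a fifth of the population, so most of the
  # overlap arises naturally through the inclusion model (the uniform
  # top-up to the target overlap carries no design signal)
  st <- small_study(N = 5e4, n1 = 1000, n2 = 2e4, overlap = 0.5, seed = 71)
  cfg <- imputation_config(M = 2, B = 1)
  inc1 <- fit_inclusion_survey(st$tab, cfg)
  # known design pi1 take precedence for survey subjects
  sv <- which(st$tab$in_survey)
  expect_identical(inc1$pi1[sv], st$tab$pi1[sv])
  expect_true(all(inc1$pi1 > 0 & inc1$pi1 < 1))

  inc2 <- fit_inclusion_ehr(st$tab, cfg)
  # predicted pi2 ranks like the true design inclusion probabilities
  p <- st$params
  s2 <- plogis(p$b[1] + p$b[2] * st$tab$u1 + p$b[3] * st$tab$u2 +
                 p$b[4] * st$tab$x1)
  expect_gt(cor(inc2$pi2, s2, method = "spearman"), 0.5)

  # constant design factors: every prediction equal
  cfg_const <- imputation_config(design_factors_u = "const",
                                 design_factors_v = "const")
  tab2 <- st$tab
  tab2$const <- 1
  suppressWarnings({
    i1 <- fit_inclusion_survey(tab2, cfg_const)
    i2 <- fit_inclusion_ehr(tab2, cfg_const)
  })
  ehr_only <- which(!tab2$in_survey)
  expect_lt(diff(range(i1$pi1[ehr_only])), 1e-12)
  expect_lt(diff(range(i2$pi2)), 1e-12)
})

test_that("inclusion-to-record model rejects degenerate overlap", {
  full <- small_study(N = 5e4, n1 = 200, n2 = 2000, overlap = 1.0, seed = 81)
  cfg <- imputation_config()
  expect_error(fit_inclusion_ehr(full$tab, cfg), "complete overlap")
  part <- small_study(N = 5e4, n1 = 300, n2 = 2500, overlap = 0.5, seed = 55)
  none <- as.data.frame(part$tab)
  sv <- none$in_survey
  none$linked[sv] <- FALSE
  none$in_ehr[sv] <- FALSE
  none$y2[sv] <- NA
  expect_error(fit_inclusion_ehr(subject_table(none), cfg), "no overlap")
})

test_that("imputation passes never touch observed outcomes", {
  st <- small_study(N = 5e4, n1 = 300, n2 = 2500, overlap = 0.5, seed = 55)
  tab <- st$tab
  obs2 <- !is.na(tab$y2)
  Z <- as.matrix(as.data.frame(tab)[, c("x1", "x2")])
  strata <- rep(1:4, length.out = nrow(tab))
  y1full <- ifelse(is.na(tab$y1), 0, tab$y1) # conditioning column, complete
  set.seed(6)
  res <- prevpool:::impute_pass(tab$y2, y1full, Z, strata,
                                train_idx = obs2, fill_idx = !obs2,
                                prior_scale = 2.5, pass_label = "test")
  expect_identical(res$values[obs2], tab$y2[obs2])
  expect_true(all(!is.na(res$values)))
})

test_that("with nothing missing the estimator returns the weighted prevalence", {
  n <- 600
  set.seed(12)
  y2 <- rbinom(n, 1, 0.4)
  y1 <- ifelse(runif(n) < 0.85, y2, 1 - y2)
  tab <- linked_table(n, y1, y2)
  for (M in c(2, 5)) {
    cfg <- imputation_config(M = M, B = 3, seed = 99)
    res <- suppressWarnings(run_imputation(tab, cfg))
    expect_identical(res$P_R, weighted_prevalence(y1, rep(1, n)))
    expect_true(all(res$p_m == res$P_R))
  }
})

test_that("run_imputation is reproducible and satisfies its variance identity", {
  st <- small_study(N = 5e4, n1 = 300, n2 = 2500, overlap = 0.5, seed = 55)
  cfg <- imputation_config(M = 4, B = 3, seed = 17)
  r1 <- suppressWarnings(run_imputation(st$tab, cfg))
  r2 <- suppressWarnings(run_imputation(st$tab, cfg))
  expect_identical(r1$p_m, r2$p_m)
  expect_identical(r1$se_phi, r2$se_phi)
  expect_equal(r1$P_R, mean(r1$p_m), tolerance = 1e-15)
  expect_equal(r1$se_phi^2, r1$W + (1 + 1 / cfg$M) * r1$B_between,
               tolerance = 1e-12)
  expect_gte(r1$se_phi, sqrt(r1$W))
  expect_error(run_imputation(st$tab, "nope"))
})

test_that("strong concordance between sources pins the estimate to the record source", {
  # phi = 6 gives ~96% agreement while keeping enough discordant linked
  # pairs to identify the misclassification model without separation
  params <- generative_params(N = 5e4, n1 = 1000, n2 = 5000, overlap = 1.0,
                              target_p1 = 0.30, target_p2 = 0.30,
                              phi = 6, seed = 31)
  params <- prevpool:::resolve_params(params)
  pop <- draw_population(params)
  expect_gt(mean(pop$y1 == pop$y2), 0.95)
  tab <- sample_sources(pop, params)
  cfg <- imputation_config(M = 6, B = 3, seed = 7)
  res <- suppressWarnings(run_imputation(tab, cfg))
  ehr <- tab[tab$in_ehr, ]
  p2_hat <- weighted_prevalence(ehr$y2, ehr$w2)
  expect_lt(abs(res$P_R - p2_hat), 0.025)
})

test_that("cross-validated AUC separates null from deterministic misclassification", {
  n <- 2000
  set.seed(77)
  y2 <- rbinom(n, 1, 0.4)
  cfg <- imputation_config(M = 2, B = 1, seed = 3)
  # outcome independent of everything: AUC ~ 0.5
  tab_null <- linked_table(n, y1 = rbinom(n, 1, 0.3), y2 = y2, seed = 78)
  set.seed(10)
  auc_null <- suppressWarnings(cv_auc_misclassification(tab_null, cfg, 5))
  expect_true(all(abs(auc_null - 0.5) < 0.05 | is.na(auc_null)))
  # outcome equal to the record outcome: AUC ~ 1
  tab_det <- linked_table(n, y1 = y2, y2 = y2, seed = 79)
  set.seed(10)
  auc_det <- suppressWarnings(cv_auc_misclassification(tab_det, cfg, 5))
  expect_true(all(auc_det > 0.95, na.rm = TRUE))
  # smoke: simulator misclassification is between the two, reproducibly
  st <- small_study(N = 5e4, n1 = 300, n2 = 2500, overlap = 0.5, seed = 55)
  set.seed(10)
  a1 <- suppressWarnings(cv_auc_misclassification(st$tab, cfg, 4))
  set.seed(10)
  a2 <- suppressWarnings(cv_auc_misclassification(st$tab, cfg, 4))
  expect_identical(a1, a2)
  expect_true(all(a1 > 0.5 & a1 < 1, na.rm = TRUE))
})
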