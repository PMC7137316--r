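test_that("joint probabilities encode the conditional logistic models exactly", {
  expect_equal(unname(joint_probs(0, 0, 0)), rep(0.25, 4), tolerance = 1e-15)
  # phi = 0: independence
  jp <- joint_probs(1.3, -0.4, 0)
  expect_equal(jp[["p11"]],
               (jp[["p11"]] + jp[["p10"]]) * (jp[["p11"]] + jp[["p01"]]),
               tolerance = 1e-12)
  # conditional-logit identity on random parameters
  set.seed(19)
  for (i in 1:200) {
    eta10 <- rnorm(1, 0, 3); eta01 <- rnorm(1, 0, 3); phi <- rnorm(1, 0, 2)
    jp <- joint_probs(eta10, eta01, phi)
    expect_equal(sum(jp), 1, tolerance = 1e-12)
    # logit P(Y1 = 1 | Y2 = y) = eta10 + phi * y
    expect_equal(logit(jp[["p11"]] / (jp[["p11"]] + jp[["p01"]])),
                 eta10 + phi, tolerance = 1e-12)
    expect_equal(logit(jp[["p10"]] / (jp[["p10"]] + jp[["p00"]])),
                 eta10, tolerance = 1e-12)
    # logit P(Y2 = 1 | Y1 = y) = eta01 + phi * y
    expect_equal(logit(jp[["p11"]] / (jp[["p11"]] + jp[["p10"]])),
                 eta01 + phi, tolerance = 1e-12)
    expect_equal(logit(jp[["p01"]] / (jp[["p01"]] + jp[["p00"]])),
                 eta01, tolerance = 1e-12)
  }
  # overflow safety
  big <- joint_probs(600, 600, 100)
  expect_true(all(is.finite(big)) && abs(sum(big) - 1) < 1e-12)
  expect_error(joint_probs(Inf, 0, 0), "finite")
})

test_that("intercept calibration hits the target marginals", {
  sym <- generative_params(N = 1e4, target_p1 = 0.3, target_p2 = 0.3)
  ic <- calibrate_intercepts(sym)
  expect_equal(ic[["gamma0"]], ic[["beta0"]], tolerance = 1e-8)
  asym <- generative_params(N = 1e4, target_p1 = 0.30, target_p2 = 0.35)
  ic2 <- calibrate_intercepts(asym)
  expect_gt(ic2[["beta0"]], ic2[["gamma0"]])
  # Monte-Carlo validation of the quadrature
  params <- prevpool:::resolve_params(
    generative_params(N = 5e5, target_p1 = 0.30, target_p2 = 0.35, seed = 13))
  pop <- draw_population(params)
  tol1 <- 3 * sqrt(0.30 * 0.70 / params$N)
  tol2 <- 3 * sqrt(0.35 * 0.65 / params$N)
  expect_lt(abs(mean(pop$y1) - 0.30), tol1)
  expect_lt(abs(mean(pop$y2) - 0.35), tol2)
})

test_that("population draws are reproducible and honour the concordance limit", {
  params <- prevpool:::resolve_params(
    generative_params(N = 2e4, seed = 44))
  p1 <- draw_population(params)
  p2 <- draw_population(params)
  expect_identical(p1, p2)
  expect_error(generative_params(N = 500), "at least 1000")
  strong <- prevpool:::resolve_params(
    generative_params(N = 2e4, phi = 20, seed = 44))
  pop <- draw_population(strong)
  expect_gt(mean(pop$y1 == pop$y2), 0.99)
})

test_that("sampling honours overlap, shows selection bias, and post-stratification removes it", {
  st <- small_study(N = 1e5, n1 = 400, n2 = 4000, overlap = 0.5, seed = 101)
  tab <- st$tab
  expect_identical(sum(tab$linked), 200L) # overlap * n1
  full <- small_study(N = 5e4, n1 = 200, n2 = 2000, overlap = 1.0, seed = 81)
  expect_identical(sum(full$tab$linked), 200L) # every survey subject linked

  # the design factors enter the inclusion model positively, so the raw
  # samples over-represent them; u1 (coefficient 1) is detectable at this n
  se_bin <- function(n) 3 * sqrt(0.25 / n)
  expect_gt(mean(tab$u1[tab$in_ehr]), 0.5 + se_bin(sum(tab$in_ehr)))
  # x1's coefficient (0.187) needs a larger sample to clear 3 MC SEs
  big <- small_study(N = 2e5, n1 = 400, n2 = 1e5, overlap = 0.5, seed = 113)
  expect_gt(mean(big$tab$x1[big$tab$in_ehr]),
            0.5 + se_bin(sum(big$tab$in_ehr)))
  # post-stratified weighted mean of a cell variable equals the population mean
  eh <- tab[tab$in_ehr, ]
  expect_equal(sum(eh$w2 * eh$x1) / sum(eh$w2), mean(st$pop$x1),
               tolerance = 1e-12)
  expect_equal(sum(eh$w2 * eh$u1) / sum(eh$w2), mean(st$pop$u1),
               tolerance = 1e-12)
  # survey weights are inverse inclusion probabilities
  sv <- tab[tab$in_survey, ]
  expect_equal(sv$w1, 1 / sv$pi1, tolerance = 1e-12)
  expect_true(all(is.na(tab$pi2))) # record-source inclusion deleted
})

test_that("experiment summaries match hand computation and are reproducible", {
  params <- generative_params(N = 2e4, n1 = 200, n2 = 1500, overlap = 0.5,
                              target_p2 = 0.33, seed = 61)
  res <- run_experiment(params, replicates = 2, estimators = "survey")
  x <- res$replicates$survey
  expect_equal(res$summary$mean_estimate, mean(x), tolerance = 1e-12)
  expect_equal(res$summary$sqrt_mse, sqrt(mean((x - 0.3)^2)),
               tolerance = 1e-12)
  # sqrt(MSE)^2 = bias^2 + variance (population divisor)
  res3 <- run_experiment(params, replicates = 6,
                         estimators = c("survey", "ehr", "mosteller"))
  for (nm in c("survey", "ehr", "mosteller")) {
    v <- res3$replicates[[nm]]
    mse <- res3$summary$sqrt_mse[res3$summary$estimator == nm]^2
    expect_equal(mse, (mean(v) - 0.3)^2 + mean((v - mean(v))^2),
                 tolerance = 1e-12)
  }
  # determinism under the same base seed
  res3b <- run_experiment(params, replicates = 6,
                          estimators = c("survey", "ehr", "mosteller"))
  expect_identical(res3$replicates, res3b$replicates)
  expect_error(run_experiment(params, replicates = 1), "at least 2")
  expect_error(run_experiment(params, 2, estimators = "imputation"),
               "no imputation_cfg")
})

test_that("full-scale study parameters are accepted by the validators", {
  params <- generative_params(N = 1e7, n1 = 500, n2 = 1e5, overlap = 1.0,
                              target_p2 = 0.35)
  expect_s3_class(params, "generative_params")
  cfg <- imputation_config(M = 30, B = 10)
  expect_identical(cfg$M, 30L)
})
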