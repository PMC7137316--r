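---
title: "Pooling a gold-standard survey with error-prone health records: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling a gold-standard survey with error-prone health records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevpool)
```

## The problem

Two samples measure the same binary health outcome in one target
population. The survey $S_1$ (size $n_1$, design weights $w_1$) measures
$Y_1$, taken as error-free; its weighted prevalence
$\hat p_1 = \sum_{S_1} w_{1i} Y_{1i} / \sum w_{1i}$ is design-unbiased but
noisy because $n_1$ is small. The record source $S_2$ (size $n_2 \gg n_1$)
measures $Y_2$, a possibly misclassified version of the same condition,
under a nonprobability inclusion mechanism; post-stratified weights $w_2$
remove the selection bias that is explainable by the weighting cells, but
no weighting can remove subject-level misclassification. A linked subset
$S_c = S_1 \cap S_2$ carries paired $(Y_1, Y_2)$ observations.

`prevpool` provides the two ends of the methodological spectrum: an
aggregate-mode pooled estimator needing only published estimates and
intervals, and a microdata-mode multiple-imputation estimator that models
the misclassification directly.

## The pooled (Mosteller-type) estimator

All pooling happens on the log-odds scale, where sampling distributions of
prevalence estimates are closer to normal and intervals respect $(0,1)$.
With $y_j = \mathrm{logit}(\hat p_j)$ and SEs $\sigma_j$, the family
$\hat\phi = (k_1 y_1 + k_2 y_2)/(k_1 + k_2)$ has minimal MSE at
$k_1 = 1/\sigma_1^2$, $k_2 = 1/(\tau^2 + \sigma_2^2)$, where $\tau$ is the
bias of $y_2$. $\tau^2$ is estimated by the consistent plug-in
$\hat\tau^2 = (y_1 - y_2)^2$. Equivalently, $\hat\phi$ is the posterior
mean under a flat prior on the true log-odds and a N$(0, \tau^2)$ prior on
the bias; the posterior SD
$\sigma_1\sqrt{(\sigma_2^2+\tau^2)/(\sigma_1^2+\sigma_2^2+\tau^2)}$ is
never larger than $\sigma_1$, and the reported interval is the
highest-density normal interval on the logit scale, back-transformed.

Design choices:

* **CI-derived SEs.** Published tables print estimates and 95% CIs, not
  SEs. We interpret the interval as symmetric on the logit scale and take
  $\sigma = (\mathrm{logit}(u) - \mathrm{logit}(l)) / (2 z_{0.975})$. This
  matches the scale on which the package's own intervals are built and is
  exactly self-inverse. Explicit (e.g. design-based) SEs override the
  CI-derived ones when supplied.
* **No continuity corrections.** A weighted prevalence of exactly 0 or 1
  raises an error instead of being silently nudged; a hidden correction
  would contaminate $\hat\tau^2$ and hence the weights. Callers who want
  pseudo-observations must add them explicitly.
* **$y_1 = y_2$ exactly** gives $\hat\tau^2 = 0$ and $k_2 = 1/\sigma_2^2$
  with no special-casing; the formulas are continuous there.
* **Relative weights** are reported as $k_j / (k_1 + k_2)$, the
  information shares on the logit scale.
* The normal quantile is computed from the requested level; the default
  0.95 reproduces the conventional 1.96.

A caveat on reproducing published tables from printed inputs: when the two
sources are close, $\hat\tau^2$ is the square of a difference of two
rounded numbers, so third-decimal weight shares for near-agreeing
indicators are sensitive to input rounding. The packaged NYC table flags
the indicators (diabetes, smoking, obesity) where this can shift the last
printed digit; the pooled *estimates* still agree to 0.1 percentage points
for all six.

## The subject-level imputation estimator

The microdata estimator imputes the gold-standard outcome for every
unlinked record-source subject and then uses the record source's size:

$$\hat p_m = \frac{\sum_{i \in S_2} w_{2i}\,\hat Y_{m,1,i}}{\sum_{i \in S_2} w_{2i}},$$

with $\hat Y_{m,1,i} = Y_{1,i}$ whenever observed — observed outcomes are
never overwritten, and an assertion enforces this on every pass.

**Misclassification models.** Within strata $l = 1,\dots,4$,

* M1: $\mathrm{logit}\,P(Y_2 = 1 \mid z, y_1) = \beta_{0l} + \beta_{1l} z + \beta_{2l} y_1$
* M2: $\mathrm{logit}\,P(Y_1 = 1 \mid z, y_2) = \gamma_{0l} + \gamma_{1l} z + \gamma_{2l} y_2$

The strata are quartiles of the estimated inclusion probability to the
*other* source's sampling mechanism ($\pi_2$ for M1, $\pi_1$ for M2); the
stratification, rather than weighted likelihoods, carries the design
information into the fits. Quartile ties collapse to fewer strata with a
warning.

**Inclusion-probability models.** $\pi_1$ is known by design for survey
subjects only; a logistic regression of the survey-membership indicator on
the survey design factors, fitted over the record-source subjects weighted
by $w_2$, predicts it elsewhere. Because a forced linkage rate shifts the
observed membership frequency away from the population rate, predictions
are anchored: predicted logits are shifted so their average over subjects
with known $\pi_1$ matches the known values, and known values always take
precedence. This only needs to preserve ranks — the quartile cut points are
all that downstream code uses. $\pi_2$ is modelled symmetrically
(membership known through linkage, fitted over survey subjects with
weights $w_1$). When linkage is *complete* — every survey subject is in
the record source, the design of the benchmark scenarios — that membership
indicator is constant and the $\pi_2$ model is unidentified; the package
then stratifies by quartiles of $1/w_2$ instead, since post-stratified
weights are inversely proportional to inclusion within weighting cells.
This fallback is automatic and logged in the result.

**Bayesian fits and draws.** Each stratum model is a logistic regression
with independent Cauchy(0, 2.5) priors on all coefficients, the
weakly-informative default that keeps posterior modes finite under the
complete separation that small strata produce. Predictors are standardised
before the prior applies (binary centred; continuous scaled to SD 0.5) and
coefficients mapped back. The fit is a damped Newton ascent of the
penalised log-likelihood; the imputation draw is taken from the normal
approximation at the mode (covariance the inverse observed information)
rather than MCMC — orders of magnitude cheaper and adequate away from
separation. Its known weakness: *under* near-separation the true posterior
of the separating coefficient is right-skewed, the symmetric approximation
over-weights small slopes, and imputations become slightly noisier than an
exact posterior would make them. This is visible only in the
near-deterministic concordance regime (tests place it at about one
percentage point of prevalence at stratum size 250) and does not affect
the realistic misclassification settings.

**Iteration schedule.** Each of the $M$ imputations runs an initial
restricted pass — M1 fitted on the linked subjects (the only rows where
both outcomes are observed), then M2 fitted on the rows with observed
$Y_1$ — followed by $B$ full-sample passes in which both models are refit
on all of $S_1 \cup S_2$ treating the latest imputations as observed. A
pass with nothing to impute (e.g. $Y_2$ complete under full linkage) is
skipped. $B$ defaults to 10 with a convergence diagnostic: if an
imputation's prevalence trajectory moves by 0.002 or more over the last
three passes, a warning suggests a larger $B$. At desk-scale record sizes
(around $10^4$) the per-pass Bernoulli redraw noise alone is of that
order, so the diagnostic warns liberally there; it is calibrated for
full-scale runs (around $10^5$) where residual drift is the signal.

**Combination.** The $M$ logit-scale estimates and naive delta-method SEs
are combined by Rubin's rules, $T = W + (1 + 1/M)B$, with Barnard–Rubin
degrees of freedom. The complete-data df $\nu_{com}$ is not prescribed by
the combination rule itself; we use the Kish effective record-source
sample size $\left(\sum w_2\right)^2 / \sum w_2^2$ minus one, the
defensible survey choice when weights are unequal. The reported point
estimate is $\bar p = \sum_m \hat p_m / M$ with the interval centred at
$\mathrm{logit}(\bar p)$ and back-transformed.

**Model-fit diagnostic.** `cv_auc_misclassification()` reports the k-fold
cross-validated AUC of M2 on the linked subjects, per stratum — the
practical check of whether the available covariates can model the
misclassification at all (AUC near 0.5 means they cannot, and the
aggregate-mode estimator should be preferred). It never feeds back into
the estimates.

## The simulator

The generator exists to create exactly the conditions under which the
estimators were benchmarked, at any scale.

* **Population.** $x_1 \sim$ Bernoulli(0.5), $x_2 \sim N(0,1)$, design
  factors $u_1, u_2$ likewise, all independent. Outcomes are drawn jointly
  with cell odds $(p_{11}:p_{10}:p_{01}:p_{00}) =
  (e^{\varphi+\eta_{10}+\eta_{01}} : e^{\eta_{10}} : e^{\eta_{01}} : 1)$,
  which makes both conditionals exactly logistic with log odds ratio
  $\varphi$ — an algebraic identity the test suite checks to $10^{-12}$.
* **Calibration.** The benchmark scenarios are stated as target marginals
  ($p_1 = 0.30$; $p_2$ from 0.30 to 0.35), not intercepts. The intercepts
  are solved by damped Newton on the two-dimensional moment condition,
  with the expectation over $x_2$ by 40-node Gauss–Hermite quadrature
  (residuals below $10^{-8}$). Slopes and $\varphi$ are not identified by
  the targets; the defaults $\gamma_1=\gamma_2=\beta_1=\beta_2=0.3$,
  $\varphi = 1.5$ give a moderate, realistic covariate-driven
  misclassification structure and are freely overridable. Benchmarks
  insensitive to them (means of design-unbiased estimators, root MSEs
  dominated by design bias and variance) reproduce regardless.
* **Sampling.** "Inclusion proportional to" the logistic transform of
  $a_0 + a_1 u_1 + a_2 u_2 + a_3 x_1$ with $(1, 1, 1, 0.187)$ for both
  sources — a linear predictor itself cannot be a probability, so the
  expit is used as the size measure, normalised to the expected sample
  size. Fixed-size draws use sequential Poisson sampling (smallest
  $u_i/s_i$). Because $x_1$ drives both outcomes and inclusion, the
  induced missingness is MAR but not MCAR. The required linked fraction is
  topped up by uniform draws among not-yet-included survey participants —
  the simplest mechanism that adds members without new design information.
* **Post-stratification.** $w_2$ uses the full joint cells
  $u_1 \times \mathrm{quartile}(u_2) \times x_1$ against the realised
  population distribution — exact cell weighting, no raking; an empty
  sample cell with positive population share is an error rather than a
  silent collapse. Weighted cell-variable means then equal population
  means exactly (tested to $10^{-12}$).
* **Replication.** Each replicate redraws the population (configurable to
  a fixed population), with replicate $r$ seeded at `seed + r` and the
  imputation substream at `seed + 7919·r`, so any replicate can be
  reproduced in isolation and imputations are order-independent.
  Estimator failures are recorded and excluded with a count, never
  silently dropped.

### What the generator does and does not emulate

It reproduces selection on observed design factors, covariate-dependent
misclassification with a controlled marginal bias, partial linkage, and
known population cell totals. It does **not** emulate linkage errors,
survey non-response, measurement error in the covariates, institution-level
clustering of record errors, or selection on unobservables — so passing
benchmarks here shows the estimators do what they claim under their own
assumptions, not that those assumptions hold in any particular real
linkage study.

### Problem sizes used in the shipped checks

The published benchmarks were produced at $N = 10^7$, $n_2 = 10^5$, 200
replicates and $M = 30$. The package's own test suite and acceptance
script run the same code path at the reduced sizes it states inline —
$N = 10^6$, $n_2$ of 10–20 thousand, 50–200 replicates, $M = 10$ —
chosen so that the Monte-Carlo error of each checked quantity is still
several times smaller than the effect being verified. Full-scale
parameters are accepted and validated by the same constructors.

## Numerical and degenerate-input policy

* `logit` rejects 0 and 1 rather than returning infinities; pooling needs
  finite log-odds, and the error names the offending value.
* Quantile binning (`discretize`) refuses to build fewer than the
  requested number of distinct bins; stratification (`assign_strata`)
  instead collapses with a warning, because there a degraded stratification
  is preferable to a dead stop mid-imputation.
* First-pass imputation strata need at least 10 training rows and both
  outcome classes; violations name the stratum and pass.
* The joint-probability kernel subtracts the row maximum before
  exponentiating, so arbitrarily large linear predictors are safe.
* Newton steps (both the Bayesian fits and the intercept calibration) are
  halved until the objective improves, with a BFGS fallback for the fits;
  non-convergence is an error, never a silent result.

## Known limitations

* The aggregate-mode estimator inherits the printed inputs' rounding; for
  near-agreeing sources the weight split (not the estimate) can shift in
  the third decimal.
* $\hat\tau^2 = (y_1-y_2)^2$ is itself noisy at small $n_1$; the pooled
  estimator's credibility interval does not propagate that uncertainty
  (the posterior treats $\tau^2$ as known).
* The normal-approximation posterior draw under near-separation slightly
  under-disperses the separating coefficient (see above).
* Post-stratification assumes the population joint distribution of the
  cell variables is known exactly — true in the simulator, an
  approximation with census-derived control totals.
* The imputation estimator's validity rests on the misclassification
  models being correct and the linked subset being representative at
  stratum level; with covariates that cannot predict the misclassification
  (low cross-validated AUC), its intervals can be wider than the survey's
  own, and the aggregate-mode estimator is the better tool.
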