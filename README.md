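# prevpool

Estimating a population prevalence from two imperfect sources: a small
probability **health survey** whose outcome measurement is treated as the
gold standard, and a much larger **electronic health record (EHR)** style
source whose outcome may be misclassified and whose inclusion mechanism is
not a probability design. Public-health surveillance teams increasingly have
both — a few hundred to a few thousand carefully examined survey
participants, and hundreds of thousands of clinical records — and neither
alone is satisfactory: the survey is unbiased but noisy, the record source
is precise but can be badly biased even after post-stratification.

`prevpool` implements two estimators that pool the sources, plus the full
simulation machinery to validate them.

## The estimators

**Mosteller pooling (aggregate mode).** Work on the log-odds scale with
`y1 = logit(p̂1)`, `y2 = logit(p̂2)` and standard errors σ₁, σ₂ (recovered
from printed 95% CIs when microdata are unavailable). With the squared
estimated bias τ̂² = (y₁ − y₂)², the pooled log-odds is the
precision-weighted average

    φ̂ = (k₁y₁ + k₂y₂) / (k₁ + k₂),   k₁ = 1/σ₁²,  k₂ = 1/(τ̂² + σ₂²),

which minimises MSE in this family and is the posterior mean under a flat
prior on the true log-odds and a zero-mean normal prior (variance τ²) on the
bias of the second source. The posterior SD is
σ₁·√((σ₂² + τ²)/(σ₁² + σ₂² + τ²)), so pooling can only sharpen the
gold-standard interval; a record source that disagrees strongly is
discounted almost entirely.

**Subject-level multiple imputation (microdata mode).** When some subjects
can be linked across sources, the misclassification is modelled directly:
stratified Bayesian logistic regressions M1 (`y2 ~ z + y1`) and M2
(`y1 ~ z + y2`) with Cauchy(0, 2.5) priors, stratified by quartiles of the
estimated inclusion probabilities to each source, are iterated to impute
the gold-standard outcome for every record-source subject. M imputations
are combined by Rubin's rules with Barnard–Rubin degrees of freedom.

## Worked example

Pooling the published aggregates for six adult health indicators in New
York City (gold-standard examination survey vs post-stratified EHR
surveillance):

```r
library(prevpool)
nyc_demo()
#> Pooled prevalence for six NYC health indicators (percent):
#>     indicator survey_pct ehr_pct pooled_pct ci_lower_pct ci_upper_pct
#>  hypertension       34.3    34.7       34.7         33.9         35.4
#>      diabetes       13.3    14.9       13.8         12.1         15.7
#>       smoking       17.3    15.0       16.8         14.8         19.0
#>       obesity       31.7    28.0       31.2         28.4         34.0
#>    depression       19.0     8.3       18.9         16.5         21.5
#>     influenza       48.6    21.7       48.5         45.3         51.7
#>  weight_survey weight_ehr input_rounding_sensitive
#>          0.062      0.938                    FALSE
#>          0.660      0.340                     TRUE
#>          0.799      0.201                     TRUE
#>          0.858      0.142                     TRUE
#>          0.992      0.008                    FALSE
#>          0.997      0.003                    FALSE
```

Reading the table: where the two sources agree (hypertension), the pooled
estimate leans on the huge record source and its interval narrows to a
fraction of the survey's. Where they disagree wildly (depression 19.0% vs
8.3%, influenza 48.6% vs 21.7%), τ̂² inflates the record-source variance so
its weight collapses to under 1% and the pooled estimate stays within 0.1
points of the survey — the gold standard acts as a safeguard. The flag
marks indicators whose printed inputs are rounded coarsely enough to shift
the last displayed digit.

Simulating a two-source study and comparing estimators:

```r
params <- generative_params(N = 1e6, n1 = 500, n2 = 2e4, overlap = 1,
                            target_p1 = 0.30, target_p2 = 0.35, seed = 1)
run_experiment(params, replicates = 100,
               estimators = c("survey", "ehr", "mosteller"))
#>  estimator mean_estimate sqrt_mse ...
#>     survey        ~0.300   ~0.021
#>        ehr        ~0.350   ~0.050
#>  mosteller        ~0.306   ~0.022
```

The record-source estimator carries its full 0.05 misclassification bias;
the pooled estimator stays close to the truth at roughly the survey's root
MSE — and beats the survey outright when the record bias is moderate.

## Command line

A thin launcher wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "prevpool.R", package = "prevpool"))')
Rscript "$CLI" nyc-demo
Rscript "$CLI" pool inst/extdata/nyc_depression.csv report.json
Rscript "$CLI" --seed 7 make-fixture study.csv
Rscript "$CLI" simulate inst/extdata/table1_p235_scaled.yaml out/
```

Every command writes a manifest (seed, config hash, package version)
alongside its outputs; rerunning with the same inputs and seed reproduces
stochastic outputs byte-for-byte.

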