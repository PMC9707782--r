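# beartrack

Camera-trap analysis of large-carnivore habitat use along an
urban–wildland gradient.

Wildlife that persists near people often adjusts *where* and *when* it is
active. This package implements the full analysis chain for testing both
adjustments with camera-trap data on black bears (*Ursus americanus*)
sampled across urban, rural and wild strata: detection-event processing,
zero-inflated negative-binomial mixed modelling of monthly detection
counts with AICc multimodel inference, a risk-ratio test for increased
nocturnality near people, and spatial residual diagnostics. A
synthetic-study generator emulates the whole sampling design so every
stage can be exercised and validated end to end without field data. It is
written for quantitative ecologists and wildlife managers analysing
camera-trap surveys in human-dominated landscapes.

## The models

**Habitat use.** Monthly detection counts `y_ij` at site *i* in month *j*
are modelled as zero-inflated negative binomial with a site random
intercept and an effort offset:

```
log mu_ij = x_ij' beta + u_i + log(effort_ij),   u_i ~ N(0, sigma^2)
P(y = 0)  = pi + (1 - pi) NB(0 | mu, dispersion)
```

with NB variance either `mu (1 + mu/theta)` (nb2) or `mu (1 + alpha)`
(nb1). The site random intercept is integrated out by adaptive
Gauss–Hermite quadrature (15 nodes; Laplace available), and candidate
models — competing hypothesis sets built from standardized, buffer-
extracted covariates — are compared by AICc and Akaike weights, with the
parameter count `k = ncol(X) + sigma + dispersion + zi`.

**Nocturnality.** Detections are classified day/night by solar geometry
(NOAA algorithm, −0.833° rise/set altitude). For each disturbed class
against the wild baseline, the log risk ratio of nocturnal proportions

```
RR = ln(X_high / X_low),
Var(RR) = 1/O_high,night − 1/O_high + 1/O_low,night − 1/O_low
```

gets a Wald 95% CI, and is compared against a permutation null built by
reassigning detections to strata 1000 times (stratum totals and diel
labels fixed). A shift is significant when the observed CI and the 95%
highest-density interval of the null are disjoint.

**Diagnostics.** Moran's I with inverse-distance, row-standardized
weights on per-site Pearson residuals, with a one-sided permutation
p-value, screens the best-supported model for residual spatial
autocorrelation.

## Worked example

```r
library(beartrack)

# a complete synthetic study at the default (study-emulating) conditions
bundle <- generate_study(truth_config(seed = 1))
bundle
#> <btk_bundle> 54 sites x 13 months (702 site-month rows), 612 detection records
#>   zero site-months: 77.2%; seed 1

# events -> diel labels -> nocturnality inference
events <- classify_diel(independent_events(bundle$records),
                        bundle$deployments)
noct <- nocturnality_analysis(events, n_iter = 1000, seed = 1)
dplyr::select(noct, class, O, O_night, rr, ci_low, ci_high,
              hpdi_low, hpdi_high, significant)
#> # A tibble: 2 × 9
#>   class     O O_night    rr ci_low ci_high hpdi_low hpdi_high significant
#>   <chr> <int>   <int> <dbl>  <dbl>   <dbl>    <dbl>     <dbl> <lgl>
#> 1 urban   104      58 1.16   0.693    1.62   -0.336     0.336 TRUE
#> 2 rural   411     177 0.899  0.453    1.34   -0.254     0.272 TRUE
```

`rr` is the log risk ratio of nocturnal activity against the wild
baseline (positive = more nocturnal near people), `ci_*` its Wald 95%
interval, and `hpdi_*` the 95% highest-density interval of the
permutation null; `significant` applies the interval-overlap rule. Here
the synthetic bears — generated with urban/rural/wild nocturnal
probabilities 0.52/0.47/0.22 — are correctly detected as significantly
more nocturnal in both disturbed strata.

Model comparison on the same bundle:

```r
tab <- bundle_model_table(bundle)
fits <- lapply(table1_model_set(), fit_zinb, data = tab)
compare_models(fits)
autoplot(fits$conflict_int) # standardized effect sizes with 95% CIs
```

The single-call pipeline writes every stage's table (events, site-month
counts, covariates, both model comparisons, nocturnality, Moran's I) plus
a manifest with seeds and a config hash:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
```

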