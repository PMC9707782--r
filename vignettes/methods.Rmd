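---
title: "Models and methods behind beartrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind beartrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

beartrack implements a complete analysis chain for camera-trap monitoring
of a large carnivore across an urban-rural-wild disturbance gradient:
from raw detection records to habitat-use models and a test for increased
nocturnality near people. This vignette describes the statistical models,
the assumptions they carry, the defaults and why they were chosen, and
what the synthetic-data generator does and does not emulate.

## From detections to observations

Motion-triggered cameras fire repeatedly while an animal lingers, so raw
records overstate the number of independent visits. Records at a site are
collapsed into *independent detection events*: a record opens a new event
when it is at least `gap` minutes (default 30) after the immediately
preceding record. We measure the gap from the previous *record*, not from
the event's opening record, which is the common camera-trap convention
and the simplest reading of "separated by at least 30 minutes"; the two
interpretations coincide unless a burst of records chains past the gap,
and the alternative is available via `rule = "event-start"`. A separation
of exactly the gap counts as independent. Sows with cubs are treated as a
single event upstream of this package (an image-classification concern).

Events are summed per site and calendar month into the modelling unit:
one row per site-month (54 cameras over 13 monthly occasions gives 702
rows), with the number of active camera days as sampling effort. Month
boundaries use the site's local civil time with a fixed UTC offset
(default -8 h); no daylight-saving logic is applied, because the offset
is explicit per run and a one-hour shift near midnight affects at most a
handful of month assignments. The plotted detection rate is
`count / effort * days-in-month`, and it is undefined (`NA`, never zero)
when effort is zero.

Seasons follow the phenology-adjusted mapping used for this system —
spring February-April, summer May-July, autumn August-October, winter
November-January — so that autumn covers peak berry abundance and
hyperphagia. Spring is the factor reference level.

## Solar geometry and diel classification

Each event is diurnal if it falls in `[sunrise, sunset)` for its site and
local civil date, nocturnal otherwise. Sunrise and sunset come from the
NOAA low-precision solar-position algorithm (Meeus-style series for the
solar longitude, declination and equation of time) with the conventional
-0.833 degree altitude accounting for refraction and the solar disc, and
one refinement pass at the provisional rise/set time. The algorithm is
self-contained and accurate to about a minute at mid-latitudes; tests
check the equator/equinox geometry analytically and compare a one-year
day-length sweep at the study latitude against an independent ephemeris
model (`geosphere::daylength`), which agrees to a few minutes — the two
series genuinely differ, so that check bounds gross errors rather than
asserting minute-level agreement. Latitudes beyond 66.5 degrees (polar
day/night) are rejected explicitly; the study envelope is mid-latitude.

## Covariate extraction

Site covariates are extracted from gridded layers as area-weighted means
over a 150 m circular buffer: each cell contributes its value weighted by
the area of its intersection with the disc, so cells extending past the
buffer edge are down-weighted by the excluded fraction. Intersection
areas are computed by regular sub-cell sampling (default 32 x 32 points
per cell); exact circle-square geometry would add complexity without
changing results at the tolerances that matter here, and the resolution
is a tested knob that converges to dense numerical integration. No
distance-decay weighting is applied inside the buffer — nothing in the
method calls for it. Conflict reports are counted within a 500 m buffer,
with boundary points included (distance less than or equal to the radius).

The monthly vegetation index handles satellite composites whose fixed
16-day windows straddle calendar months: the monthly value is the
buffer mean of each overlapping window, weighted by its days of overlap
with the focal month.

Continuous covariates are standardized (centred, divided by the sample
n-1 standard deviation) so effect sizes are directly comparable, and the
covariate set is screened for collinearity by flagging any pair with
absolute Pearson correlation at or above 0.7 — absolute, because
collinearity is sign-agnostic. Distance-to-feature layers and the
per-season conflict-probability surface are consumed as supplied inputs;
computing them from vector geodata, and propagating the conflict
surface's estimation uncertainty, are out of scope (the uncertainty is
knowingly not propagated).

## The count model

Site-month counts are modelled as zero-inflated negative binomial with a
site random intercept and a log-effort offset:

- conditional mean `log mu_ij = x_ij' beta + u_i + log(effort_ij)` with
  `u_i ~ N(0, sigma^2)`;
- negative binomial variance either quadratic in the mean,
  `mu (1 + mu / theta)` ("nb2"), or linear, `mu (1 + alpha)` ("nb1");
- a zero-inflation mixture `P(0) = pi + (1 - pi) NB(0)`, with `pi`
  modelled as a single logit-scale intercept.

Zero-inflation is intercept-only because that choice exactly reproduces
the candidate tables' parameter accounting (for example the conflict
hypothesis with the trail-by-human-density interaction has
k = 10 fixed-effect columns + sigma + dispersion + zi intercept = 13);
richer zero models would change k for every candidate. Parameter count
is always `k = ncol(X) + 3`.

The marginal likelihood integrates the random intercept out per site.
That one-dimensional integral is evaluated by *adaptive Gauss-Hermite
quadrature*: a damped Newton search (analytic first and second
derivatives in `u`) finds each site's conditional mode, the quadrature
nodes are recentred there and rescaled by the curvature, and 15 nodes
(default) are combined on the log scale. A Laplace option
(`method = "laplace"`) keeps only the mode and curvature and is roughly
twice as fast; it is useful for large simulation studies. The quadrature
is validated against brute-force trapezoid integration to 1e-6 on small
fixtures, and whole fits are cross-checked against an independent
mixed-model implementation (glmmTMB) in the test suite.

Maximization is quasi-Newton (BFGS) on the unconstrained scale — `beta`
free, `log sigma`, `log dispersion`, `logit pi` — from a moment-based
start (intercept at the raw log rate) plus seeded jittered restarts
(default 5 starts; the simulation studies use 1, since the moment start
is reliable there). Standard errors come from the numeric Hessian at the
optimum; Wald p-values are reported with no multiple-testing correction,
mirroring standard practice for these candidate tables. Non-convergence
is flagged honestly and flagged fits are excluded from comparisons with a
warning. Rows with zero effort are dropped (their offset is undefined)
with a message.

Candidate models are compared by AICc,
`-2 logLik + 2k + 2k(k+1)/(n-k-1)`, with `n` the number of site-month
rows (702 at the default design) — the effective sample size of a mixed
model is ambiguous, and the row count is the documented convention here.
Akaike weights are relative likelihoods normalized within a hypothesis
set; the comparison table reports each model's AICc difference from the
best model within its set and each set leader's difference from the
overall best. The seasonal candidate set is fitted under both nb1 and
nb2, keeping whichever has the lower AICc per hypothesis. One published
df column for that table is internally inconsistent (values like 87 and
4 that no zero-inflated mixed count model of these terms can produce);
we derive df from the model structure instead, which matches the
defensible entries (11 for conflict-by-season, 7 for season-only).
Quadratic terms are raw polynomials on standardized covariates — with
intercept-only zero inflation the fit is invariant to orthogonalization,
and raw terms keep coefficients interpretable on the standardized scale.

## The nocturnality test

Nocturnality is compared between each high-disturbance class (urban,
rural) and the wild baseline through the log risk ratio
`RR = ln(X_h / X_l)`, where `X` is the proportion of night detections,
with variance `1/O_h,night - 1/O_h + 1/O_l,night - 1/O_l`. Positive RR
means more nocturnal activity under more human presence. The observed
interval is Wald on the log scale, `RR ± 1.96 sqrt(var)`; the
construction is not dictated by the risk-ratio definition alone, but it
is the unique standard form that reproduces both published intervals
from the published point estimates and the variance equation, which is
why it is the default and only option.

The null reference is a permutation distribution: detections are
randomly reassigned to the urban/rural/wild categories 1000 times,
preserving the observed number of detections per category (sampling
effort per stratum is fixed by design) and each detection's diel label;
both RRs are recomputed per iteration. Iterations producing a zero night
count in a needed cell leave the RR undefined and are dropped from the
interval with a logged count — at study-sized counts this essentially
never happens. The 95% highest-density interval of the null draws is the
shortest contiguous window of the sorted sample containing
`ceiling(0.95 n)` points, ties broken toward the lower start. A shift is
declared significant when the observed CI and the null HPDI are
disjoint; a shared endpoint counts as overlap, the conservative choice.
This overlap rule is nonstandard as a test, so the package measures its
operating characteristics by simulation rather than assuming them: at
study-sized counts the acceptance suite reports a rejection rate under a
no-shift world (empirically well under 10%) and under a true shift of
RR = 0.8 (empirically well above 50%). Season-stratified risk ratios are
computable with the same functions but are not produced by default — at
these sample sizes the per-season cells are too small to be meaningful.

## Spatial diagnostics

Residual spatial autocorrelation is checked with Moran's I on per-site
residuals: Pearson residuals `(y - E[y]) / sd[y]` under the fitted
zero-inflated model at the population level (random effect at its zero
mean), averaged within site. Weights are inverse Euclidean distance with
zero diagonal, row-standardized — the scheme and residual type are
documented assumptions, since the method only requires *a* global
autocorrelation test, and a binary nearest-neighbour scheme is available
behind a flag. The p-value is one-sided for positive autocorrelation
from 999 value permutations, `p = (1 + #{I_perm >= I_obs}) / (n_perm +
1)`; a strongly negative I therefore yields p near 1, which is how a
diagnostic value like I = -0.05 with p = 0.999 should be read.

## The synthetic-study generator

`generate_study()` produces a complete study with the statistical
structure the analysis assumes, so every stage can be exercised and
validated without any external data. Its defaults are the study
conditions: 11/19/24 cameras in urban/rural/wild strata; 13 monthly
occasions from July 2018 with mid-month deployment and retrieval and a
12% daily outage rate (total effort near 16,500 camera-days); counts
from the zero-inflated NB model above with a stratum contrast
(wild baseline, rural strongest), a seasonal log-scale cosine peaking in
early September (amplitude 1.8 — detections peak in early autumn and
nearly vanish in late winter), `sigma_site = 0.8`, nb2 dispersion 0.8
and zero-inflation 0.33, which together put the zero fraction at 80% of
site-months within a few points; and per-stratum nocturnal
probabilities 0.52/0.47/0.22 (urban/rural/wild), the values implied by
the reconstructed study counts, so the default study lands near the
headline risk ratios. Event timestamps are drawn inside the correct
solar window on an active day and respect the 30-minute independence
gap, so the event bookkeeping round-trips exactly — the generator's
counts are the oracle for the events module.

Covariates are generated with the broad structure that matters for the
candidate models — human, road and trail densities and distances
organized around a town centre with a rural ring and wild outskirts,
a summer-peaked vegetation index that is higher in forested wild sites,
salmon presence near freshwater in autumn, and a conflict probability
rising with human density and peaking in late summer/autumn — on planar
metre coordinates with 25 m grid cells so the 150 m and 500 m buffers
are meaningful.

What the generator does *not* emulate: real animal movement and home
ranges (counts are conditionally independent across site-months given
the random intercept), spatial autocorrelation in the residual field,
temporal autocorrelation beyond the shared site intercept, camera-model
detectability differences, and observation error in covariates. Passing
tests on synthetic data therefore validate the estimation machinery and
bookkeeping — not the ecological fidelity of any particular fitted
coefficient on real data.

## Numerical choices and limitations

- Quadrature: 15 adaptive nodes by default; accuracy checked to 1e-6
  against dense trapezoid integration. Simulation studies in the test
  suite use 7 nodes and one start after verifying estimates agree to
  four decimals with the defaults.
- The simulation studies run at deliberately moderate sizes — Wald
  coverage at 200 sites over 200 replicates, model selection over 50
  replicates, test calibration over 500 replicates — chosen as the
  smallest sizes at which the binomial noise on the reported rates is
  comfortably inside the asserted bounds.
- Optimization: boundary attraction of the zero-inflation probability
  (`pi -> 0`) is expected when the NB component can absorb the zeros
  (low means, small theta); this is a property of the likelihood, not
  the optimizer — an independent implementation lands on the same
  optimum. Coefficient estimates remain well calibrated in that regime.
- The permutation null for the nocturnality test conditions on the
  observed diel labels and stratum totals; it does not model
  month-of-year structure in the labels.
- `aicc()` requires `n > k + 1` and errors otherwise; Akaike weights
  require finite AICc values.
- Degenerate inputs error loudly rather than returning silent defaults:
  constant columns in `standardize()`, constant values or duplicate
  coordinates in `morans_i()`, zero counts in the risk-ratio equations,
  polar latitudes in `sun_times()`.
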