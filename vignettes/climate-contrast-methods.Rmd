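---
title: "Methods: climate-contrast analysis of paired seed-cohort trait change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-contrast analysis of paired seed-cohort trait change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The design

Resurrection ecology grows stored (historic) seeds alongside freshly
collected (modern) seeds of the same species from the same site in a common
garden, so that trait differences between the two cohorts reflect heritable
change over the storage interval. The raw historic-vs-modern difference is
confounded by seed storage, viability loss and maternal effects. The
climate-contrast variant of the design removes this confound statistically:
because climate change is uneven across a landscape, one can regress
per-species trait change on per-site climate change across many species
pairs. Any artefact that applies uniformly to all historic cohorts (a
"storage bias") moves the *elevation* of that regression, never its
*slope*. The slope is therefore the climate signal, and the intercept is a
diagnostic: under no climate change the expected trait change should be
zero.

This package implements that analysis end to end, with a synthetic-data
generator whose ground truth is known, so every stage can be verified
without any external data.

## Trait change: the log ratio of means

For species $s$ and trait $t$, with cohort means $\bar m_{mod}$,
$\bar m_{hist}$, sample SDs and sizes, the effect size is

$$y_i = \ln\!\frac{\bar m_{mod}}{\bar m_{hist}}, \qquad
v_i = \frac{sd_{mod}^2}{n_{mod}\,\bar m_{mod}^2}
    + \frac{sd_{hist}^2}{n_{hist}\,\bar m_{hist}^2},$$

the standard delta-method sampling variance of a ratio-of-means effect. We
state the variance formula explicitly (rather than deferring to a tool) so
that independent implementations agree bit for bit. Means must be positive;
a non-positive mean, a single-individual cohort, or two zero SDs flag the
effect as unusable rather than erroring. lnRR is antisymmetric in the eras
and invariant to rescaling the measurement units, and both properties are
tested.

Intrinsic water-use efficiency is a derived trait,
$\mathrm{iWUE} = A_{sat}/g_s$, computed per individual *before* cohort
summarisation. Leaf nitrogen is measured on pooled per-era samples in this
design; it has no within-era variance, so its changes enter only the
unweighted leaf-economics analysis, never the variance-weighted
regressions.

## Climate change: twelve metrics, two scalings

Each era is summarised over the five years before its seed collection.
"Month prior" quantities use a 30-day trailing window before each of the
five collection anniversaries and are averaged over anniversaries; we chose
the trailing window over the calendar month to avoid month-length artefacts
(the calendar-month reading is noted as an alternative). The metrics:

* **Means** — daily *median* temperature and daily *mean* precipitation of
  the month prior, averaged over 5 anniversaries.
* **Variability** — coefficient of variation (sample SD / mean) of the same
  windows. A zero-mean window (an all-dry month) makes the CV undefined;
  it is flagged missing, not set to 0 or infinity.
* **Ranges** — yearly max minus min of daily values, averaged over the five
  anniversary years. Daily extremes are the stricter of the two plausible
  readings (daily vs monthly means) and are what we use.
* **Seasonal precipitation extremes** — maximum and minimum of the four
  calendar-month precipitation totals preceding the anniversary month,
  averaged over anniversaries. This fixed four-month rule is a documented
  simplification of season bounds that vary by latitude.
* **Aridity** — vapour pressure deficit from the Tetens saturation curve,
  $e_s = 0.6108\,e^{17.27T/(T+237.3)}$ kPa, $VPD = e_s(1 - rh/100)$,
  aggregated like the precipitation mean.
* **Extreme-event durations** — the longest heatwave by the excess heat
  factor: with 3-day trailing means $\bar T_3(i)$,
  $EHF(i) = \big(\bar T_3(i) - T_{95}\big)\cdot
  \max\!\big(1, \bar T_3(i) - \bar T_{30}(i)\big)$, where $T_{95}$ is the
  95th percentile of all in-window 3-day means and $\bar T_{30}$ the
  preceding 30-day mean; an event is $\ge 3$ consecutive positive-EHF
  days. The dry-spell index applies the identical machinery to daily VPD.
  All four constants (3, 0.95, 30, 3) are arguments. Both indices are
  invariant to adding a constant to the whole series, because the
  significance and acclimatisation terms are differences.
* **Drought duration** — the source analysis reports this metric without
  defining it, so our construction is an explicit stand-in: the longest run
  of days whose trailing 30-day precipitation total falls strictly below
  the in-window 10th percentile of such totals. Aggregation length and
  quantile are arguments, and the manifest records them. The metric is
  invariant to rescaling precipitation.

Changes are modern minus historic for the temperature metrics (including
the temperature CV and range) and $\ln(\text{mod}/\text{hist})$ for the
precipitation metrics, VPD and the durations; durations use
$\ln\frac{d_{mod}+1}{d_{hist}+1}$ so that zero-day durations are
admissible. The VPD and duration scalings are not fixed by the source
description; we assign them the log-ratio family because they are
positive-valued and precipitation-like, and the output manifest records the
assignment. Percentiles throughout use the linear-interpolation (type 7)
convention.

## Meta-regression

The analysis unit is $(y_i, v_i)$ per species. The model is
$y_i = \mathbf{x}_i^\top\beta + u_i + e_i$ with $u_i \sim N(0, \tau^2)$ and
$e_i \sim N(0, v_i)$ known. Weights are $w_i = 1/(v_i + \tau^2)$;
$\hat\beta = (X^\top W X)^{-1} X^\top W y$. $\tau^2$ is estimated by Fisher
scoring on the restricted (REML, default) or full (ML) likelihood score,
truncated at zero, to a tolerance of $10^{-10}$ in at most 100 iterations.
On balanced intercept-only data with common $v$, the REML estimate has the
closed form $\max(0, s_y^2 - v)$, which the tests verify to $10^{-8}$; the
fixed-effect fit equals inverse-variance weighted least squares to
$10^{-10}$ against an independent closed-form oracle.

Inference is Wald-normal. Knapp–Hartung-type small-sample adjustments are a
listed extension, not implemented, because the source analysis does not
state one. Pseudo-$R^2$ is the proportional reduction in $\tau^2$ relative
to the intercept-only model, truncated to $[0, 100]$ — the convention of
the standard meta-analysis tooling whose "marginal $R^2$" this mirrors.
Negative adjusted $R^2$ values appear only in the ordinary least-squares
ancillary regressions, where they are legitimate and preserved.

Every fit also reports the ML log-likelihood *for the same fixed-effect
structure*, because REML likelihoods are not comparable across different
fixed-effect structures. Information criteria therefore always use ML
likelihoods, even when coefficients are reported from REML fits; this is a
documented, switchable decision.

## All-subsets AICc selection

For each trait, every subset of the twelve climate-change moderators
(including the intercept-only model) is fitted on the complete-case
species. With $p$ = intercept + moderators + $\tau^2$ parameters and $k$
species,

$$AICc = -2\ell_{ML} + 2p + \frac{2p(p+1)}{k - p - 1},$$

models with $k - p - 1 \le 0$ being excluded and logged. Akaike weights
are $w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$; a moderator's
importance is the summed weight of models containing it; model-averaged
coefficients use zero substitution (a moderator absent from a model
contributes 0), matching the "average weighted value across all models"
convention; conditional averaging is a possible alternative we did not
default to. No cap is placed on moderators per model unless `max_terms`
is set. Exhaustive enumeration is tested against an independent subset
iterator, and weights must sum to 1 within $10^{-12}$.

## The leaf-economics axis

Changes in SLA (inverse LMA), photosynthetic rate and leaf nitrogen form a
species × 3 matrix with missing cells. Missing cells are completed by
iterative PCA: initialise with column means, then iterate centring,
rank-$r$ SVD reconstruction and overwriting of the missing cells only,
until the largest imputed-cell change is below $10^{-8}$. The default rank
is 1 (it cannot exceed 2 with three columns) and is recorded in the
manifest; rank 0 reduces to mean imputation. The completed matrix is
decomposed by column-centred, unscaled PCA (scaling is off by default,
matching the default of the standard PCA routine; the choice is recorded),
with each loading column's sign fixed so its largest-magnitude entry is
positive — this makes results deterministic across SVD implementations.

Component retention uses Horn's parallel analysis on correlation-scale
eigenvalues: observed eigenvalues are compared with those of seeded random
standard-normal matrices of the same shape, retaining components
sequentially while the mean-adjusted eigenvalue exceeds 1 (or, under the
`p95` rule, while the observed eigenvalue exceeds the random 95th
percentile). We standardise for the retention decision even though the PCA
itself is unscaled, because the adjusted-eigenvalue-vs-1 rule is only well
defined on the correlation scale. Component scores carry no sampling
variance, so they are regressed on the climate means with equal weights
($v_i \equiv 1$); the weighted machinery is reused unchanged.

## The synthetic generator: what it emulates, and what it does not

The generator is the package's stated world, fixed in advance of any test
outcome. Daily temperature is a sinusoidal seasonal cycle (southern-
hemisphere phase) plus AR(1) noise with $\phi = 0.7$ and marginal SD 3 °C —
i.i.d. noise would make the run-length extreme indices degenerate, so
persistence is essential. Precipitation is zero-inflated Gamma (wet-day
probability 0.35, shape 0.8), supporting mean, variability and extreme
metrics with non-negative values. The modern window applies a warming
offset, a variability multiplier, an additive boost to its top-5% hottest
days, and a multiplicative precipitation trend. Collection gaps default to
the study's 29–40 years; windows are 5 years plus a 60-day margin so the
extreme indices have their acclimatisation history.

Trait cohorts follow the analysis model itself: true
$\ln RR = \alpha + \sum_j \beta_j \Delta c_j + u$, with $u \sim N(0,
\tau^2)$ drawn independently per species × trait (traits are analysed in
separate univariate models, so a shared species effect would not be
identified; this is our reading of the per-species heterogeneity term).
Individuals are $N(\mu, (cv\,\mu)^2)$ truncated at zero by redraw. Draws
are generated as $\mu(1 + cv\,z)$ so that the entire random stream is
independent of $\mu$: multiplying the historic mean by $e^{-\delta}$ (the
storage bias) scales every historic individual exactly, shifts every
$y_i$ by exactly $+\delta$, and leaves every $v_i$ and every climate delta
untouched. This makes the framework's central claim — bias moves
intercepts, never slopes — exactly testable, and the pipeline-level test
verifies it to $10^{-8}$ through the full selection stack. Default cohort
sizes are 10 (the study's gas-exchange sampling) in the pipeline and 25 in
the parameter-recovery simulations; defaults for $\tau$ (0.02–0.05
log-ratio units) and within-cohort CV (0.2) are what we consider realistic
for seedling leaf traits.

The generator does **not** emulate: spatial correlation between sites,
phenology, species' differing baseline climates beyond a uniform draw,
non-Gaussian trait distributions, or correlated trait responses. A green
test therefore establishes that the estimators recover the stated
generative structure — not that the biological conclusions of any
particular dataset are correct. The generator writes ground truth to a
sidecar table only; the pipeline never sees it.

## Numerical and reporting choices

* Percentile convention: linear interpolation (R type 7), fixed.
* $\tau^2$ scoring tolerance $10^{-10}$, 100 iterations, truncation at 0;
  non-convergence is flagged, and non-convergent models are excluded from
  candidate sets with a logged reason.
* Ties in AICc resolve to the first enumerated (smaller) subset.
* No multiple-testing correction across the trait × moderator grid,
  mirroring the source reporting; significance stars use the
  .0001/.001/.01 thresholds.
* CSV outputs render numerics with `%.10g` so a fixed seed reproduces the
  artefact bundle byte for byte; the manifest records every decision above
  and contains no timestamps.

## Known limitations

Species are treated as independent (no phylogenetic covariance). The
drought metric is a documented stand-in. The equal-weight treatment of
PCA-score responses is our decision where the source is silent. The CLI
covers simulation, climate metrics, effect sizes and the full pipeline but
is a thin wrapper; programmatic use is the primary interface.
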