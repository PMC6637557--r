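---
title: "NPMR habitat analysis of whale behavioral state: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NPMR habitat analysis of whale behavioral state: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arsnpmr)
```

This vignette is the package's own account of its methods: the estimation
model and its assumptions, the tunable parameters and their defaults, what
the synthetic-data generator emulates (and what it does not), and the
numerical and design choices made where the method description left the
design open.

## The estimation model

The response is binary: presence (1) or absence (0) of area-restricted
search (ARS) at a daily, state-space-modeled whale location. ARS — slow,
tortuous movement — is the behavioral signature of foraging within a prey
patch; transiting — fast, directed movement — connects patches. The model
asks where along the track the environment makes ARS likely.

NPMR makes almost no structural assumptions about that relationship. The
estimate at a target location is a kernel-weighted local mean of the
response over all *other* locations, with one Gaussian weight per
continuous predictor, multiplied together:

$$w_{ti} = \prod_j \exp\!\left(-\frac{(x_{tj}-x_{ij})^2}{2\sigma_j^2}\right)
\qquad
\hat y_t = \frac{\sum_{i\ne t} w_{ti}\,y_i}{n^*_t},\quad
n^*_t = \sum_{i\ne t} w_{ti}.$$

Multiplicative combination means a location only informs the estimate when
it is close in *every* predictor simultaneously — predictor interactions
are native, not added terms. Categorical predictors (e.g. individual
whale) enter through an exact-match indicator weight, the only kernel
consistent with multiplicative combination in the absence of an ordering.

Leave-one-out is the overfitting control: the target never informs itself,
so a model that merely memorizes earns nothing. Estimates are only issued
where the neighborhood is populated, $n^*_t \ge n_{\min}$ with
$n_{\min} = 0.25\,\bar N$ ($\bar N$ = mean $n^*$ over estimated rows).
Because $n_{\min}$, the estimated-row set, and $\bar N$ are mutually
defined, the package resolves them by fixed-point iteration starting from
the all-rows mean; the same rule re-resolves $n_{\min}$ on any new
prediction set, which is why a regime-shifted validation set reports its
own, typically smaller, $\bar N$ and $n_{\min}$.

Fit statistics: logB is the base-10 log likelihood ratio against a naive
model predicting the observed prevalence everywhere (logB = 0);
$B_{ave} = 10^{\mathrm{logB}/SU}$ is its per-location average, independent
of sample size; xR² is the cross-validated pseudo-R²; $\chi^2 = 2\ln(10)\,
\mathrm{logB}$ is the deviance against the naive model. Before likelihood
evaluation the estimates are clamped to $[\varepsilon, 1-\varepsilon]$
with $\varepsilon = 1/(2\,SU)$, a bounded-likelihood convention that keeps
a pure (single-class) neighborhood from contributing an infinite term.

**Tolerance** ($\sigma_j$) is each predictor's smoothing scale, reported
both in predictor units and as a percentage of the observed range.
**Sensitivity** ($Q_j$) nudges each row's predictor value by ±5% of the
range, re-estimates with the original neighbors (still leave-one-out), and
averages $|\Delta\hat y|$ over rows and directions, divided by the nudge
fraction: $Q_j = 0.71$ means a 20% predictor change moves the estimated
ARS likelihood by about 14 percentage points.

## Model search, tuning, inference

`npmr_search()` is a forward-stepwise free search: every candidate is
scanned over a tolerance grid (default 5%–100% of range in 5% steps) as a
single-predictor model; the best model of each size is extended by each
remaining candidate with a full grid scan over the *added* predictor's
tolerance, keeping incumbent tolerances fixed. A joint re-scan of all
tolerances at every step would cost $O(g^k)$ fits and is not what stepwise
search does; `npmr_tune()` closes the gap afterwards by coordinate-wise
refinement on a fine grid (one coarse step either side, five
subdivisions) until logB gains less than 0.01. Tuning only ever accepts
improvements, so it cannot lower logB.

Parsimony ("medium" overfitting controls): an added predictor must
improve logB by at least 5% of the incumbent's (or by 1.0 when the
incumbent is non-positive); model size is capped at a 30:1
row-to-predictor ratio; ties break toward fewer predictors, then larger
tolerances (the grid is scanned from large to small with strict
improvement). All three knobs are exposed in `npmr_control()`.

Inference: `npmr_boot()` resamples rows with replacement, refits the
fixed model spec, and reports the 5th/95th percentiles and median of logB
(replicates with no populated neighborhood are recorded missing, not
dropped silently). `npmr_randomization()` shuffles the response and
reruns the *entire free search* per replicate — the null distribution is
"the best model findable in noise" — with
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + R)$, the +1/+1
correction preventing a literal zero. Both derive replicate seeds from a
base seed by fixed increments and are exactly reproducible.

## Track preparation

The behavioral-mode value in [1, 2] is thresholded at strict 1.25/1.75:
below, transiting; above, ARS; between (inclusive), uncertain and
excluded. Track-level retention is a disjunction — duration > 14 d *or*
path length ≥ 888 km — so short tracks that cover ground and long slow
tracks both survive; the thresholds correspond to the typical transit
time and separation between ARS patches. Location-level rules run in a
fixed order (months July–November, study-polygon containment, credible
box ≤ 100 km, certain mode, non-terminal, depth ≤ 2000 m) so removal
logs are comparable across runs; each removal is attributed to the first
rule that rejects it, and counts always reconcile
(input = retained + removed).

Two conventions the rule descriptions leave open: "100 km in radius" is
interpreted as the *larger* of the two credible-interval half-widths,
converted to km at the point's latitude (max is the conservative reading
of a box-shaped uncertainty region); and the terminal location of each
track — which carries no behavioral classification upstream — is flagged
on first sight and the flag persisted, so re-filtering an
already-filtered table is a no-op (the filters are idempotent).

## Environmental extraction

Each location's predictor value is a weighted average of the grid cells
whose centers fall inside its credible box (half-open on the east/north
edges, a deterministic resolution-independent membership rule), weighted
by a smooth taper of great-circle distance from the estimated location:
$w(d) = (1-(d/d_{\max})^2)^2$, with $d_{\max}$ the distance to the
farthest box corner. The taper equals 1 at the location and 0 at the box
edge; its exact profile is injectable for sensitivity analysis. This
propagates location uncertainty into the extraction and, because the box
usually spans several cells, makes the value robust to cloud-masked
cells; the value is missing only when *no* non-missing cell center lies
in the box. Time-resolved grids contribute their nearest slice, and only
if it lies within one native time step of the location's date (satellite
products are 1–8 d composites; a location between composites should not
borrow a stale one).

Latitude-driven variables (SST, SSH) are detrended with a locally linear
loess on latitude (degree 1, span 0.75); the anomaly is the value minus
the fitted trend and represents local dynamic structure rather than the
planetary heating gradient. Note loess is a linear smoother but not a
projection, so detrending is exactly idempotent only for noiseless
trends; on noisy series a second pass moves the anomalies by a fraction
of a percent of their scale.

Collinearity: pairwise Pearson correlations on pairwise-complete rows
(listwise deletion would waste data under cloud cover); pairs with
|r| ≥ 0.7 are resolved by dropping the member with the lower
single-predictor logB, iterating until no flagged pair remains.

## Classification assessment

The continuous ARS likelihood is binarized at the cutoff maximizing
TSS = TPR + TNR − 1, scanning all distinct estimate values plus 0 and 1
with the closed rule "present iff estimate ≥ cutoff"; ties take the
lowest cutoff (favoring sensitivity, and deterministic). Rows without an
estimate (unpopulated neighborhoods) are excluded from every denominator
and their count reported — this is why a model fitted to *n* rows can
report a confusion matrix totalling fewer. The suite: confusion cells,
TPR/TNR/FPR/FNR, TSS, observed and predicted prevalence, accuracy,
precision, AUC (pairwise concordance with half ties, identical to the
trapezoidal ROC integral), RMSE, and the Brier score (= RMSE², the mean
squared residual). Undefined ratios (zero denominators) are reported
missing rather than silently zero.

## Spatial autocorrelation diagnostics

The weighted-averaging estimator accounts for spatial autocorrelation
implicitly: the response at a location is estimated from responses at
environmentally neighboring locations. To make the spatial structure
visible, `npmr_spatial()` fits a purely spatial (longitude × latitude)
model — both predictors forced, tolerances scanned jointly — and
`compare_npmr()` contrasts its neighborhood sizes and predictions with
the environmental model's, row by row and through sample variograms.
The ratio of the axis tolerances (percent of range) expresses the
anisotropy of the tracking data's spatial structure.

Variograms use the classical Matheron estimator
$\gamma(h) = \sum_{pairs}(z_i-z_j)^2 / (2N(h))$ with great-circle pair
distances (lags are in km across ~17° of latitude, so Euclidean degrees
would distort), default 20-km bins to 500 km, both exposed. No variogram
model is fitted — the sample variogram is the diagnostic.

## The synthetic-data generator

The simulator inverts the analysis: it generates tracks from a known
behavior–environment link so the pipeline can be asked to find it.

* **Fields.** Chlorophyll (lognormal, richer inshore), SST (deterministic
  latitudinal trend, default −0.45 °C per degree, plus a correlated
  anomaly), a static shelf bathymetry, and an aspect-like EASTNESS field
  in [−1, 1]. Anomalies are stationary Gaussian random fields sampled by
  2-D circulant embedding (FFT; exact up to clamping of tiny negative
  embedding eigenvalues), with Gaussian covariance parameterized by the
  *practical range* — the distance at which the semivariance reaches 95%
  of the sill (default 150 km). A configurable fraction of satellite
  cells (default 15%) is masked missing to emulate cloud cover and
  exercise the extraction's missing-data path. A "warm regime" switch
  (+1.5 °C, chlorophyll × 0.6) emulates the warm, low-productivity years
  used for cross-regime validation.
* **Tracks.** A discrete-time two-state correlated random walk with
  gamma-distributed daily steps (shape 4): transiting at mean 81.5 km/day
  with near-persistent headings (wrapped-normal increments, SD 0.3 rad),
  ARS at mean 27.3 km/day with near-uniform turning. Each day's ARS
  probability is a configurable link evaluated on the local field values
  (default: a saturating logistic in log-chlorophyll), blended with a
  persistence term (default 0.25) for behavioral stickiness. The heading
  persistence, step shape, persistence level and link form are free
  parameters of the simulator chosen once for realism — the source
  analyses report no turning-angle magnitudes to match.
* **Observation model.** The continuous mode value is the true state ±
  uniform(0, 0.2) noise folded inward (so thresholding at 1.25/1.75
  recovers the true state exactly), except 10% of locations drawn inside
  the uncertain band to exercise that filter branch. Credible-box
  half-widths are lognormal (median 30 km), occasionally exceeding the
  100-km filter.

Defaults reproduce the study conditions: 72 whales × 25 days (~1800
locations), 55/18 whales in the building (cool-regime) and validation
(warm-regime) years, a 12° × 19° coastal domain at 0.25° resolution.

What passing tests on this generator do **not** show about real data: the
simulator has no Argos error structure or duty cycles, no real
bathymetry, prey fields, or memory-driven site fidelity; its behavioral
link is stationary and known. Recovery of the link by the pipeline
demonstrates correctness of the machinery, not ecological validity of
any particular fitted model.

## Numerical choices and problem sizes

* Likelihood clamping at $\varepsilon = 1/(2\,SU)$; n_min fixed-point
  tolerance 1e-10; tuning stops below 0.01 logB per sweep.
* Ties in tolerance scans resolve toward larger tolerances (smoother
  models); ties in model size toward fewer predictors; TSS-cutoff ties
  toward the lowest cutoff.
* Geographic steps in the simulator convert km to degrees with the local
  metric (1° lat = 111.32 km, longitude scaled by cos(lat)); analysis
  distances use the haversine on a 6371-km sphere.
* The test suite sizes its simulations for desk-scale runtimes while
  keeping estimates stable: oracle-equivalence tables of 20–50 rows,
  selection/calibration studies of 20 seeded replicates at 150–1400
  rows, variogram recovery from 2000 sampled cells per seed, and an
  end-to-end pipeline at 12 + 5 whales; the bundled demo runs the full
  55 + 18-whale configuration. Stochastic test bounds (e.g. the
  white-noise variogram flatness margins) were frozen from 40-replicate
  oracle studies of the corresponding estimator at the test's sample
  size.

## Known limitations

* Only the local-*mean* NPMR variant with a binary response is
  implemented (no local-linear or local-logistic variants, no
  quantitative responses).
* The free search is stepwise, not exhaustive; with strongly
  interacting predictors it can stop at a local optimum — the tuning
  pass mitigates but does not eliminate this.
* The randomization test reruns the search per replicate and is the most
  expensive operation; its cost scales with candidates × grid ×
  replicates × n².
* Grid I/O uses a plain-text CSV container with axis metadata rather
  than binary NetCDF; the in-memory contract (regular axes, optional
  time, missing cells) is the same.
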