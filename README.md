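# arsnpmr

Habitat analysis of satellite-tracked whale movement with **nonparametric
multiplicative regression (NPMR)**.

Satellite telemetry of foraging whales is typically post-processed by a
switching state-space model into one location per day, each carrying a
continuous behavioral-mode value in [1, 2] (1 = transiting, 2 =
area-restricted search, "ARS") and a 95% credible-limit box. `arsnpmr`
takes it from there: it links the presence/absence of ARS behavior — a
proxy for foraging — to oceanographic predictors (chlorophyll,
temperature, bathymetry, ...), validates the fitted model across climatic
regimes, converts the continuous ARS likelihood into a binary
classification at the skill-maximizing cutoff, and diagnoses how much
spatial autocorrelation the environmental predictors absorb. A paired
simulator generates tracks and environmental fields with known ground
truth so every stage is testable without any data download.

## The model

NPMR is a local-mean kernel regression in which univariate weights are
combined **multiplicatively**. For target row *t* and neighbor *i*,

    w_ti = prod_j exp( -(x_tj - x_ij)^2 / (2 sigma_j^2) )

over continuous predictors *j* (times an exact-match indicator for
categorical predictors such as individual). The standard deviation
`sigma_j` is the predictor's **tolerance** — its smoothing scale. The
estimated likelihood of ARS at *t* is the leave-one-out weighted mean of
the binary response:

    yhat_t = sum_{i != t} w_ti y_i / n*_t ,   n*_t = sum_{i != t} w_ti

`n*` is the **neighborhood size**; rows with `n* < n_min = 0.25 * N_ave`
receive no estimate. Fit quality is the base-10 log likelihood ratio
against the naive model that predicts the observed prevalence everywhere:

    logB = sum_t log10[ L(y_t | yhat_t) / L(y_t | prevalence) ]

with `B_ave = 10^(logB/SU)` the average per-location contribution,
`xR2` the cross-validated pseudo-R², and `chi^2 = 2 ln(10) logB`.
Models are built by free stepwise search over candidate predictors and a
tolerance grid, refined by local tuning, and assessed by bootstrap
(logB interval) and a shuffled-response randomization test. Binary skill
uses the true skill statistic `TSS = TPR + TNR - 1`, maximized over
cutoffs, plus AUC, RMSE and the Brier score.

## Worked example

```r
library(arsnpmr)

# simulate study-scale inputs and run the whole analysis
cfg <- demo_run_config("demo", seed = 1)
rep <- run_pipeline(cfg)

# the selected environmental model
print(rep$env_fit)
```

```
NPMR local-mean model (binary response)
Predictors: CHL x DEPTH x SST
Tolerances:
  CHL        0.06425 (2% of range)
  DEPTH      281.6 (15% of range)
  SST        3.655 (38% of range)
SU = 711, N_ave = 41.55, n_min = 10.39
logB = 27.22, B_ave = 1.09, xR2 = 0.17, r = 0.41, chisq = 125.37
```

The free search picked chlorophyll (the variable that actually drives the
simulated behavioral switch) with a tight tolerance, plus depth and
temperature; 711 of the filtered building locations have populated
neighborhoods (average size 41.6 effective neighbors) and the model beats
the naive prevalence model by 27.2 orders of magnitude of likelihood
(`B_ave` = 1.09: each location contributes ~9% improvement).

```r
# classification at the TSS-optimal cutoff (building set)
print(classification_report(rep$env_fit$y, fitted(rep$env_fit)))
```

```
Classification at cutoff 0.507 (TSS = 0.35)
          predicted
observed   absence presence
  absence      252       93
  presence     138      228
cutoff: 0.506562
prevalence obs/pred = 0.51/0.45  accuracy = 0.68  precision = 0.71
AUC = 0.73  RMSE = 0.46  Brier = 0.21  (n = 711, 64 excluded)
```

```r
# movement scales recovered from the filtered tracks
print(movement_stats(rep$points), digits = 3)
```

```
        mode n_pairs mean_km median_km mean_kmh median_kmh
1        ARS     400    27.0      25.0     1.12       1.04
2 transiting     409    80.0      76.1     3.34       3.17
3    overall     809    53.8      40.2     2.24       1.68
```

The per-mode daily displacements recover the simulator's configured
transiting/ARS step scales of 81.5 and 27.3 km/day.

`run_pipeline()` also writes every intermediate artifact (filter logs,
the extracted sample table, search results, TSS and response curves,
variograms of neighborhood sizes and predictions for the environmental
and the purely spatial model, and a `summary.json` with the full
statistic suite for all four fits) under `cfg$out_dir`. A thin CLI over
the same functions lives at `inst/cli/arsnpmr.R`
(`Rscript arsnpmr.R demo --dir DIR --seed 1`).

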