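# frontdive

Tools for linking the dive behaviour of central-place foraging seabirds to
thermal ocean fronts. The package covers the full analysis chain for a
GPS + time-depth-recorder (TDR) tracking study of a plunge-diving seabird
(the motivating system is northern gannets breeding in a shelf sea):

* **Dive processing** — detect dives (depth ≥ 1.5 m) in 1 Hz continuous or
  10 Hz depth-triggered TDR traces, segment the active swim phase from
  vertical depth gradients, and classify dives as V-shaped plunges or
  U-shaped pursuit dives (swim phase ≥ 3 s at 1 Hz, ≥ 4 s at 10 Hz).
* **Track processing** — strip civil-night fixes, remove activity within
  2 km of the colony, split foraging trips, interpolate tracks to 1 s with
  cubic splines, geolocate dives (mismatches > 1 s excluded), and flag
  dives within 10 km / 1 h of a fishing vessel.
* **Front mapping** — single-image edge detection on SST rasters
  (32 × 32 px frames, 0.4 °C threshold), 7-day composite front maps, and
  the three metrics *Gdens* (smoothed front gradient density, Gaussian
  filter of width 5 px), *Fdist* (distance to the nearest simplified
  front) and *Ffreq* (seasonal percentage of clear observations with a
  frontal gradient ≥ 0.04 °C).
* **Habitat use** — population 95% kernel utilization distribution, five
  pseudo-absences per dive sampled inside it, and per-metric
  use-availability tables.
* **Inference** — binomial mixed models with a complementary log-log link
  fitted by penalized quasi-likelihood (`Dive event (0/1) ~ metric × Sex +
  (1|Bird)`), linear mixed models for dive depth/duration
  (`~ metric × Sex + DecTime + DecTime²`), CI-based model reduction and
  AIC/LRT selection, AUC, marginal pseudo-R² (latent residual variance
  π²/6 for cloglog), and bootstrap prediction curves.
* **Synthetic data** — generators for SST scenes with a parametric front
  and clumped cloud, central-place foraging tracks, depth traces with
  known dive truth, and use-availability tables drawn from known
  coefficients, so every stage is testable end to end with no downloads.

The model at the core of the habitat analysis is

> P(dive | x) = 1 − exp(−exp(β₀ + β₁·Sex + β₂·metric + β₃·Sex·metric + b_bird)),
> b_bird ~ N(0, σ²)

fitted to a 1 presence : 5 pseudo-absence design by PQL (working-response
iteration with an `nlme::lme` mixed step), with Wald z intervals.

## Worked example

Simulate a use-availability table from known coefficients and recover them:

```r
library(frontdive)

d <- simulate_use_availability(
  true_betas = c(-2.675, -0.133, 2.402, -5.593), # int, sexF, Gdens, sexF:Gdens
  n_birds = 50, dives_per_bird = 40, sigma_bird = 0.5, seed = 1
)
fit <- fit_binomial_glmm(d, response ~ Gdens * sex)
tidy(fit)
#> # A tibble: 4 × 6
#>   term            estimate std.error conf.low conf.high   p.value
#>   <chr>              <dbl>     <dbl>    <dbl>     <dbl>     <dbl>
#> 1 (Intercept)       -2.73      0.115   -2.96     -2.51  8.30e-126
#> 2 Gdens              1.91      0.389    1.14      2.67  9.40e-  7
#> 3 sexfemale         -0.158     0.165   -0.481     0.164 3.36e-  1
#> 4 Gdens:sexfemale   -5.63      0.951   -7.50     -3.77  3.12e-  9
glance(fit)
#> # A tibble: 1 × 7
#>   n_obs n_birds sigma_bird sigma_resid   auc pseudo_r2 converged
#>   <int>   <int>      <dbl>       <dbl> <dbl>     <dbl> <lgl>    
#> 1 12000      50      0.501        1.64 0.681      6.28 TRUE
```

Every true coefficient lies inside its 95% CI: the positive male Gdens
slope (1.91, truth 2.402) and the strongly negative female interaction
(−5.63, truth −5.593) are recovered, the bird-level standard deviation
(0.501, truth 0.5) almost exactly. `pseudo_r2` is the marginal variance
explained by the fixed effects in percent, `auc` the rank-statistic area
under the ROC curve of the fitted probabilities.

The full synthetic pipeline — scenes → dives → tracks → front metrics →
use-availability tables → fits → descriptive report — runs with:

```r
out <- run_pipeline(default_config(), out_dir = "pipeline_out", seed = 1)
out$report          # trips, dive rates, inter-dive intervals, U/V split, ...
out$manifest$filters # record-conservation ledger for every filter
autoplot(out$metrics$Gdens)
```

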