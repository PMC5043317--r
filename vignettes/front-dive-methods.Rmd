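---
title: "Methods: thermal-front metrics and seabird dive behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-front metrics and seabird dive behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frontdive)
```

## The question and the pipeline

Plunge-diving seabirds such as gannets forage from a central colony over
shelf seas where thermal fronts — boundaries between water masses with strong
horizontal SST gradients — concentrate prey. `frontdive` implements the full
chain needed to ask whether such a predator (i) preferentially dives near
fronts, (ii) switches dive strategy there, and (iii) changes dive depth or
duration there:

1. **Dive processing** — detect dives in time-depth recorder (TDR) traces,
   segment the active swim phase, classify dives as V-shaped plunges or
   U-shaped pursuit dives, and summarize dive activity.
2. **Track processing** — filter GPS fixes (civil night, 2 km colony
   buffer), split tracks into foraging trips, interpolate trips to 1 s with
   cubic splines, geolocate each dive, and flag dives near fishing vessels.
3. **Front mapping** — detect thermal fronts in SST scenes by single-image
   edge detection (SIED) and derive three metrics: 7-day composite front
   gradient density (*Gdens*), distance to the nearest simplified front
   (*Fdist*), and seasonal front frequency (*Ffreq*).
4. **Habitat use** — estimate the population's 95% kernel utilization
   distribution (UD), draw five pseudo-absences per dive inside it, and
   assemble use-availability and dive-level model tables.
5. **Inference** — binomial mixed models with a complementary log-log link
   estimated by penalized quasi-likelihood (PQL) for dive probability and
   dive shape; linear mixed models for depth and duration; model
   reduction/selection; AUC, marginal pseudo-R², and bootstrap prediction
   curves.
6. **Synthetic data** — a generator with known ground truth for every stage,
   so the entire pipeline is testable without any satellite or tag download.

`run_pipeline()` wires these together on the synthetic scenario and audits
every filter in a record-conservation manifest.

## Dive detection and classification

A dive is a maximal run of samples at or below **1.5 m** depth. That
threshold matches the recording logic of triggered archival loggers (which
only log below 1.5 m), so continuously sampling (1 Hz) and triggered (10 Hz)
dialects yield comparable dive sets; it also removes bathing and other
subsurface noise. Durations run from the first to the last suprathreshold
sample plus half a sampling interval at each end, so sub-second 10 Hz dives
are representable. Triggered bursts separated by less than 1 s are merged
(pressure chatter at the recording threshold).

The **active swim phase** is found from gradients in the vertical change in
depth. Per-interval vertical velocity is thresholded at `v_active` = 0.4
m/s: ballistic plunge descents run at roughly 2 m/s and passive ascents near
1.5 m/s, while wing-propelled swimming along the bottom of a pursuit dive
stays well below 0.4 m/s, so the threshold separates the regimes with a wide
margin on both sides. Sub-threshold intervals form bottom-phase candidates;
candidate runs separated by short super-threshold gaps (bottom wobble) are
merged, and the run containing the deepest sample is the swim phase.

Two numerical refinements matter and are deliberate design choices:

* **Dialect-adaptive smoothing.** At 1 Hz no depth smoothing is applied
  (sensor noise contributes only ~0.07 m/s to interval velocities); at
  10 Hz a 7-sample (0.7 s) moving average is used, because raw 10 Hz
  interval velocities carry ~0.7 m/s of noise that would shred the bottom
  phase into fragments. Smoothing delays the detected run boundaries
  inward by about half the window, which is compensated explicitly.
* **Sub-sample boundary refinement.** At 1 Hz the boundary-straddling
  interval is split by the fraction of it spent at ballistic speed (with
  the reference plunge speed floored at 1 m/s, since a single partial
  descent sample under-represents the true rate on shallow dives); at
  10 Hz each boundary is the intersection of a line fitted to the
  ballistic limb and a line fitted to the bottom phase, which is exact on
  clean profiles regardless of sampling phase and noise-robust because
  each line pools many samples.

With these defaults the swim phase of a noise-free simulated pursuit dive is
recovered to within one sampling interval at both rates, which is what makes
the classification rule sharp: **U-shaped iff the swim phase is at least 3 s
(1 Hz) or at least 4 s (10 Hz)**, ties classifying as U ("at least").

## Track processing

Civil night (solar elevation below −6°, computed with the NOAA solar
position algorithm at each fix's own longitude/latitude — relevant at
foraging ranges of 100+ km) is stripped, all activity within 2 km of the
colony is removed, and trips are maximal runs of fixes outside that buffer;
a trip that never returns to the buffer (battery exhaustion, record end) is
flagged incomplete. Projected x(t) and y(t) are interpolated separately with
natural cubic splines at 1 s; gaps longer than 30 min (e.g. stripped nights)
break the spline into separately fitted segments so it cannot swing across
unobserved intervals, and segments with fewer than 4 fixes fall back to
linear interpolation with a warning. Dives take the dense-track position at
their start timestamp; allocations mismatched by more than 1 s are excluded
and counted, as are dives starting in civil night (the boundary counts as
day). All projections use UTM (WGS84) in the colony's zone, implemented
in-package and validated against independent geodesic distances.

## Front mapping

**SIED.** Each SST scene is scanned with half-overlapping 32 × 32 pixel
frames (~1.1 km pixels). In a frame with at least 25% cloud-free pixels the
SST values are split at the threshold maximizing the between-population
separation; a front is accepted when the two populations differ by at least
**0.4 °C**, each holds at least 25% of the valid pixels, and both are
spatially cohesive (≥ 0.90 of neighbour pairs same-population). Frontal
pixels are valid pixels adjacent to the population boundary; each carries
the central-difference SST gradient magnitude in °C/km. The window size and
0.4 °C threshold are the published constants of the method; the split
criterion, population-size floor, cohesion bound and half-window stepping
follow the edge-detection literature and are exposed as arguments.

**Composites.** Detections over a 7-day window centred on the date of a
fix are combined: frontal flags by union, per-pixel gradients by the mean
over the days the pixel was frontal. Pixels cloudy on all 7 days stay
missing and exclude dependent records downstream.

**Gdens** is the composite gradient (zero at valid non-frontal pixels)
convolved with a normalized Gaussian kernel. "Width of five pixels" is
interpreted as the full width at half maximum (FWHM = 5 px, σ ≈ 2.12 px) —
the common meaning of a filter "width" — with σ = 5 px available via
`width_is_fwhm = FALSE`. Missing pixels are excluded by mask-normalized
convolution; on a cloud-free interior the kernel sums to one, so total
gradient mass is conserved.

**Simplified fronts** trace continuous contours through the strongest
smoothed frontal pixels. The clustering step is unspecified in the front
mapping literature at the level of an algorithm, so a deterministic,
testable stand-in is used: threshold Gdens at the 75th percentile of its
positive values, thin the suprathreshold region to one-pixel ridges
(Zhang–Suen), link 8-connected ridge pixels into polylines, and drop
polylines shorter than 10 px (~11 km). **Fdist** is then the Euclidean
distance (projected km) to the nearest polyline segment; with no fronts in
the window the metric is missing and dependent records are excluded.

**Ffreq** uses the pre-smoothing detections of a June–August season: per
pixel, the percentage of *clear-sky* observations in which the pixel was
frontal with a gradient of at least **0.04 °C** (per pixel scale). The
denominator is deliberately clear-sky observations rather than all scenes —
a pixel should not be penalized for having been unobservable — and is
switchable only by constructing the counts from the returned
`n_detections`/`n_observations` rasters; this choice should be kept in mind
when comparing against maps built with a total-scenes denominator.

## Habitat use

The UD is a bivariate Gaussian kernel density of all filtered at-sea GPS
fixes pooled across birds — availability means "accessible at-sea area for
this population", not just the dived locations — on the UTM plane, with
per-axis normal-reference (Silverman) bandwidths as the default since the
original kernel settings are not recoverable. The 2 km colony buffer (and
any supplied land polygon; the synthetic scenario is all sea) is clipped
out before thresholding, and the 95% isopleth is the density level whose
cells enclose 95% of the remaining mass (attained mass within
[0.949, 0.951] by construction on a 256² grid). Five pseudo-absences per
dive are drawn uniformly inside the isopleth; each inherits its parent
dive's bird, sex, timestamp and vessel flag, so that time-varying 7-day
composites can be sampled for absences on the parent dive's date (the
alternative — absences without timestamps — would make the use and
availability samples incommensurable for Gdens/Fdist). Records missing a
metric are dropped per metric, and every exclusion is counted.

`DecTime` is the fraction of the UTC day in [0, 1); the quadratic term is
computed on the centred value, `DecTime2 = (DecTime − 0.5)²`, which reduces
collinearity between the linear and quadratic terms. The fitted
time-of-day curve is identical; only the intercept's interpretation shifts.

## Inference

**Dive probability and dive shape** are binomial GLMMs with a cloglog link
— the natural link for the asymmetric 1:5 use-availability design — and a
random bird intercept, estimated by PQL: iterate a weighted working
response, fit it as a linear mixed model (`nlme::lme`, optionally with a
spatial `corExp(~x+y|bird)` or temporal `corCAR1(~t|bird)` residual
structure nested in bird), and stop when no fixed effect changes by more
than 10⁻⁶ (max 50 iterations; non-convergence is flagged, never silent).
With `random = NULL` the loop is exactly iteratively reweighted least
squares, i.e. a plain GLM — the degenerate case used as an oracle check.
PQL coefficients on binary data are method-sensitive at the second decimal
relative to ML/Laplace estimates; that is inherent to the estimator, and
`MASS::glmmPQL` is used as an independent cross-check in the test suite,
never as the implementation.

Because PQL has no true likelihood, the binomial models are reduced, not
AIC-selected: the least significant droppable term whose 95% CI (estimate
± 1.96 SE, Wald z) passes through zero is removed and the model refitted,
interactions before the main effects they contain, the intercept never.
**Depth and duration** LMMs are selected backwards-and-forwards under ML:
drops must be confirmed by a likelihood-ratio test (p > 0.05; candidate
AICs are recorded in the trace), re-additions need both AIC support and
LRT significance (which also makes the procedure terminate), and the final
model is refitted with REML. A purely AIC-driven backward pass was
rejected because it retains pure-noise terms at the well-known ~16% rate,
which defeats the purpose of reduction in this low signal-to-noise
setting.

**Evaluation.** AUC is the Mann–Whitney rank statistic of fitted
probabilities versus outcomes (invariant to monotone transforms; verified
against an O(n²) pairwise oracle). The marginal pseudo-R² is
var(Xβ) / (var(Xβ) + σ²_bird + σ²_resid), with the latent residual
variance π²/6 for the cloglog link, reported in percent. Prediction curves
for an "average bird" (random effect zero) carry 95% bands from a
nonparametric bootstrap that resamples birds with replacement and refits.
The vessel sensitivity re-analysis refits the use-availability model with
vessel-associated dives *and their five pseudo-absences* removed, and the
dive-characteristic models with a two-level vessel factor added, reporting
sign and significance agreement.

## The synthetic generator: what it does and does not emulate

* **SST scenes**: a two-water-mass field with a parametric front
  (temperature step ΔT across a sigmoid transition a fraction of a pixel
  wide, optional day-to-day drift), Gaussian pixel noise, and cloud as
  thresholded smoothed Gaussian random fields — spatially clumped, like
  real cloud, not i.i.d. pixels. Defaults: ΔT = 1.2 °C (a strong shelf
  front, three times the detection threshold), noise 0.05 °C, 25% cloud.
* **Tracks**: correlated random walks from the colony with an outbound and
  a homeward-biased return phase, 1-min fixes, ~35 km/h, default maximum
  range 140 km (σ 30 km) and ~23 h trips spanning day and night (the
  pipeline scenario uses 80 km trips so they fit inside its raster).
* **Depth traces**: V dives descend at 2 m/s and ascend at 1.5 m/s with no
  bottom time; U dives hold the scheduled swim phase at the bottom with a
  smooth, bounded ±0.3 m wobble that tapers to zero at the phase edges;
  surface and sensor noise are 0.05 m. The kinematic rates are
  order-of-magnitude plausibilities, not estimates of gannet kinematics,
  and are configurable. Scheduled dives respect two identifiability constraints:
  U swim phases are at least 5 s (one second above the stricter dialect
  threshold) so shape truth is unambiguous, and maximum depths are at
  least 2.5 m so every scheduled dive spends at least one 1 Hz sample
  above the 1.5 m recording threshold and is observable by both dialects.
* **Use-availability tables**: outcomes drawn directly from the cloglog
  model, with each bird contributing `dives_per_bird` clusters of six
  candidate rows (1 presence : 5 absence design) and a Normal(0, σ²)
  bird intercept; σ_bird defaults to 0.5, a realistic between-bird spread
  on the cloglog scale for a colony sample. One global seed fans out to
  per-component substreams, so regenerating one stage never perturbs
  another, and fixed seeds are bitwise-reproducible.

Passing tests on these data show the *algorithms* are correct under known
truth; they do not show that real gannet dives lack prey-capture wiggles,
that AVHRR SST is unbiased, or that real fronts are sigmoid steps. Device
effects (pressure drift, GPS error beyond spline smoothing), diel prey
migration and behaviourally realistic prey fields are out of scope.

## Problem sizes and numerical conventions

The shipped test-and-acceptance battery uses 200 mixed-dialect traces of 6
dives for detection/classification; 64² step-edge scenes (ten for recall,
five at 0.3 °C for the threshold rule); 100 replicates of the 50-bird ×
40-cluster recovery study (coefficient truth taken from the dive-probability
model's reported Gdens coefficients); and a 2-bird, 96²-pixel end-to-end
pipeline for the design invariants — sizes chosen so the whole battery runs
in a few minutes on one core while keeping Monte-Carlo error well inside
the asserted bands. Other conventions: depths are positive downward with
the surface at 0; timestamps are UTC throughout (local solar time exists
only inside the twilight computation); distances are great-circle for
lon/lat and Euclidean on the UTM plane; CSV output uses ISO-8601
timestamps, '.' decimals and empty missing fields; rasters are written as
long-format CSV and fronts/polygons as GeoJSON (plain-text formats chosen
for lossless, dependency-light round-tripping).

## Known limitations

* PQL is the estimator of record here; its small-cluster bias on binary
  data means coefficients should not be compared to Laplace/AQ fits at
  more than two decimals.
* The simplified-front stand-in (percentile + skeletonization + linking)
  is deterministic and testable but is not the original clustering
  implementation; Fdist values near junction-rich front networks depend
  on it at the one-pixel scale.
* The Ffreq denominator (clear-sky) and the UD bandwidth (normal
  reference) are defensible defaults for unrecoverable upstream choices;
  both are surfaced in the API rather than buried.
* Trips are delimited by buffer crossings; brief colony visits that stay
  outside 2 km do not split a trip.
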