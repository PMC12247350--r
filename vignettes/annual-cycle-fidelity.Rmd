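---
title: "Annual-cycle site fidelity and migration repeatability from satellite telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annual-cycle site fidelity and migration repeatability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trackfidelity)
```

## The scientific problem

Multi-year satellite tracks of individual migratory birds let us ask how
*consistent* an individual is — in where it goes, and in when it goes
there — across repeated annual cycles. The biological pattern of interest
here is stage-specific site fidelity: a bird may return to the same
wintering site every year yet choose a fresh breeding site each summer
(exploratory breeding dispersal), and the timing of its migration may be
repeatable near some parts of the annual cycle and flexible near others.

`trackfidelity` implements the full chain from raw Argos Doppler fixes to
those quantities:

1. **speed filtering** of implausible fixes,
2. **residency clustering** with a spatio-temporal DBSCAN,
3. **home ranges** as 90% kernel utilization distributions and
   **between-year fidelity metrics** (overlap proportion, minimum
   centroid distance),
4. **regularized migration tracks** and a population **mean route**,
5. per-latitude-band and per-event **repeatability** (intraclass
   correlation) with parametric-bootstrap confidence intervals,
   boundary-corrected likelihood-ratio tests and FDR control,
6. **mixed-model comparisons** of fidelity across the four annual stages.

Because real tracking data cannot ship with the package, a first-class
synthetic generator produces Argos-like multi-year tracks with known
ground truth; every stage of the pipeline is validated against that truth
or against independent oracles.

## The statistical core

### Repeatability

For a timed or spatial variable measured on the same individuals in
several years, repeatability is the intraclass correlation from the
one-way random-intercept model

$$ y_{ij} = \mu + \alpha_i + \varepsilon_{ij}, \qquad
   \alpha_i \sim N(0, \sigma^2_{id}), \;
   \varepsilon_{ij} \sim N(0, \sigma^2_{res}), $$

$$ R = \frac{\sigma^2_{id}}{\sigma^2_{id} + \sigma^2_{res}}. $$

`fit_random_intercept()` estimates the components by REML. Rather than
calling a general mixed-model optimizer, the model is profiled: for a
fixed variance ratio $\gamma = \sigma^2_{id}/\sigma^2_{res}$ the GLS mean
and the residual variance are closed-form, leaving a one-dimensional
optimization over $\gamma \ge 0$. The tests check agreement with
`lme4::lmer()` to six significant figures on unbalanced designs and with
the balanced one-way ANOVA decomposition to 1e-6. The profiled form
matters because the parametric bootstrap (`repeatability()`,
`n_boot = 1000` by default, raiseable to the 1e5 scale by configuration)
and the calibration simulations refit this one tiny model hundreds of
thousands of times.

Confidence intervals are percentile intervals over parametric-bootstrap
refits (data regenerated from the fitted model on the observed design).
Significance of $\sigma^2_{id} = 0$ uses the REML likelihood-ratio
statistic against the boundary-corrected null, the equal mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, because the variance is tested on
the edge of its parameter space. Under a true zero variance the
simulated type-I error at $\alpha = 0.05$ stays within [0.01, 0.10]
(tested); with $R = 0.6$, 30 birds and 3 years the mean estimate is
within 0.05 of truth and CI coverage within [0.90, 0.99] (tested).

Two notes on estimator choice. REML (not ML) is used throughout, which
makes the estimate *almost* — not exactly — invariant to duplicating the
data set with cloned individuals; the ML estimator would be exactly
invariant, but REML's fixed-effect correction shifts the result by
O(1/n). And year is not modeled as a crossed effect: the model carries
the individual intercept only.

### Band profiles

Migration timing and route consistency are profiled over 1° latitudinal
bands (low latitudes 8°N to 72°N, 65 bands). For each band:

- **entry date** — the date the interpolated track first enters the band;
- **longitudinal deviation** — for every mean-route point in the band,
  the signed east–west geodesic distance (west negative) from the route
  point to the nearest point of the individual track, averaged within
  the band.

A band is estimated only with data from at least two individuals, and at
least one individual observed in two years; p-values are
Benjamini–Hochberg-adjusted across each profile.

### Stage comparison models

Between-year fidelity per bird, stage and consecutive-year pair is
summarized by two variables:

- **overlap proportion** $= 2A_\cap / (\sum A_x + \sum A_y)$, where
  $A_\cap$ is the area of intersection of the unions of the year-x and
  year-x+1 home ranges and the denominator sums all individual
  home-range areas — 1 for identical ranges, 0 for disjoint ones;
- **minimum centroid distance** — the smallest geodesic distance between
  any pair of cross-year home-range centers.

Stage effects are tested with two mixed models fitted via `glmmTMB`: a
zero-inflated beta model for the overlap proportion (logit P(no overlap)
~ stage; beta mean ~ stage with common precision; bird random intercept
on the conditional part) and a Gaussian model for the centroid distance
(`lme4`, REML, Wald contrasts). Overlap values of exactly 1 are shrunk
to $1 - 10^{-6}$ (the beta support is open) and counted. glmmTMB cannot
share a single random-intercept term between the conditional and
zero-inflation parts, so the bird intercept enters the conditional part
only — the same structure a default glmmTMB zero-inflated fit of these
data would have.

## Geometry and algorithmic choices

**Distances.** All point-to-point distances are geodesics on the WGS84
ellipsoid (`geosphere::distGeo`); a haversine option exists behind a
switch (differences ≲0.6%). Great-circle interpolation between fixes
uses spherical linear interpolation of unit vectors.

**Projection.** Kernel densities and areas are computed in a local
azimuthal equal-area projection centered per cluster group (authalic
radius), which keeps areas faithful at the tens-of-kilometers scale of a
residency cluster. All clusters of one bird × stage share a frame so
their rasters are commensurable for overlap computation.

**Spatio-temporal DBSCAN.** The residency-clustering algorithm is
standard DBSCAN with one change: two fixes are neighbors only when they
are within `eps_m` *and* within `max_lag_d` days of each other
(pairwise temporal gate). This is what makes a revisit to the same site
after a long absence a *new* cluster. The published description names
the temporal parameter without fixing its mechanics; the pairwise gate
was chosen because it reproduces the temporally-distinct-cluster
behavior and admits a brute-force oracle (all-pairs reachability graph +
connected components), against which the implementation is tested for
exact partition equality on 200 random tracks. Border points are
assigned to the earliest core point (in time order) that reaches them,
removing DBSCAN's usual order ambiguity. `maxLag` is interpreted in
days, consistent with tenure being measured in days. Defaults are
MinPts = 3, eps = 4000 m, maxLag = 10 d, with a coarser preset
(5 / 8000 / 20) for birds using larger areas.

**Cluster centers.** The center is the mode of a Gaussian-kernel point
intensity on a grid over the cluster bounding box (the location of
highest probability of occurrence), with ties broken toward the cell
nearest the temporally earliest member fix, so a symmetric two-blob
cluster resolves to the earlier-occupied blob.

**Home ranges.** The utilization distribution is a bivariate Gaussian
product-kernel density with the ad-hoc reference bandwidth per axis
($h = \hat\sigma\, n^{-1/6}$, floored at 100 m for degenerate clusters),
evaluated on a grid padded three bandwidths beyond the data extent with
200 cells on the longer axis. Clusters with fewer than five fixes are
cycled up to five before fitting, since a kernel density on 3–4 points
is otherwise degenerate. The 90% home range is the highest-density
region: cells ranked by density and accumulated to 0.90 mass, so the
contained mass lies in [0.90, 0.90 + one cell). On an isotropic Gaussian
fixture the contour area matches the analytic
$\pi\,\chi^2_{2,0.90}\,\sigma^2$ within the grid tolerance, and halving
the cell size moves the area by under 10% (both tested). Overlap areas
are computed by rasterizing the cell sets onto a common grid at half the
finest cell size; on axis-aligned fixtures the worked overlap cases
(1, 0, 0.5) are exact.

**Track interpolation.** Migration segments are regularized to 15-minute
positions with a correlated-random-walk Kalman smoother (integrated
random-walk velocity model, class-dependent isotropic observation error,
RTS smoothing) in a local plane, with a piecewise-great-circle mode as a
transparent fallback. Positions are valid only when at least two
observed fixes fall within the surrounding 24-hour window, so long
transmission gaps carry no weight; validity is a function of fix
timestamps only. The state-space form was chosen over the original
move-persistence model because only predicted locations — not the
persistence parameter — feed any downstream statistic, and the simpler
smoother is fully specifiable and testable.

**Mean route.** The population mean route is 500 ordered points placed
to minimize the distance to the nearest locations on the individual
tracks. It is initialized as the pointwise average of the tracks
resampled to 500 points by cumulative-distance fraction and refined
iteratively (average of nearest track points, re-spacing, tolerance 1 km
on mean displacement, at most 100 iterations). The route's endpoints are
anchored at the mean track start and end: the nearest-point objective
alone is minimized by contracting all route points into the densest part
of the corridor, and the anchor is what guarantees the route spans the
full course of migration. A step that fails to
improve the objective keeps the previous route, so the objective trace
is non-increasing by construction; the published sources of the
route-averaging idea do not state whether a single pass or a fixed point
is intended, and the iterative scheme is this package's documented
choice. Input tracks are thinned to a 1 km minimum vertex spacing first,
so multi-week stopovers (thousands of near-identical vertices) do not
dominate the averages. With a single input track the mean route is
exactly that track resampled; its residual objective is then just the
resampling granularity (distance from resampled points to the nearest
original vertex), not zero. Nearest-point searches use vertices, not
segment projections: at 15-minute spacing the vertex resolution is
10–20 km in flight, adequate for 1° (~111 km) bands. The deviation
measure pairs each mean-route point with the 2-D nearest track point
(not the same-latitude intercept) — an ambiguity in the source method
resolved here and worth a sensitivity check on real data.

**Seasons.** Stage assignment is polygon-based: a breeding (wintering)
season runs from the first fix inside the range to the last fix inside
it; migrations fill the gaps, directed by the flanking seasons. Boundary
fixes count as inside (closed polygons) — a convention that must be
fixed for reproducibility. Opening or closing a season requires at least
two consecutive in-range fixes, so an isolated gross location error
cannot create or split a season; this automated rule stands in for the
manual screening of clearly erroneous locations that real-data analyses
apply. Cycle-year labels use the calendar year in
which an interval starts; since a winter spans the new year as one
interval, nothing is split, and "wintering year y" naturally pairs with
"wintering year y+1" for fidelity records. Birds that never enter the
known wintering range fall back to cluster-based wintering: the season
starts at the first residency cluster overlapping the configured
wintering calendar window (default 1 November – 1 March, a choice the
source leaves unquantified) and ends at the onset of the first sustained
northward flight (≥100 km poleward within 24 h, both configurable).
Migration bounds are anchored on the longest-tenure residency cluster
inside each range (ties: more fixes, then earlier start) — so the
"breeding site" of a year is its longest-held residency.

## The synthetic study

`generate_population()` emulates an Arctic-breeding, two-flyway shorebird
population:

- **wintering**: one site per bird, drawn once inside the wintering
  range and reused every year with 3 km jitter (strong fidelity);
- **breeding**: a fresh site each year from a Gaussian dispersal kernel
  (sd 127 km per axis, implying ~159 km mean consecutive-year
  displacement for an unbounded kernel; resampling against the range
  boundary truncates the realized mean somewhat below that);
- **southward migration**: 1+ stopovers on the great circle toward the
  wintering site with cross-track jitter, constrained to the
  33.5–60°N staging belt, the first being an extended molt-staging stop
  absorbing ~70% of the staging time (realized staging averages roughly
  two months at mid-latitudes), followed by a slow final approach of
  exponentially distributed extra duration (mean 6 d) — so the end of
  staging is not a deterministic offset of the wintering arrival date;
- **northward migration**: at least one short stopover that absorbs the
  time between wintering departure and the target breeding arrival;
- **timing**: each range event (arrival/departure × breeding/wintering)
  follows population mean + bird intercept + annual noise, with
  per-event configurable sigmas, so true repeatability
  $R = \sigma^2_b/(\sigma^2_b+\sigma^2_w)$ is known exactly;
- **sampling and error**: fixes arrive in transmission bursts (mean 1.5
  fixes within 30 min of each duty-cycle uplink, default every 6 h);
  every fix gets an Argos class drawn i.i.d. from the configured class
  distribution and isotropic Gaussian error with the class sd (defaults
  150 m–4 km, inside the published envelope for these transmitters —
  per-class magnitudes are configuration, not truth); 2% of fixes are
  gross errors with 25× the class sd, which is what gives the speed
  filter something to do.

The reference study (`study_sim_config()`) uses 20 birds × 3 cycles with
wintering-anchored timing: between-individual sd 10 d at wintering
arrival against 3 d at the breeding events (within-individual sd 6 d
throughout), so true timing repeatability peaks at the wintering area
(0.74 there, 0.20 at breeding). Spatial route repeatability is not
imposed; it *emerges* — near the wintering grounds every bird funnels
toward its own fixed site (high between-, low within-individual
variance), while near the breeding grounds each year's route targets a
new breeding site (high within-individual variance) — and the pipeline
recovers the rising-toward-wintering profile from the fixes alone.

What the generator does **not** emulate: heavy-tailed (non-Gaussian)
Argos error beyond the gross-error mixture, duty-cycle seasonality, tag
failure and mortality, environmental covariates of timing (snowmelt,
predation), flyway-specific corridors beyond a longitude split, and
within-season foraging movement structure. Passing tests on synthetic
data therefore demonstrate the *statistical machinery* and its
calibration, not the behavior of any real population; real-data
idiosyncrasies (manual outlier screening, per-bird clustering parameter
overrides) are supported as configuration but not validated here.

## Problem sizes and numerical settings

The test suite and the acceptance script run desk-scale versions of all
studies: 3-bird populations for recovery properties, 12–20 birds for the
end-to-end contrasts, 200 replicate data sets × 1000 bootstrap
iterations for the repeatability calibration, 200 random tracks for the
clustering oracle. Bootstrap iteration counts are configuration
(`n_boot`); published analyses of this kind use up to 1e5 iterations,
which this implementation sustains because a single refit costs about a
millisecond. Other numerical settings: REML ratio optimized on the log
scale over e^[-12, 12] with tolerance 1e-10 plus an explicit boundary
check at zero; KDE grids of 200 cells per axis; overlap rasters at half
the finest cell size; mean-route tolerance 1 km / 100 iterations;
interpolation validity 2 fixes per 24 h window.

## Known limitations

- The ZIB stage model can fail to converge or give singular fits when a
  stage has no non-zero overlaps and very few records — the pipeline
  reports the fit with its convergence status rather than masking it.
- Longitude averaging in the mean route assumes the corridor does not
  cross the antimeridian (true for the Americas flyways simulated).
- Entry-date repeatability uses day-of-year values; events that
  straddle 1 January within a population would need circular handling.
- The speed filter is greedy-forward (keep the earlier fix); it equals
  the maximal feasible subsequence on tracks with isolated outliers
  (tested against a dynamic-programming oracle) but can differ from the
  global optimum when consecutive fixes are jointly erroneous.
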