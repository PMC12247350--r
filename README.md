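# trackfidelity

Annual-cycle site fidelity and migration repeatability from Argos
satellite telemetry.

Multi-year tracks of individual migratory birds make it possible to ask
how consistent an individual is across years — in *where* it goes
(site fidelity, route fidelity) and in *when* it moves (timing
repeatability) — and whether that consistency differs among the four
stages of the annual cycle: breeding, southward migration, wintering,
northward migration. A recurring pattern in Arctic-breeding shorebirds
is strong fidelity to the wintering area combined with exploratory,
long-distance breeding dispersal; this package implements the complete
analysis chain that quantifies such patterns from raw Doppler fixes.

## What it computes

| Step | Method |
|---|---|
| Data filtering | iterative ground-speed filter (WGS84 geodesic, default 150 km/h) |
| Residency areas | spatio-temporal DBSCAN: neighbors within ε meters **and** maxLag days (defaults MinPts 3, ε 4000 m, maxLag 10 d); clusters kept at tenure > 1 d |
| Home ranges | 90% utilization distribution per cluster — Gaussian-kernel density on a local equal-area grid, highest-density region; < 5-point clusters cycled to 5 |
| Between-year fidelity | overlap proportion `2·A∩ / (ΣAx + ΣAy)` and minimum centroid distance, per bird × stage × consecutive-year pair |
| Migration routes | cluster-center substitution, 15-min correlated-random-walk Kalman smoothing (positions valid only with ≥ 2 fixes per 24 h), 500-point population mean route |
| Repeatability | intraclass correlation `R = σ²id/(σ²id+σ²res)` from a profiled-REML random-intercept fit; parametric-bootstrap CIs; boundary-corrected LRT (½χ²₀+½χ²₁); BH-FDR across each 1°-band profile (8–73°N) and across the seven annual events |
| Stage comparison | zero-inflated beta mixed model for overlap (glmmTMB), Gaussian mixed model for centroid distance (lme4), stage fixed effect + bird random intercept |

A synthetic Argos-track generator (`generate_population()`) with known
ground truth — per-bird wintering sites, yearly breeding-dispersal draws,
stopover itineraries, per-event timing intercepts, class-dependent
positional error with occasional gross errors, duty-cycle bursts — makes
the whole chain testable end to end. See the methods vignette
(`vignettes/annual-cycle-fidelity.Rmd`) for the model details and design
choices.

## Worked example

```r
library(trackfidelity)

cfg <- study_sim_config(seed = 1)          # 20 birds x 3 annual cycles
sim <- generate_population(cfg)
res <- run_pipeline(sim$fixes, cfg$breeding_polygon, cfg$wintering_polygon,
                    pipeline_config(n_boot = 0, seed = 1))

res$summary[, c("stage", "n_residency_areas", "median_home_range_km2",
                "overlap_incidence", "mean_min_center_dist_km")]
#>             stage n_residency_areas median_home_range_km2 overlap_incidence mean_min_center_dist_km
#> 1        breeding                66                101.37                 0                 149.190
#> 2 south_migration               136                102.21                 0                 523.957
#> 3       wintering                76                106.00                 1                   4.528
#> 4 north_migration                48                 98.39                 0                 954.622

res$event_rpt[, c("event", "R")]
#>                     event     R
#> 1        breeding_arrival 0.073
#> 2      breeding_departure 0.188
#> 3       wintering_arrival 0.621
#> 4     wintering_departure 0.487
#> 5    south_stopover_start 0.184
#> 6      south_stopover_end 0.550
#> 7 south_stopover_duration 0.495
```

Reading this: every bird reused its wintering area (overlap in 100% of
year pairs, home-range centers ~4.5 km apart) while no bird's breeding
ranges overlapped (centers ~150 km apart — breeding dispersal); and the
timing of arrival at the wintering area is the most repeatable annual
event (R = 0.62 against a simulated truth of 0.74 at 20 birds), while
breeding-event timing is flexible — exactly the structure the generator
encodes.

The numbered scripts under `analysis/` run the same workflow as a
narrative sequence (simulate → filter/segment/cluster → home ranges →
routes → repeatability → stage models), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter_segment_cluster.R
Rscript analysis/03_homerange_fidelity.R
Rscript analysis/04_routes.R
Rscript analysis/05_repeatability.R
Rscript analysis/06_stage_models.R
```

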