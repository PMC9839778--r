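# beatkit

Quantification of beating-heart time-lapse microscopy, built for studies of
atrioventricular (AV) valve development in the embryonic zebrafish heart.
The package is aimed at researchers who film larval hearts — high-speed
brightfield for blood flow, plane-by-plane GCaMP movies for calcium,
confocal z-stacks for morphology — and need the bespoke measurements those
experiments call for, with a synthetic ground-truth generator so every
stage is testable without raw data.

## What it computes

* **AV flow profile** — per-frame blood-flow classification at the AV
  canal from a midline kymograph: displacement per frame pair by
  normalized cross-correlation with sub-sample (parabolic) refinement and
  ensemble averaging; labels `anterograde` (atrium→ventricle, positive),
  `retrograde`, `no_flow` (|v| below a speed threshold, default 115 µm/s);
  percentages per cardiac cycle averaged over three cycles, plus the heart
  rate from the autocorrelation/periodogram period of the atrial-diameter
  trace.
* **Midline segmentation** — the midline at mid-distance from two traced
  heart walls (computed per chamber, joined at the AV point), divided into
  100 segments proportional to chamber arc length, with per-segment
  diameter (normal-chord wall intersections) and mean fluorescence
  (wall-clipped quadrilaterals), and mean ± SEM aggregation across samples.
* **4D calcium assembly** — retrospective phase alignment of 50 single-plane
  movies (fold to the common beat period, correlate against a
  neighbour-propagated template), integer-frame shifts, maximum
  z-projection, atrial diastole/systole frame selection, and the
  AV-normalized calcium profile along the tube.
* **Valve morphometry** — leaflet lengths and threshold elongation calls;
  valve cell counts with greedy cross-plane deduplication of nucleus
  detections.
* **Statistics** — two-sided Fisher exact test (probability-mass
  convention), Student's/Welch's t, 2^-ΔΔCt qPCR fold changes against a
  reference gene (eef1b2 by convention), and box-plot group summaries.
* **Synthetic beating heart** — seeded generator for brightfield flow
  movies (contracting two-chambered tube with advected, light-absorbing
  blood speckle following a configurable anterograde/retrograde/no-flow
  schedule), calcium plane series with known per-plane phase offsets, and
  static expression stacks — each with exact ground truth.

## Worked example

Simulate a flow movie whose schedule is 70% anterograde, 20% retrograde,
10% no-flow at 300 µm/s (240 fps, 2.5 Hz beat), then run the full pipeline:

```r
library(beatkit)

cfg <- heart_sim_config(seed = 42)
sim <- simulate_brightfield_movie(cfg)
sim$movie
#> <movie_stack> 480 frames, 96 x 160 px, 240 fps, 1.92 um/px

flow_profile_pipeline(sim$movie, sim$annotation)
#> <flow_profile> anterograde 68.6% / retrograde 17.4% / no-flow 13.9% (3 cycles, 150.9 bpm)

unname(sim$truth$true_fractions)
#> [1] 70 20 10
```

The recovered fractions sit within a few percentage points of the
scheduled truth and the heart rate within 1% of the configured
150 beats/min (2.5 Hz × 60). Segment-wise geometry and intensity come from
the same annotation:

```r
segs <- resample_segments(build_midline(sim$annotation), 100)
head(measure_intensity_profile(sim$movie$pixels[1, , ], sim$annotation, segs)[, 1:5], 3)
#>   segment_index arc_position_um chamber diameter_um mean_intensity
#> 1             0        1.020415  atrium    22.59841             NA
#> 2             1        3.061245  atrium    23.22766       65.85015
#> 3             2        5.102075  atrium    24.03791       80.84318
```

The first segment sits at the open inflow end, so its chord misses a wall
and the value is missing by contract. And the statistics, here the
elongation contingency table of 32/34 versus 5/13 larvae:

```r
r <- fisher_exact_two_sided(rbind(c(32, 2), c(5, 8)))
sprintf("p = %.3g, odds ratio = %.1f", r$p_value, r$odds_ratio)
#> [1] "p = 0.000144, odds ratio = 25.6"
```

A thin command-line interface over the same functions ships at
`system.file("cli", "beatkit.R", package = "beatkit")` with subcommands
`simulate`, `flowprofile`, `midline`, `gcamp4d`, `valve` and `stats`.

The methods vignette (`vignettes/beatkit-methods.Rmd`) documents the
models, parameter defaults, simulator design and known limitations.

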