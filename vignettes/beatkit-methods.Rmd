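---
title: "Quantifying the beating zebrafish heart: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the beating zebrafish heart: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatkit)
```

beatkit quantifies time-lapse microscopy of the embryonic zebrafish heart
around the stage when the atrioventricular (AV) valve forms: blood-flow
direction through the AV canal from high-speed brightfield movies, the
heart's 100-segment midline geometry, retrospective 4D assembly of
plane-by-plane calcium imaging, valve morphometry, and the supporting
statistics. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic ground-truth generator does and
does not emulate, and the numerical choices that were genuinely open.

## The AV flow profile

A heart movie (typically 240 frames/s, 1.92 µm/pixel) is reduced to a
kymograph: intensity sampled along the midline within ±20 µm of the AV
point, one line per frame, averaged over a 3-pixel band normal to the
midline. Sample index always increases from atrium to ventricle, so the
sign of between-frame displacement reads directly as flow direction.

Displacement per frame pair is the lag maximizing the normalized
cross-correlation of consecutive kymograph lines, refined to sub-sample
precision by parabolic interpolation of the peak and its neighbours. Two
robustness layers matter in practice:

* **Static-background removal** (`remove_static`): the temporal median of
  each kymograph column is subtracted, so stationary structure such as wall
  shading cannot anchor the correlation at zero lag.
* **Ensemble correlation** (`ensemble`, default 9): the correlation curves
  of 9 consecutive frame pairs are averaged before the peak is picked.
  Single-pair correlations on noisy movies occasionally lock onto spurious
  far peaks; averaging the curves (not the displacements) suppresses them
  while blurring flow transitions by at most ±4 frames, under 4% of a
  cycle at 240 frames/s and 2.5 Hz.

Classification uses two thresholds: a speed threshold (default 115 µm/s,
about a quarter pixel per frame at the standard acquisition settings) below
which a pair is `no_flow`, and a confidence floor (default 0.3) below which
motion is unmeasurable and also scored `no_flow`. When the expected flow
speed of an experiment is known, a threshold near 30% of it separates flow
from jitter; all thresholds are recorded in the outputs. Percentages are
computed over frame pairs (motion is defined between frames), per cycle,
and averaged over the first three complete cycles — the first three because
the choice must be deterministic.

Cycle detection estimates the beat period from the autocorrelation of the
atrial-diameter trace (chamber width at the mid-atrium chord, averaged over
five nearby chords). The first credible autocorrelation peak — the first
local maximum after the zero crossing within 30% of the strongest, not the
global maximum, which can sit on a multiple of the period — seeds a
periodogram maximization that refines the period to sub-frame precision.
Diastole peaks (cycle boundaries) are then placed by fitting the phase of a
cosine at that period, which uses every frame and is robust to local maxima
in the width trace. In brightfield the chord width tracks the dark wall
band on each side within its plausible radial range, so blood speckle
cannot capture the minimum; on max-projected fluorescence movies (which are
speckle-free and filled-bright) it measures the bright-band extent.

## Midline segmentation

Two manually traced wall polylines, inflow to outflow with an AV marker
each, define the geometry. Within each chamber — split at the AV markers,
because the atrium and ventricle curve very differently — both walls are
resampled to equal normalized arc length and paired point-by-point; the
midline is the midpoint of each pair, lightly smoothed (5-point moving
average, junctions pinned). The 100 segments are allocated to the chambers
proportionally to their midline arc lengths, preserving uniform spatial
resolution; no segment straddles the AV point.

Per segment, the diameter is the distance between the nearest intersections
of the centre's normal chord with the two walls, and the intensity is the
mean over the quadrilateral bounded by the wall-clipped chords at the
segment's boundaries. Pixels on shared chord boundaries are claimed by the
first segment containing them, so the regions partition their union and
total intensity is conserved exactly. Chords that miss a wall (open traces)
yield missing values, not errors. The profiled region is the full
wall-clipped band (lumen plus wall); which compartment the original
analyses profiled is not recoverable, and the band is the least-assumption
choice.

Equal-arc pairing is exact for parallel walls and concentric arcs, and
stays within 5% equidistance for gently curved tubes; strong centerline
curvature (bend radius approaching the tube radius) skews it, which is why
hearts are traced in a view roughly normal to the heart axis.

## Retrospective 4D assembly of calcium plane series

Fifty single-plane movies (50 frames/s), the optical plane moved 4 µm
between acquisitions to cover 200 µm starting ventrally, each start at an
arbitrary phase of the beat. Alignment assumes one stable beat period
across the acquisition: the per-plane period comes from the mean-intensity
trace autocorrelation and the common period is the median, with >10%
deviants flagged rather than corrected.

Each plane's trace is folded to the common period into 100 phase bins with
linear interpolation. The reference plane is the one with maximal temporal
variance (the strongest signal); other planes are aligned in order of
distance from it, each against the running mean of the already-aligned
folded traces, so adjacent planes — which share anatomy — anchor each
other. A plane whose folded-trace correlation peaks below 0.2 is flagged
unalignable. Offsets are reported modulo the period; planes are shifted by
whole frames (no temporal interpolation, which would alter intensities) and
the series is truncated to the common overlap rather than wrapped, since
the movie length need not be an exact multiple of the period. The maximum
z-projection then shows the whole heart, and the atrial diastole and
systole frames are picked by the same cosine phase fit on the projection's
atrial-width trace, at sub-frame precision before rounding to acquired
frames.

A limitation worth knowing: any alignment built on a scalar per-plane trace
measures the *total* phase of that plane — acquisition offset plus the
local anatomical phase. With a strong peristaltic wave the two are
confounded; the procedure still synchronizes the volume but the offsets no
longer equal the acquisition offsets alone.

## Valve morphometry and counting

Leaflet elongation is a threshold call on the maximal per-plane traced
leaflet length (default 10 µm — the original scoring was visual, so the
criterion is explicit and recorded in every output). Cell counts
deduplicate per-plane nucleus detections by greedy nearest-neighbour
linking across planes (xy distance ≤ 3 µm, plane gap ≤ 1); since nuclei
are solid bodies whose centres sit farther apart than twice the link
radius, greedy linking provably agrees with connected components, and the
test suite checks that agreement against a brute-force union-find oracle.
The undeduplicated per-plane sum is also available, since whether the
original manual counts were deduplicated is not recorded.

## Statistics

The two-sided Fisher exact test sums hypergeometric probabilities of all
tables with the observed margins whose probability does not exceed the
observed one — the probability-mass convention of standard statistical
software, pinned by an exhaustive enumeration oracle over every 2×2 table
with total ≤ 30. Student's t is equal-variance by default with Welch as an
option. qPCR fold changes follow 2^-ddCt: technical replicates averaged
per biological sample, dCt against the reference gene (eef1b2 by
convention), ddCt against the mean control dCt, fold per test replicate.
No multiple-testing correction is applied; comparisons are reported
per-condition. Group summaries use n−1 standard deviations, SEM = sd/√n,
and type-7 (inclusive linear interpolation) quartiles.

## The synthetic beating heart

Every stage is validated against `heart_sim_config()` simulations with
exact ground truth; no real acquisitions ship with the package.

**Geometry.** Two ellipse-profile chambers (Gaussian radius bulges,
default rest radii 30/26 µm in the brightfield configuration) joined by a
narrow canal (10 µm) on a gentle S-curved centerline, ventral view with the
atrium right and the AV canal at the tube's midpoint. Walls contract
sinusoidally (default amplitude 0.22 of the radius) with a configurable
peristaltic phase lag; phase 0 is atrial diastole. The bend is kept at 5%
of the image height: the midline tracer's equal-arc pairing is only
specified to 5% equidistance on gently curved tubes, and traces of real
hearts are made in comparably mild views.

**Brightfield.** Bright lumen, dark wall band, grey background; blood
speckle as Gaussian spots (σ 1.5 px) that attenuate light multiplicatively
(Beer–Lambert), so overlapping cells darken smoothly instead of clipping
to black and erasing texture. Advection conserves volume flux: the
scheduled speed applies at the AV canal (where flow is read out) and local
speed scales with (canal radius / local rest radius)², so cells shoot
through the constriction in near single file and dawdle in the chambers,
as real blood does; initial positions are drawn from the steady-state
density. The default 120 particles give chamber speckle coverage in line
with embryonic hematocrit. The scheduled flow fractions are exact ground
truth; frame labels follow the schedule at the frame's phase.

**Calcium plane series.** The tube is tilted along the optical axis —
chambers anchored near the ventral and dorsal faces, the tapered
inflow/outflow tracts overhanging the imaged depth — so the simulated heart
depth is 2·(atrial + ventricular radius); with radii 52/48 µm the 50-plane,
4-µm protocol covers it exactly. The indicator signal fills the tube
cross-section (a hollow shell would make cap-tangent planes oscillate in
antiphase with mid-chamber planes, leaving no well-defined scalar-trace
phase truth) and carries a calcium-like modulation (amplitude 0.6) in phase
with the area modulation. The study configurations use synchronous
contraction (zero peristaltic lag) because, per the limitation above, a
peristaltic wave makes per-plane acquisition offsets unidentifiable from
scalar traces; the flow module's simulations retain the wave. The
acquisition-phase offsets are drawn uniformly per plane and recorded
exactly. The coarser 4 µm pixel pitch of this configuration keeps a 200-µm
heart in a compact field of view.

**Expression stacks.** A static (stopped-heart) z-stack whose wall
intensity follows a caller-supplied per-segment multiplier, for testing
intensity profiling; the encoded profile is exact truth.

**What the simulator does not emulate:** optics (point-spread function,
scattering, depth attenuation), deformable-mesh or hemodynamic mechanics,
beat-to-beat rate variability, cell-shape diversity, and real intensity
statistics, which the original movies' descriptions do not constrain.
Passing the simulation-based tests therefore demonstrates that the
*procedures* are implemented correctly against known truth, not that any
particular biological effect size would be recovered from real data.

**Determinism.** One seeded private RNG stream per simulation call;
identical configuration and seed give bit-identical arrays and ground
truth, and the caller's RNG state is untouched.

## Problem sizes in the test suite

The packaged tests simulate 480-frame brightfield movies at 96×160 px
(about five beats at 240 frames/s, 2.5 Hz), 20 of them spanning anterograde
50–90%, retrograde 5–40%, canal speeds 50–600 µm/s and noise up to 20% of
the intensity range; ten 50-plane calcium series of 60 frames at 48×100 px;
and ten simulated hearts for geometry checks. These sizes give every
estimator several cycles or planes to work with while keeping a full test
run within a few minutes on one CPU.
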