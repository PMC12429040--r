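---
title: "Tracking, morphometry and autocorrelation-corrected statistics with trackmorph"
author: "trackmorph maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking, morphometry and autocorrelation-corrected statistics with trackmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackmorph)
```

# Scope and model of the data

`trackmorph` analyses label-free time-lapse microscopy of adherent cells
(mesenchymal stem cell cultures are the motivating system). The data model
is a sequence of frames, each carrying a set of segmented cell footprints
as polygons in pixel coordinates (x right, y down, origin top-left,
0-based). Where the polygons come from is deliberately out of scope: any
detector that can emit YOLO-format segmentation text, binary masks, or
in-memory polygon lists can feed the pipeline, and a classical
adaptive-threshold segmenter is bundled as a fallback. The package then
answers three questions in sequence:

1. *Which footprint in frame t+1 is the same cell as this footprint in
   frame t?* (the tracker)
2. *How does each cell look and move?* (static and dynamic morphometry)
3. *Do experimental series of a frame-level metric differ, given that
   neighbouring frames are strongly autocorrelated?* (the statistics
   engine)

A synthetic scene generator closes the loop by producing scenes with known
identities, divisions and detection dropouts, so every layer is testable
against ground truth.

# Geometry and the appearance descriptor

Static shape descriptors are computed from the polygon itself where exact
formulas exist: area by the shoelace formula, perimeter as the vertex-chain
length, circularity as $4\pi A/P^2$ (the bounded, unit-free choice that is
1 for a perfect circle), and the equivalent ellipse from the exact second
central moments of the filled region obtained via Green's theorem.
Eccentricity is $\sqrt{1-(b/a)^2}$ and the orientation is the major-axis
angle in $[0,180)$ degrees; an isotropic region reports eccentricity 0 and
orientation 0 by convention. We deliberately keep orientation on the full
$[0,180)$ range rather than folding at 90 degrees: the two half-ranges are
only equivalent for shapes without head/tail distinction, and folding would
destroy the alignment signal in collectively oriented fields. Exact
moments, rather than rasterized ones, make these descriptors stable at any
scale and vertex density.

The tracker's appearance descriptor is different: it must put intensity
statistics and shape moments on the same support, so it rasterizes the
polygon with a pixel-center-in-polygon rule (half-open even-odd crossing
test, so shared boundaries are counted exactly once) and computes, over the
inside pixels: 7 intensity statistics (mean, sd, min, max, median,
skewness, excess kurtosis; zero when no image is supplied), the 7 Hu
invariant moments, 7 scale-normalized central moments
($\eta_{11},\eta_{20},\eta_{02},\eta_{21},\eta_{12},\eta_{30},\eta_{03}$),
and the three ratios solidity, aspect ratio and fill factor. The
concatenated 24-vector is L2-normalized, which makes cosine similarity the
natural comparison and removes exposure differences between frames. The
descriptor lives purely in pixel space and is invariant to integer
translation, so the micrometre calibration never touches tracking.

The boundary "smoothness" index is reported as convex-hull perimeter over
polygon perimeter: 1 for convex outlines and decreasing as the margin
becomes protrusive. This is one reasonable formalization of boundary
regularity among several; it was chosen because it is parameter-free and
shares the hull computation with solidity.

# The tracker

Tracking is framed as a per-frame rectangular assignment problem. For
track $t$ and detection $d$ the cost is

$$c(t,d) = w_{iou}\,(1-\mathrm{IoU}) + w_{dist}\,\min(\delta/g_t, 1) +
  w_{feat}\,(1-\cos(f_t,f_d)) + w_{area}\,\frac{|A_t-A_d|}{\max(A_t,A_d)}$$

with default weights $(0.4, 0.3, 0.2, 0.1)$. The IoU is computed between
the detection and the track's last polygon translated by its velocity
estimate; $\delta$ is the centroid distance, and the gate
$g_t = 50\,\mathrm{px} + 2\,\|v_t\|$ adapts to speed. Pairs outside the
gate are infeasible. The weights put geometry first (overlap and
proximity), with appearance as the tie-breaker — on brightfield data
appearance is informative but noisy, while footprint overlap at typical
frame intervals is the strongest cue.

Assignment runs in two stages: a primary pass over active tracks capped at
cost 0.6, then a fallback pass over the leftovers with doubled gates and a
cap of 0.8, which catches fast or deformed cells without loosening the
primary pass. Three recovery mechanisms follow:

* **Division.** An unmatched detection overlapping a track's predicted
  polygon with IoU at least 0.2 indicates a split. The better-overlapping
  daughter keeps the parent's identity; the other daughter becomes a child
  track with `generation = parent + 1` and a recorded lineage event.
  Continuing the parent's id in one daughter (rather than archiving the
  parent and starting two children) keeps trajectories long for the
  downstream motility statistics. The 0.2 threshold correctly refuses
  far-flung daughters; on synthetic scenes a geometrically extreme division
  (thin parent, strong perpendicular motion) can fall below it and is then
  counted as a new cell, which is the intended conservative behaviour.
* **Merge.** A track whose feasible detections were all won by other
  tracks has merged with (or is occluded by) a neighbour; it is marked
  occluded and waits.
* **Re-identification.** Occluded tracks within the tolerated gap (30
  frames) rematch to leftover detections when the cosine similarity of the
  EWMA appearance histories is at least 0.9 and the detection lies within a
  gap-scaled gate. The same id is restored and a `reid` event recorded.

Matched tracks update exponentially weighted histories with
$\alpha = 0.3$: appearance $f \leftarrow \mathrm{norm}((1-\alpha)f +
\alpha f_{new})$, area likewise, and velocity as the EWMA of centroid
displacement. A track unseen longer than 30 frames is archived and never
reused — ids are permanent.

Per frame the tracker logs track count, mean matched IoU, split/merge/re-id
counts and a continuity score (fraction of previously active tracks matched
this frame; 1 when there were none). Live "id switches" cannot be defined
without ground truth, so the live log reports re-identification events,
and true identity errors are computed by the evaluation harness
(`evaluateTracking`): per-frame IoU association against truth at 0.5,
MOT-style switch counting, identity preservation (fraction of true tracks
whose modal predicted id covers at least 90% of their matched frames) and
division recall within a one-frame tolerance.

# Motility metrics

The baseline linker reproduces a classical centroid-tracking setup:
greedy mutual-nearest-neighbour linking with a hard displacement bound of
10 µm per time step and linear-interpolation bridging of gaps up to 2
frames. A reappearance after $g$ missing frames is accepted within
$(g{+}1)\times 10$ µm, i.e. the per-step bound times the elapsed steps,
which reduces to the plain bound for consecutive frames. Interpolated
positions are flagged so downstream statistics can exclude them.

Calibration is 0.5199 µm/px by default and the frame interval (350 s by
default) is carried as metadata: speeds are reported in µm/frame, the unit
in which the arrest threshold (0.2 µm/frame) is stated, with conversion to
µm/s available via the interval. Twelve per-track metrics are computed;
the from-origin mean squared displacement
$\frac{1}{T}\sum_{k=1}^{T}\|r_k-r_0\|^2$ is the single-scalar summary used
in per-track tables, while a separate lag-resolved MSD supports diffusion
diagnostics (for an isotropic walk with per-axis step deviation $\sigma$
its slope is $2\sigma^2$ per lag, the property the tests verify). The
meandering index and directionality ratio are computed by the same
net-over-total formula and reported under both names so that downstream
table schemas carrying both columns stay filled. Zero-length steps have no
direction and are excluded from turning-angle statistics rather than being
scored as zero turns; fully stationary tracks report angle metrics as
missing, not zero. Sharp turns are counted above a configurable 90-degree
threshold. Aggregation is offered both ways: per-track lifespan means
("dynamic", one row per track) and per-frame cross-sections over the cells
present ("static", one row per frame).

# The statistics engine

Frame-level metric series from k experimental conditions are compared with
a Friedman design: each frame position within a sliding window is a block,
each series a treatment. Two deviations from the textbook test are the
core of the engine:

1. **Smoothing and effective sample size.** Each series is first smoothed
   with a centered moving average (width 15 frames; only full windows are
   emitted). Within each test window the lag-1 autocorrelation
   $$Q = \frac{\sum_{t=1}^{N-1}(X_t-\bar X)(X_{t+1}-\bar X)}
              {\sum_{t=1}^{N}(X_t-\bar X)^2}$$
   is estimated per series, averaged over series, and clamped to
   $[0, 0.99]$ (negative Q would inflate the sample size, which is
   anti-conservative; the upper clamp keeps the result positive). The
   Bartlett effective sample size is $N_{eff} = N\,(1-Q)/(1+Q)$, and the
   tie-corrected Friedman statistic over the N blocks is scaled by
   $N_{eff}/N$ before the $\chi^2_{k-1}$ lookup. Scaling the statistic is
   the standard variance-inflation remedy and reduces exactly to the
   classical test at $Q=0$ (verified against `stats::friedman.test` to
   1e-9). Windows with $N_{eff} < 3$ are reported untestable (`NA`) rather
   than forced through the asymptotic approximation. Because a width-15
   moving average mechanically drives within-window Q toward $14/15$, most
   smoothed windows land in this untestable regime — the correction is
   intentionally ruthless about how little independent information a
   smoothed window contains.
2. **Permutation reference on the raw frames.** In parallel, each window
   gets a permutation Friedman test computed on the *raw* (unsmoothed)
   values at the centers of the same moving-average spans: treatment
   labels are shuffled independently within each block (1000 permutations
   by default) and $p = (1+\#\{S^* \ge S\})/(B+1)$ (the add-one
   estimator, so p is never 0). The raw data matter here: a moving
   average makes the blocks inside a window strongly dependent, and a
   window of near-constant smoothed series would hand the within-block
   permutation null a statistic at its maximum — grossly anti-
   conservative. On raw frames the within-block exchange is the intended
   exact test, and it drives window-level significance in the sliding
   scan; both p values are reported side by side (the smoothed/corrected
   one and the raw/permutation one).

When a window's omnibus test is significant at $\alpha = 0.05$,
Conover–Iman pairwise comparisons on the within-block ranks follow, with
Holm step-down control of the family-wise error rate; fully tied panels
short-circuit to p = 1. The long-form window-by-pair table the scan
exports is the "which pairs differ when" heatmap data.

Calibration is part of the test suite: on 500 exchangeable-null panels the
permutation test rejects at a rate inside $[0.03, 0.08]$ at
$\alpha=0.05$, and on AR(1) panels with $\phi=0.6$ the corrected
asymptotic test rejects a true null strictly less often than the
uncorrected one (which inflates severely, illustrating why the correction
exists).

Two auxiliary tools complete the layer: two-sample distribution distances
(Kolmogorov–Smirnov as the ECDF sup-distance; 1-D Wasserstein as the ECDF
integral, so a pure location shift of c yields exactly |c|), and a
percentile bootstrap of the mean (10,000 resamples by default, seeded;
`level = 0` degenerates to the point estimate).

# The synthetic scene generator

The generator is first-class, tested code, and its defaults define the
study conditions the tests run under. Motion models: Brownian
($r_{t+1}=r_t+N(0,\sigma^2 I)$), persistent (constant-speed steps with
wrapped-Gaussian heading noise scaled by $1-\phi$), directed (fixed step
vector), and arrested (a two-state Markov switch between Brownian movement
and zero steps — the episodic burst-and-pause pattern seen in adherent
cell cultures). Cells are 16-vertex noisy ellipses with axis ratio
1.2–3, placed on a jittered grid with a margin of four cell radii;
trajectories are reflected at the margins *when generated*, so rendering
and division geometry always agree on positions. Divisions replace a
parent with two 60%-area daughters offset $\pm 0.6$ major semi-axes along
its axis; dropouts withhold a detection for 1–3 frames and are enumerated
in the truth. Every generator call is seeded through a pinned
Mersenne-Twister wrapper, making outputs byte-identical across runs and
platforms.

What the generator does *not* emulate: texture and intensity structure
inside cells, segmentation noise on boundaries, cell–cell contact and
crowding, drift and illumination artifacts. Passing tests on these scenes
therefore demonstrate the correctness of the algorithms under their stated
assumptions — not detector robustness on real imagery, which depends on
the upstream segmentation quality.

# Problem sizes, numerics and defaults

The validation suite runs at sizes chosen to make the statistical checks
sharp while keeping the whole suite comfortably interactive: tracking
fidelity on 20 cells over 100 frames (well-separated regime, spacing above
twice the gate), 500 panels for test calibration, 500 trajectories for the
diffusion slope, 300 replicates for bootstrap coverage, and 200 random
matrices against an exhaustive assignment oracle (n up to 7, where
enumeration is exact and fast).

Numerical choices worth knowing: polygon clipping is exact Vatti clipping
(via `polyclip`), with IoU agreement against a subpixel rasterization
oracle asserted to 0.02; clipper output is accurate to about 1e-9 of the
coordinate scale, so equality tests use 1e-7 tolerances. Ties in the
assignment are resolved deterministically by the solver, and identical
inputs always reproduce identical track tables. Intensity skewness and
kurtosis are defined as 0 on constant patches (the 0/0 case). The
configuration surface is one flat key-value file; every constant above is
overridable, and each pipeline stage echoes its effective configuration
and input checksums into a manifest so a run can be reproduced from its
output directory alone.

# Known limitations

* Appearance in the cost matrix uses mask statistics only when no raw
  image is supplied; with no intensity channel, re-identification relies
  on shape alone and the 0.9 cosine threshold is easier to meet by chance
  in dense scenes.
* The split rule requires daughter–prediction IoU of at least 0.2; fast,
  thin cells can divide below it (the daughters then start as new tracks
  with a broken lineage link). Lowering the threshold trades this against
  false splits from touching neighbours.
* The two window tests guard different failure modes and neither subsumes
  the other. The permutation p is exact when frames within a window are
  exchangeable in time and anti-conservative under strong serial
  dependence (consistent rank orderings persist across neighbouring
  blocks); the Bartlett-corrected p absorbs exactly that dependence but
  is very conservative after heavy smoothing, often to the point of
  declaring windows untestable. The scan's binary flag follows the
  permutation p; for strongly autocorrelated metrics the conservative
  read is the set of windows where both tests reject, which the exported
  per-window table makes easy to compute.
* Kalman-style state estimation is not implemented; velocity is a first-
  order EWMA, adequate at the frame rates the defaults target but not for
  strongly manoeuvring objects.
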