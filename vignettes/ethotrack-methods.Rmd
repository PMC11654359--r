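---
title: "ethotrack: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ethotrack: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethotrack)
```

## The assay and what the package computes

`ethotrack` post-processes animal pose-estimation tracks from a
place-preference assay on a linear runway: a 24 × 4 inch chamber divided
into four equal quadrants along its long axis, with a stimulus (exposure)
port at one end (quadrant 4) and the start position at the other
(quadrant 1). An animal — in the motivating experiments a Madagascar
hissing cockroach tracked with a 27-node skeleton — moves freely for a
2-minute session while a top-down camera records it; a pose-estimation
tool (SLEAP-style) converts each video into per-frame x/y pixel
coordinates for every skeleton node, with missing values where a joint
was occluded or blurred.

From such a track the package computes, in order of the pipeline:

1. **Zone occupancy** (`scoreOccupancy`): each whole second is assigned
   to the quadrant containing the *head* node, replicating the manual
   scoring protocol (one score of 1–4 per second).
2. **Kinematics** (`computeKinematics`): per-node speed in cm/s and
   distance travelled per quadrant, using the *metathorax* as the body
   anchor and a single long-axis pixel-to-centimetre calibration.
3. **Ethogramming** (`runEthogram`): unsupervised clustering of
   per-frame kinematic features into k = 4 behaviors (resting,
   scurrying, left- and right-leg movement), with semantic labeling,
   bout segmentation and a 2-D PCA or UMAP embedding.
4. **Group statistics** (`gatedCompare` and friends): an
   assumption-gated decision tree — Shapiro–Wilk and Levene gates, then
   either Kruskal–Wallis with pairwise Mann–Whitney and
   Benjamini–Hochberg correction, or ANOVA with Tukey/Dunnett post hocs
   — plus hand-vs-machine agreement and confusion-rate arithmetic.
5. **Synthetic data** (`generateSession`, `generateCohort`): a
   Markov-chain locomotion simulator with known ground truth, so that
   every stage above can be validated without video.

## Conventions and key parameters

* **Coordinates** are image pixels, origin top-left, x rightward along
  the runway's long axis, y downward; frame indices are 0-based. A
  missing detection is an `NA` pair — x and y are always missing
  together.
* **Frame rate** is explicit everywhere. The recording rate of the
  motivating study is stated as 60 fps, but its own worked example is a
  3,600-frame 2-minute video (30 fps effective); nothing in the package
  assumes either, and file readers fall back to a configurable default
  (60) only when the file carries no rate.
* **Calibration** divides the runway's pixel extent by its physical
  length (default 60.96 cm, i.e. 24 in): `pixelsPerCm(geometry)`.
  Anisotropic pixels and lens distortion are out of scope; the same
  factor is applied to y.
* **Zones** partition `[xMinPx, xMaxPx)` into `nZones` (default 4) equal
  half-open intervals; positions outside the runway clamp to the nearest
  end zone, so zone assignment is total on finite inputs.
* **Per-second labels** are the majority vote of the anchor's per-frame
  zones over the frames of that second in which the anchor was detected.
  The aggregation rule is not specified by the manual protocol, which
  scores whole seconds by eye; majority vote with ties broken toward the
  previous second's zone (else the lower zone index) is the
  least-surprising choice that favors temporal continuity. A second with
  no detected anchor frame is unscorable (`NA`) and is reported
  alongside the per-zone totals so that time is always conserved.
* **Distance attribution**: a step between consecutive frames is
  credited wholly to the zone of its starting frame. This is unambiguous
  and conserves total distance exactly.
* **Anchors** are configurable: occupancy defaults to the head (the
  hand-scoring criterion), distance/velocity to the metathorax (the
  central body anchor). The motivating study uses both without stating
  why; we keep both overridable.
* **Gap filling** (`fillMissing`): interior missing runs up to
  `maxGapFrames` (pipeline default 3) are linearly interpolated per
  node; longer and leading/trailing runs stay missing, and present
  values are never altered. The operation is idempotent.

## The ethogram stage

Features for one frame are the per-node speed (cm/s) over the step to
the next frame followed by the per-node x/y position (cm): `3 × n_nodes`
columns. Frames with any missing feature are dropped; every column is
z-scored, constant columns are set to zero, and the transform is
recorded so summaries can be reported in physical units.

Speed (cm/s) and position (cm) are incommensurate, which is why features
are standardized at all. But per-column z-scoring alone leaves a second
imbalance: the positions of a rigid body's nodes are mutually
near-collinear, so the `2n` position columns would enter k-means with
weight proportional to their column count while carrying roughly two
dimensions of information (where the animal is). `clusterFrames`
therefore rebalances the position block so that its total variance
equals its *effective rank* — the participation ratio
`(Σλ)² / Σλ²` of the block's covariance eigenvalues, about 2 for a rigid
body — before clustering. The weighting is computed from the data at
hand, involves no tuned constant, and can be disabled
(`balance = FALSE`) to cluster plain z-scored features; the embedding
stage always uses the plain standardized features.

Clustering is `stats::kmeans` with a fixed seed and 50 random restarts
(the inertia landscape has local optima in which a rare behavior merges
into a common one; 50 restarts reliably finds the better optimum at
these problem sizes). Semantic labeling of a k = 4 solution is a
heuristic stated in physical units: the cluster with the lowest mean
midline-node speed is *resting*, the highest is *scurrying*, and the
remaining two are split by the sign of the mean left-minus-right
leg-node speed. Exact ties are broken by cluster id and flagged; raw
cluster ids are always retained alongside the map. The "n = 42 random
states" convention of the motivating analysis is interpreted as a fixed
seed of 42 and exposed as configuration.

Embeddings use either PCA (deterministic up to axis sign) or UMAP with
the study-style hyperparameters (2 components, 15 neighbors, Euclidean
metric, minimum distance 0.1, spread 1.0, seed 42), run single-threaded
so results are reproducible. The original analysis used a parametric
(neural-network) UMAP; a standard UMAP is substituted, since only the
visualization depends on it. Whether to embed all frames or cluster
summaries was left open by the source analysis; the package embeds all
retained frames.

## The statistics stage

`gatedCompare` runs Shapiro–Wilk per group and a median-centred Levene
test (the default of the Python stack used by the motivating study) at
`alpha = 0.05`; any significant gate switches the family to the
nonparametric branch. Pairwise Mann–Whitney tests use exact p-values for
small untied samples and the tie-corrected normal approximation
otherwise. Benjamini–Hochberg families are scoped per panel (one family
per quadrant, or per group), never pooled across panels, matching
per-panel reporting. In the parametric branch Tukey HSD is the default
post hoc and Dunnett (versus a control group) is available; both report
family-adjusted p-values, so raw and adjusted coincide there. When all
observations are tied the Mann–Whitney variance degenerates; the package
reports p = 1 (no evidence) rather than NaN, and the paired t statistic
of an agreement comparison with constant differences is likewise
reported as undefined with p = 1.

## The synthetic generator

`generateSession` is a first-order 4-state Markov chain (resting,
scurrying, left-leg movement, right-leg movement) driving
state-conditioned kinematics:

* Per-frame self-transition (dwell) probabilities default to 0.995 for
  resting and scurrying and 0.99 for the leg-movement states; exits are
  uniform over the other states.
* Body speed is Gaussian per state. Scurrying defaults to
  6.0 ± 0.8 cm/s, resting to 0.05 cm/s, leg movement to 0.1 cm/s.
  These values are chosen so that the *session-average* body speed is
  ≈ 2 cm/s — the only printed speed scale for the air group — and the
  per-quadrant distances land in the reported tens-of-centimetres
  range (a 2 cm/s *state* speed cannot produce the reported ~75–90 cm
  per quadrant). They are stand-ins, not study estimates, and are fully
  config-exposed.
* The centroid moves along the long axis with a persistent heading:
  headings are resampled at ~0.15 events/s and at every entry into
  scurrying, choosing the port direction with probability
  `(1 + portBias) / 2`, and each step is scaled by
  `(heading + portBias)`, so at `portBias = -1` approach to the port
  stalls entirely while retreat doubles. This realizes "drift on the
  along-axis motion" multiplicatively on the state's own speed, so a
  resting animal stays still and the ethogram's speed structure is not
  contaminated by drift. Walls reflect the centroid, keeping it inside
  the arena.
* Cross-axis (y) wander is an AR(1) whose innovation scale is
  proportional to the state's speed — a resting animal is genuinely
  still on both axes.
* Node positions follow a fixed rigid body template around the centroid
  (orientation does not flip with heading; a simplification). During
  leg-movement states the active side's leg nodes cycle along a small
  circle (radius 0.3 cm at 5 Hz), giving a steady limb speed within a
  bout — a 1-D sinusoid would pulse through zero speed and alias
  resting.
* The observed track is the truth plus optional Gaussian pixel noise
  and independent per-node-frame dropout. The generator's defaults are
  noiseless: its core product is ground truth, and corruption is an
  explicit, opt-in step (`corrupt()` or the `noiseSdPx` /
  `missingRate` fields).

Ground-truth occupancy is computed from the noiseless head trajectory by
an independent implementation of the per-second majority rule, so the
pipeline check (`scoreOccupancy` equals truth) compares two code paths.
Ground-truth states are the chain itself.

What the generator does *not* emulate: body orientation and turning,
posture variability, the spatial error structure of a pose-estimation
network (beyond isotropic noise and dropout), pharmacokinetics, and any
dependence of behavior on location (thigmotaxis). Tests passing on this
generator therefore demonstrate that the pipeline's arithmetic and
decision logic are correct under controlled conditions — not that the
ethogram's four clusters are the right description of real cockroach
behavior.

## Problem sizes used in validation

Validation simulations use 2-minute sessions at 30 fps (3,600 frames,
matching the worked example of the motivating study) and cohorts of 3
groups × 6 animals, the study's structure. The null-calibration check
runs 200 single-day cohort replicates with all port biases at zero and
requires the BH-adjusted pairwise rejection rate at α = 0.05 to stay
below 0.08; the power check runs 50 replicates with the vehicle group at
`portBias = -0.6` over 4 days per animal and requires the
vehicle-below-air port-zone contrast to be flagged in at least 80% of
them. These sizes are the package's own choices, balancing Monte-Carlo
error against run time.

## Known limitations

* Single-animal tracks only; multi-animal identity tracking is out of
  scope, as is running pose inference itself.
* The zone partition is along one axis; radial or 2-D zone schemes are
  not supported.
* The semantic labeling heuristic presumes the four-behavior repertoire;
  for other k the raw cluster ids are the interface.
* Mixed-measures ANOVA delegates to `stats::aov` with an error stratum;
  unbalanced designs fall back to the caller to restructure.
* Under exact normality the four gate tests trip by chance in ~19% of
  datasets, sending them down the (valid, slightly conservative)
  nonparametric branch; that is the cost of assumption gating, not a
  defect.
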