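---
title: "Quantifying axon guidance and growth cone assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axon guidance and growth cone assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gconequant)
```

## The assays and their measurements

Neurosphere cultures of stem-cell-derived neurons extend long axonal
projections tipped by motile, F-actin-rich growth cones.  Their response
to guidance cues is quantified through a small set of standard
measurements, each of which this package implements as a deterministic
function of its inputs:

1. **Stripe guidance.**  Spheres are plated on alternating equal-width
   lanes of cue-plus-laminin and laminin alone.  Guidance is read out two
   ways.  A *modified Sholl profile* counts neurite crossings of
   concentric rings placed every 10 µm beyond the sphere rim, with each
   crossing binned by whether it falls in a quadrant parallel or
   perpendicular to the stripes.  A *substratum-preference score*
   thresholds the F-actin channel and compares neurite coverage density
   on cue lanes vs laminin lanes (1 = indifferent, below 1 = avoidance).
2. **Growth cone collapse.**  After an acute cue treatment, each growth
   cone is scored collapsed when its lamellipodial veil is disassembled
   and at most two filopodia remain, each shorter than 10 µm.
3. **Outgrowth kinetics.**  Fixed cultures are summarized by the mean of
   the 20 longest neurites per sphere; live imaging yields leading-edge
   positions every 5 minutes, converted to extension rates in µm/hr.
4. **FRET and G-LISA.**  Biosensor activity in single growth cones is
   measured by acceptor photobleaching (donor dequenching); population
   GTPase activity by a plate-based colorimetric assay normalized to
   protein load and a control condition.

## Geometry conventions

All images are numeric matrices `img[ix, iy]` with the origin at the
top-left corner, x rightward, y downward, and `µm = pixel × scale`.
"Vertical" stripes are lanes constant in y whose label depends only on x;
the lane containing the origin is a cue lane and lane boundaries are
half-open, so every point has exactly one label.  All radial distances
(Sholl rings, exclusion zones) are measured from the sphere *rim*, not
its center, because sphere radii vary widely (the generator default is a
150 µm radius; plated spheres in these assays commonly span 100–500 µm).

Quadrants are the four 90° sectors bounded by the ±45° diagonals
relative to the stripe direction through the sphere center; the two
sectors bisected by the stripe direction are "parallel".  Boundaries are
half-open with the counter-clockwise edge included, so a point exactly on
the +45° diagonal is perpendicular and rotating the orientation by 90°
swaps every label, including boundary points.

## Sholl crossings and their oracle

A crossing is a sign change of (distance from center − ring radius)
along consecutive polyline vertices.  This makes tangencies count zero
and is insensitive to vertex spacing as long as segments are shorter
than the ring spacing.  A vertex lying exactly on a ring is treated as
inside, so it belongs to the outward crossing.  Each crossing is
assigned to the quadrant of the *exact* segment–circle intersection
point, obtained from the quadratic in the segment parameter rather than
by linearly interpolating the distance residual: with exact intersection
points the counts are bit-reproducible against an independent
root-enumeration solver, whereas an interpolated point can land on the
other side of a ±45° boundary in rare near-boundary crossings.  The test
suite verifies integer equality of quadrant-binned counts against such a
solver on 100 random trace sets.

## The synthetic scene generator

Because the original assays are measured on microscopy data that cannot
be redistributed, the package ships a generative stand-in for every
assay; its defaults define the conditions under which the pipeline is
validated.

**Neurite traces** are persistent random walks: each trace starts on the
rim at a uniform angle with an outward heading and takes 5 µm steps with
Gaussian heading noise (SD 0.35 rad), truncated at 400 µm.  Cue
avoidance is a single parameter β: a step that would *enter* a cue lane
is accepted with probability `exp(−β)`, otherwise the heading is redrawn
(10 retries, then the step slides parallel to the stripes along the lane
boundary).  Movement within a lane is free — growth cones that are
already on cue may leave but are reluctant to return.  Penalizing entry
rather than mere presence matters: under presence semantics, traces born
on a cue lane can never escape it (every within-lane step is penalized
and the parallel fallback keeps them in the lane), cue coverage stays
near laminin levels at any β, and preference would not fall with
avoidance strength.  Under entry semantics preference is ≈ 1 at β = 0
and decreases strictly in β, which is the behaviour a guidance assay
must show.  One acceptance uniform is drawn per proposal whether or not
it enters a cue lane, so at β = 0 the trace set is bitwise identical for
any stripe map under the same seed — a property the tests exploit.

The generator does *not* model fasciculation (real neurites bundle),
growth-cone-scale turning before the step scale, or any interaction
between neurites; passing recovery tests therefore demonstrates
estimator correctness, not biological realism of individual
trajectories.  No quantitative turning-angle or speed distributions are
available for these cultures, so the walk parameters are plausibility
choices, fixed once, rather than calibrated values.

**Growth-cone images** (64 × 64 µm at 0.25 µm/px) are built from the
morphological definition of the two classes.  A *spread* cone is a
filled veil sector (radius 6 µm, half-angle 110°) facing the growth
direction, with Poisson(8) filopodia of Gamma-distributed length (mean
15 µm) radiating from the rim; a *collapsed* cone has no veil, only a
distal tip with 0–2 short filopodia (mean ≈ 4 µm, capped at 8 µm).  In
both, a 3-px-wide axon shaft runs from the image border to the cone —
wider than the 1-px filopodia, as in real images — and the whole scene
is blurred (σ = 0.8 px) with Gaussian noise (SD 0.03 of the unit signal).
The border-anchored shaft motivates the package's shaft rule during
filopodium extraction: the skeleton branch nearest the mask's
border-contact pixels is the axon shaft and never counts as a
filopodium.

## Collapse morphometrics

`make_factin_mask` applies Otsu (or fixed) thresholding, keeps the
largest 8-connected component and fills holes.  `extract_filopodia`
defines the veil as the morphological opening of the mask by a 1.5 µm
disc — thin protrusions vanish, lamellipodial sheets survive — and
skeletonizes the residual by Zhang–Suen thinning.  The skeleton is split
into branches at branch points (pixels with ring crossing number ≥ 3;
raw neighbour counts misfire on diagonal staircases), spurs shorter than
0.8 µm are pruned and the skeleton re-thinned so artefactual junctions
fuse back, and each remaining branch not attributable to the shaft is a
filopodium.  Branch length is the geodesic diameter of the branch under
8-connected moves (orthogonal 1, diagonal √2), which avoids
double-counting staircase elbows.  On constructed fixtures (disc plus
1-px spokes) recovered lengths are accurate to about two pixels.

The collapse call is the conjunction: veil area ≤ 5 µm² AND ≤ 2
filopodia AND all filopodia < 10 µm.  All three sub-criteria are
reported per growth cone so alternative rules can be recomputed without
re-segmentation.  Two deliberately conservative choices: a growth cone
with no veil but two ≥ 10 µm filopodia is *not* collapsed (the length
clause fails), and the veil-area threshold is exposed as a parameter
because "disassembly of the veil" is inherently a thresholded judgement.
On 200 synthetic cones at default noise the classifier agrees with the
generative labels ≥ 95% (typically ~98%); residual errors come from
nearly-collinear filopodia merging across a junction into one long
branch.

## Kinetics

Per-interval leading-edge displacements are summed and scaled to µm/hr.
Retraction intervals below −30 µm are truncated at −30 µm (and counted),
so one catastrophic retraction cannot dominate a track average; the cap
is a parameter and `Inf` disables it, making the rate exactly net
displacement over elapsed time.  The cap is applied per interval, the
simplest reading consistent with frame-wise measurement.  2-D tracks are
projected onto a local growth axis estimated by principal components
over a rolling 5-frame window, oriented along the window's net movement;
1-D tracks bypass projection.  When a treatment time is given, pre- and
post-treatment rates and their ratio are reported, with a flag when the
pre-treatment window has fewer than two frames.

## FRET and G-LISA

The acceptor-photobleaching estimator is donor dequenching:
`E = 1 − I_pre / I_post`, with both means taken over the bleached ROI
after background subtraction (median of a 2 µm annulus by default, or
the field's 5th percentile).  Because partial bleaching biases E toward
zero, results with acceptor bleach completeness below 0.7 are flagged
invalid rather than discarded, and raw pre/post means are always
emitted.  The synthetic generator applies per-pixel Poisson noise at a
configurable photon budget; at 10⁴ counts/pixel the estimator's bias is
below 0.01 across E ∈ [0, 0.3], and it shrinks with the budget, as the
tests verify at 10³ vs 10⁵.

G-LISA fold activity divides each absorbance by its sample's protein
concentration, then by the control-condition mean, making the control
mean exactly 1 and the score invariant to absorbance units.

## Statistics

Group comparisons use one-way ANOVA with Tukey's HSD (via `aov` and the
studentized-range distribution), a two-sided F test for variance
comparison, and Pearson's chi-squared without continuity correction for
2 × K collapse tables.  Fisher's exact test is implemented from first
principles by exhaustive enumeration of the conditional hypergeometric
distribution; the two-sided p-value follows the probability-mass rule
(all tables as or less probable than the observed one), stated
explicitly because two-sided conventions differ, and the odds ratio is
the conditional maximum-likelihood estimate.  Enumeration agrees with
the reference implementation to machine precision.  One caution: the
probability-mass two-sided p and the chi-squared p are *different*
two-sided conventions and can disagree by several percentage points at
moderate counts; they converge only for large tables.  Under a 3-group
null the ANOVA's type-I error at α = 0.05 sits inside the binomial 99%
interval over 2000 simulated datasets.

The experimental unit in these assays is ambiguous between growth cone
and neurosphere; `assay_report` summarizes whatever grouping it is
given and records analysis parameters alongside, leaving the pooling
decision visible rather than hidden.

## Problem sizes and numerical choices

Validation experiments run at sizes chosen to give stable Monte-Carlo
estimates on a single CPU in minutes: 100 random trace sets for the
crossing oracle; 20 replicate scenes of 200 neurites per avoidance level;
200 growth cones (plus a 352-cone cohort, the scale of a typical
collapse experiment) for label recovery; 30 tracks of 500 frames per
rate; 100 FRET pairs per efficiency; 2000 null datasets for test size.
Degenerate inputs are handled as data, not errors, wherever a real
pipeline could produce them: blank images give empty masks with a
warning, an empty laminin region flags the preference result instead of
dividing by zero, incomplete bleaches mark the FRET result invalid, and
spheres with fewer neurites than k are averaged in full and flagged.

## Limitations

Trace-based Sholl counting is validated; counting crossings on
thresholded masks is not (mask skeletons at ring scale behave
differently and the package does not claim equivalence).  The collapse
classifier replaces a human judgement with fixed morphometric
thresholds; its agreement figure is specific to the generative model's
noise and geometry.  The FRET model omits spectral bleed-through and
photobleaching of the donor.  No mixed-effects modelling of sphere-level
clustering is provided; the report keeps both units visible instead.
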