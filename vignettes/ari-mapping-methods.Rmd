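---
title: "Methods: activation recovery interval mapping on endocardial shells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation recovery interval mapping on endocardial shells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arimap)
```

# What this package computes

Contact electroanatomic mapping of a ventricle yields, at each catheter
position, a one-second unipolar electrogram recorded during constant-rate
pacing, together with a triangulated endocardial shell. From these,
`arimap` computes:

* **activation time (AT)** — the instant of the steepest negative
  deflection (maximal $-dV/dt$) of the unipolar QRS complex;
* **repolarization time (RT)** — the Wyatt fiducial on the T wave: the
  maximal $dV/dt$ *before* the T peak when the T wave is positive, and
  *after* the trough when it is negative;
* **ARI** (activation recovery interval) $= RT - AT$, a validated
  surrogate for local action potential duration;
* per-node maps of ARI and RT on the shell, their **local spatial
  gradients** (ms/mm), and tissue-stratified summaries (mean,
  heterogeneity as SD) inside imaging-defined scar (aLGE: scar plus
  border zone merged) versus healthy myocardium;
* the study-level statistical battery comparing tissue classes, RV
  versus LV endocardial pacing, and pacing distance from the scar rim.

Because no raw animal recordings ship with the package, a first-class
synthetic-data module generates complete cases — mesh, tissue labels,
pacing metadata, electrograms — with *analytically known* fiducials, so
every stage of the pipeline can be validated in closed loop.

# Electrogram analysis

## Filtering

Unipolar traces are low-pass filtered at 80 Hz (4th-order Butterworth)
before any detection. The filter is applied forward and backward so the
net phase is zero and fiducial timing is unshifted. Plain
forward-backward filtering has large end transients, so the trace is
padded by symmetric (even) reflection at both ends before filtering and
trimmed afterwards; a constant trace passes through unchanged to
machine precision and a 10 Hz component is preserved to better than 2 %.

## Activation detection

AT is the argmin of the central-difference derivative of the filtered
unipolar trace inside a QRS search window `[stimulus, stimulus + 150 ms]`
(the window length is configurable; it plays the role of the mapping
system's initial activation estimate). Ties break toward the earliest
sample. The bipolar signal is used only as a veto: a beat whose bipolar
peak-to-peak amplitude in the QRS window is below 0.1 mV carries no
local deflection and is marked invalid, which operationalizes the use of
both unipolar and bipolar channels to reject spurious activations.

## Repolarization detection

The T search window is `[AT + 100 ms, next stimulus - 20 ms]`, clipped
to the segment and marked invalid when shorter than 40 ms (this is the
"shrink to avoid neighboring complexes" rule). The T peak is the largest
interior local maximum of the window after subtracting the window median
(a level baseline robust to a T flank touching the window edge); if no
local maximum exceeds `max(3 × noise estimate, 0.05 mV)` the T wave is
assumed negative and the trough is used instead. The noise estimate is
the median absolute deviation of the raw-minus-filtered residual.

The maximal T-wave slope itself is *not* located by a raw one-sample
argmax: on a broad, low-amplitude T wave the derivative is nearly flat
near its extremum, so sample-level argmax jitters by many milliseconds
under realistic noise. Instead the derivative is estimated by a
Gaussian-derivative kernel (SD 8 ms), its maximum is refined by a local
cubic fit (stationary point), and the known broadening of the kernel
plus the 80 Hz filter is removed analytically: a Gaussian flank of scale
$s$ seen through a kernel of scale $w$ has its steepest point displaced
by $\sqrt{s^2+w^2} - s$ toward the far side of the peak, with $s$
estimated from the fitted curvature. On noise-free Gaussian T waves this
recovers the Wyatt point exactly (to one sample) for both polarities;
under 0.05 mV white noise the median timing error stays below ~3 ms at
1 kHz. The kernel and fit half-widths are `detector_config()` parameters.

## Beats and the consistency filter

A one-second export at 500 ms pacing contains two analyzable complexes
(stimuli at 0 and 500 ms); at 300 ms it contains four stimuli of which
three complexes are analyzable and the fourth is truncated. ARI is
computed for every analyzable beat. A site is retained only when the
second beat's ARI differs from the first by **at most 10 %**
(strict inequality for exclusion, so exactly 10 % is kept); sites with
fewer than two valid beats cannot be checked and are dropped. The
reported per-site ARI is the first beat's by default, with the second
beat and the mean of both available as the appendix-style variants
(`beat_select`).

# Surface mapping

* **Shepard interpolation.** Site values are interpolated to shell nodes
  by global inverse-distance weighting, $w_i = d_i^{-2}$, with every
  site contributing to every node; a node within $10^{-6}$ mm of a site
  takes the site value exactly. The output is therefore bounded by the
  observed value range and exact on constant fields.
* **Tag transfer.** Tissue labels move from a source geometry to the
  shell by nearest-neighbor assignment; any node left unlabeled (only
  possible with partially labeled sources) is filled iteratively by the
  majority label of its labeled mesh neighbors.
* **Interface distance.** Scar and border zone are merged into aLGE;
  interface nodes (those with an edge-neighbor of the other class) get
  distance 0, and all other nodes get the along-surface distance to the
  nearest interface node from a first-order eikonal solver: Dijkstra on
  the edge graph (augmented with hinge-unfolded one-ring shortcuts)
  provides the initial value, and vectorized Gauss–Seidel sweeps of the
  planar-wavefront triangle update (with causality and
  characteristic-foot checks) refine it to convergence. Point-source
  accuracy on refined sphere meshes is a few tenths of a percent
  (median) against the great-circle oracle; line-front accuracy is
  better still. Distances are signed on request (negative inside aLGE).
* **2 mm exclusion.** Sites whose |interface distance| (read at the
  nearest node) is ≤ 2 mm are excluded before any statistics, absorbing
  image-to-shell registration error near the scar rim. Absolute distance
  is used, excluding both sides of the rim.
* **Local gradients.** Three estimators are provided. The default
  `edge` mode reconstructs the tangent-plane gradient vector at each
  node by least squares from the field differences along its
  edge-connected neighbors and reports its magnitude; it is exact for
  affine fields. `edge_mean` is the simplest edge-wise summary — the
  mean of $|\Delta f| /$ edge length over incident edges — retained for
  reference, but note it is a directional average that *systematically
  underestimates* the true magnitude (by the mean |cosine| between the
  gradient and the edge directions, approaching $1 - 2/\pi \approx 36\%$
  for isotropic edge layouts), which is why it is not the default.
  `element` computes the per-triangle linear-interpolant gradient,
  area-weighted onto nodes. Gradients are always computed from the
  interpolated node field; summaries of site values are computed from
  the sites themselves, so interpolation never enters the tissue-mean
  statistics.
* **Pacing distance.** The pacing site's distance to the scar rim is the
  interface-distance value at its nearest node, classified close/distant
  at an inclusive 10 mm cut.

# Synthetic data generator

The generator emulates the *statistical design* of a six-pig chronic
infarction mapping study, not the biophysics of individual electrograms:

| parameter | default | rationale |
|---|---|---|
| pigs / LV-paced pigs | 6 / 4 | study design |
| sites per case | 4,296 | reported mean mapping density |
| aLGE fraction | 0.19 | reported fraction of mapped points |
| cycle lengths | 500, 300 ms | pacing protocols |
| healthy mean ARI | 300 / 185 ms (500 / 300 ms CL) | reported healthy means |
| spatial ARI SD | 20 / 15 ms | reported heterogeneity range |
| `ari_offset_alge` | 0 ms | null study; set to inject a tissue effect |
| `ari_corr_length_mm` | 8 mm | regional scale of APD heterogeneity; mesh-independent |
| T-wave σ | 25 / 10 ms | physiologic narrowing at short CL; keeps the full complex inside the 300 ms window |
| T amplitude / QRS amplitude | 0.5 / 2 mV | typical unipolar morphology |
| negative-T fraction | 0.30 | mixed polarities exercise both Wyatt branches |
| trace noise SD | 0.02 mV | post-filter noise floor of contact electrograms |
| breakthrough delay + surface velocity | 10 ms + 5 mm/ms | apparent endocardial latencies; fast enough that the latest complex at 300 ms CL still fits its window |

Each beat's template is drawn inside its own inter-stimulus window: a
negative logistic step (slope width 5 ms, steepest descent exactly at
the true AT) plus a Gaussian T wave placed so the Wyatt point lands
exactly at the true RT (peak at $RT + \sigma$ for positive T, trough at
$RT - \sigma$ for negative). The level reset at each stimulus acts as
the pacing artifact. Truth that cannot fit its window (T support
colliding with the next stimulus) raises an "infeasible truth" error;
the generator guarantees feasibility by clamping the spatial
perturbation at ±2.5 SD.

The spatially smooth ARI perturbation is node-wise white noise diffused
over the mesh graph, re-centered and rescaled to the target SD —
spatial correlation without external geostatistics machinery. The
number of neighbor-averaging passes is derived from the configured
correlation length (default 8 mm, the regional scale of action
potential duration heterogeneity) and the mesh edge length, so the
field statistics do not depend on mesh resolution and scaled-down
validation meshes see the same spatial structure as full-scale ones. The true ARI field is
`mean + offset·[aLGE] + perturbation`; activation latency grows with
the eikonal distance from the pacing breakthrough node; RT truth is
AT + true ARI.

Shells are icosphere subdivisions (12, 42, 162, 642, 2,562, 10,242
nodes — the smallest size at or above the request is used, since no
general surface triangulator is bundled), optionally scaled to an
ellipsoid or opened into a ventricle-like cap; a seeded random rotation
decorrelates node placement across pigs. Sites are placed at mesh nodes,
which removes site-to-node projection ambiguity from validation surfaces
(off-node sites remain fully supported by the mapping stage). The scar
is a geodesic cap sized so the aLGE area fraction matches the target,
with a 3 mm border-zone rim inside it (border zone is kept small, as in
the imaging the design emulates).

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: fractionated scar potentials (aLGE
electrograms in vivo are heavily fractionated; here noise is additive
white only), baseline wander and far-field ventricular components,
catheter-contact and motion artifacts, true registration error between
imaging and mapping space (tissue labels are exact by construction), and
rate-dependent ARI restitution within a segment.

# Statistics

The study battery (`run_study_stats()`) mirrors the target design:
paired *t* tests for aLGE vs healthy summaries per cycle length (means
and heterogeneity; gradients pooled across cycle lengths), one-factor
within-subject repeated-measures ANOVA for RV vs LV pacing over the pigs
mapped from both chambers (with two conditions its F is exactly the
squared paired-*t* statistic; no sphericity correction is needed for a
two-level factor), Pearson correlation with a *t* test for gradient vs
pacing distance, and one-way (unbalanced) ANOVA for the ≤10 mm vs >10 mm
pacing groups. All tests are two-sided; *p* < 0.05 is the significance
convention. The computational engines are the standard R
implementations (`t.test`, `aov` with an `Error()` stratum, `anova(lm)`,
`cor.test`); the test suite checks each against hand-computed textbook
formulas to 10⁻¹⁰.

**Outliers** are removed once per data group, never iteratively:
values strictly below the 10th or strictly above the 90th percentile
(linear interpolation between order statistics, `quantile` type 7) are
excluded. The data groups are the *site-level* ARI distributions within
each case and tissue class — that is where fractionation-driven
outliers arise — and the exclusion runs inside `run_case()` as the last
site-attrition stage (after the consistency filter and the 2 mm band),
so the logged attrition mirrors the filtering sequence. A percentile
rule cannot sensibly operate on six-value case-level groups: the 10th
and 90th percentiles of six values bracket the min and max, so per-arm
trimming would always discard a third of the animals, collapse a paired
design to two or three pairs, and both inflate the type-I error and
destroy power (verified by replicate simulation during design). The
per-arm case-level variant remains available (`exclude = TRUE` in the
test functions, with pairs dropped when either member is excluded so
pairing is preserved) but is off by default. Groups with fewer than
three values skip exclusion with a warning.

# Numerical conventions and determinism

Coordinates are mm, times ms, voltages mV; node and sample indices are
0-based on disk and 1-based in R. All argmin/argmax ties break toward
the earliest sample. Synthetic generation is bit-deterministic given the
configuration (a per-case sub-seed derives from the master seed, pig,
cycle length and chamber; the global RNG state is saved and restored);
the analysis stage uses no randomness at all, so `run_case()` is
deterministic by construction. Case bundles round-trip through the
on-disk format (JSON manifest, VTK legacy ASCII mesh, long CSV
electrograms) with byte-identical re-writes.

# Problem sizes used in validation

The package defaults describe the full-scale study (4,296 sites on a
10,242-node shell, 20 maps). The automated test suite and the acceptance
script run the same code paths on reduced instances chosen as a
deliberate compromise between Monte-Carlo resolution and turnaround:
replicate six-pig studies use 60 sites on 642-node shells (enough that
each map retains a usable aLGE sample after the 2 mm exclusion),
geodesic oracles use 2,562–10,242-node spheres, and the null-calibration
and power checks use 100–200 replicate studies. These sizes are stated
here once; none of the generator's *scientific* constants (tissue
fractions, ARI levels, noise, thresholds) change between scales.

# Known limitations

* The Wyatt estimator's broadening correction assumes a locally Gaussian
  T flank; strongly asymmetric or biphasic T waves will be located with
  a small residual bias (bounded by the fit window).
* The eikonal solver is first-order; its point-source error (a few
  tenths of a percent on refined meshes, ~1 % on coarse ones) enters the
  painted-scar geometry and the latency truth of the generator.
* `edge_mean` gradients are biased low by construction (see above);
  cross-tissue *comparisons* of that estimator remain valid because the
  bias is common to both classes on isotropic meshes.
* Statistical power statements transfer to real mapping data only to the
  extent that the generator's noise model (additive white, no
  fractionation) matches reality inside scar; in vivo, beat-consistency
  attrition concentrated in aLGE reduces the effective sample there.
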