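---
title: "Methods: protocol-constrained tractography and connectivity blueprints on phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protocol-constrained tractography and connectivity blueprints on phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtract)
```

## Scope

`subtract` is a desk-scale implementation of a standardised
cortico-subcortical tractography workflow: probabilistic streamline
tracking through multi-fibre orientation fields under
seed/target/stop/exclusion protocol semantics, construction of
grey-matter-by-tracts connectivity blueprints, symmetric Kullback–Leibler
(KL) homologue matching across species, tract-similarity statistics, and
anterograde-tracer termination-probability maps. It does not estimate
fibre models from raw diffusion data, perform nonlinear registration, or
handle surface formats at real scale; orientation fields are either read
from NIfTI volumes or generated by the phantom module.

## The tracking model

Each voxel carries up to three fibre populations, each described by an
axial (sign-free) unit mean orientation, a volume fraction in $[0,1]$ and
an angular dispersion in degrees. A streamline is grown from a seed point
as two half-streamlines with opposite initial signs, concatenated at the
seed. At every step:

1. populations with volume fraction below the **volume-fraction
   threshold** (default 1%) are discarded;
2. among the survivors, the population whose orientation maximises
   $|\langle \mu, d_{prev}\rangle|$ is selected (uniformly at random when
   there is no previous direction, i.e. at the seed);
3. a dispersed direction is drawn by rotating the mean by an angle
   $\theta \sim N(0, \sigma)$ about a random perpendicular axis, where
   $\sigma$ is the population's dispersion — a simple zero-mean wrapped
   perturbation standing in for a full orientation-uncertainty model;
4. the sign is flipped if needed so the step does not point backwards;
5. the step is rejected and the streamline terminated if the turn exceeds
   the **curvature threshold** (default 80°);
6. the position advances by **step size** (default 0.5 mm, the
   human-scale setting; 0.2 mm is the macaque-scale analogue).

Propagation also terminates on leaving the grid, in fibre-free voxels, at
the **maximum step count** (default 2000 per half-streamline), on
entering a stop mask (truncation), or on entering an exclusion mask
(invalidation). A streamline is *valid* iff it visits every target mask —
an unordered conjunction — and never enters an exclusion mask; a path
truncated by a stop mask still counts if the targets were visited. The
path distribution records, per voxel, the number of *distinct* valid
streamlines entering it, and normalisation divides by the number of valid
streamlines, so normalised values are visitation probabilities in
$[0,1]$.

Numerical conventions, chosen once and used everywhere:

* voxel indices are 0-based, world coordinates are voxel-centre mm;
  voxel membership of a point is the nearest grid index;
* orientation lookup is nearest-voxel, with no interpolation of
  orientations between voxels (common practice in probabilistic
  trackers);
* the number of streamlines per seed voxel is not a quantity with a
  canonical value; the default is 1000, and the phantom analyses in the
  tests and the acceptance script use 20–100 per seed voxel, which is
  ample for the deterministic or mildly dispersed phantom fields used
  there;
* the seed position is jittered uniformly within the seed voxel;
* the single direction pair across the seed joins two independently
  initiated half-streamlines and is therefore not curvature-constrained —
  the 80° contract holds within each half. This mirrors standard
  bidirectional tracking semantics;
* when a run yields zero valid streamlines, normalisation returns an
  all-zero map with a warning rather than an error, so symmetric
  (two-run) averaging remains well defined.

## Protocols and the manifest

A protocol names a seed mask, a set of target (waypoint) masks, an
optional stop mask, exclusion masks, a laterality
(bilateral/commissural/unilateral) and a symmetric-run flag. Symmetric
protocols are tracked a second time with seed and final target swapped
and the two normalised maps averaged — the convention used for
commissural tracts such as the anterior commissure. Manifest expansion
instantiates bilateral entries once per hemisphere (`_L`/`_R` suffixes,
by mask-set naming rather than geometric reflection, which would require
real template anatomy). The packaged roster of twelve cortico-subcortical
protocols (eleven bilateral, one commissural) therefore expands to 23
tract instances.

## Connectivity blueprints

A connectivity blueprint is a GM-locations × tracts matrix whose rows
describe how each grey-matter location connects to a fixed tract set.
Cortical rows are built through an intermediary product: a GM×WM matrix
of visitation counts from unconstrained streamlines seeded at each
boundary location, multiplied by a WM×Tracts matrix collating the
normalised tract maps over a white-matter mask. The intermediary sidesteps
the gyral bias that direct intersection would inherit near the cortex.
The product is taken on raw counts; row normalisation is deferred to
assembly, where cortical and subcortical rows are stacked and each row is
divided by its sum (zero rows stay zero and are reported).

Subcortical rows use direct intersection instead: each normalised tract
map is block-mean downsampled to a coarser working resolution, values
below an absolute threshold of 0.001 (0.1% of valid streamlines, read as
a cut on the normalised map, consistent with valid-streamline
normalisation) are zeroed — downsampling strictly before thresholding —
and the result is multiplied by each binary nucleus mask. On phantoms
where one bundle terminates in nucleus A and a second structure feeds
nucleus B into the same corridor, the direct construction concentrates
the bundle's mass in A strictly more than the intermediary construction
does (specificity ratio > 1), which is the motivation for using it in
subcortex, where gyral bias is not a concern.

Downsampling supports only integer ratios (block mean or subsampling);
non-integer ratios are rejected rather than interpolated so that mass
accounting stays exact. Which interpolation a production pipeline would
use is left open deliberately.

## Divergence and homologue matching

Two connection patterns $M_i$ and $H_j$ (blueprint rows) are compared
with the symmetric KL divergence in bits:

$$D_{ij} = \sum_k M_{ik} \log_2 \frac{M_{ik}}{H_{jk}}
         + \sum_k H_{jk} \log_2 \frac{H_{jk}}{M_{ik}}.$$

To avoid degeneracies from zeros, both rows are shifted elementwise by
$\delta = 10^{-6}$ **without renormalising** — exactly as the procedure is
stated; the consequence that shifted rows sum to $1 + T\delta$ is
accepted and documented. For the disjoint unit rows $(1,0)$ and $(0,1)$
the closed form is $2\log_2((1+\delta)/\delta) \approx 39.86$ bits.

When a comparison is restricted to a tract subset (cortico-cortical
`cc`, cortico-subcortical `cs`, or an explicit name list), rows and the
reference pattern are re-normalised after restriction so the divergence
operates on comparable masses; the alternative (comparing unnormalised
restrictions) would conflate subset mass with pattern shape. A region's
reference pattern is the re-normalised mean of its rows. Best-match
selection keeps the locations below a stated percentile of the divergence
map (order-statistic rule, default the 7th percentile, at least one
location); a constant map is degenerate and returns an empty set with a
warning.

The matched-blueprint generator emulates the cross-species setting: each
region draws a tract profile once from a Dirichlet-type simplex
distribution and both "species" draw rows around that shared profile with
independent multiplicative log-normal noise before row normalisation.
Cortico-cortical profiles share a common background component (70%
common, 30% region-specific), while cortico-subcortical profiles are
fully region-specific — so including the subcortical tracts sharpens the
matched-vs-unmatched contrast, the phantom analogue of the benefit the
subcortical tracts bring to cross-species mapping. Defaults (5 regions
in the demo, 12 tracts split 6/6, 20 locations per region, concentration
0.5, noise SD 0.25) were fixed once as a regime where regional profiles
are distinctive but noticeably noisy.

## Similarity statistics

Tract similarity between two subjects is the Pearson correlation of
their normalised path distributions after zeroing values below 0.5% of
valid streamlines, computed over the union of the two supra-threshold
supports (the procedure states the threshold but not the support; the
union makes the statistic symmetric and sensitive to support mismatch).
Fewer than three support voxels, or a constant map, gives a missing
value, which is excluded from per-pair means and counted.

The family-structured cohort emulates a twin design: each pair shares a
latent two-parameter bundle geometry (bow amplitude and axial offset of a
curved bundle in a 16³ voxel grid), perturbed per member by the group's
within-pair SD — 0.1 for monozygotic (MZ) pairs, 0.5 for dizygotic (DZ)
and non-twin sibling pairs, and independent draws for unrelated pairs,
against a heritable SD of 1. These SDs were chosen once so that the four
groups are separated but overlapping at $n = 10$ pairs per group, the
cohort size used throughout. Group comparisons use a two-sided
Mann–Whitney U test: the exact null distribution of U via the standard
closed-form count for untied data, explicit enumeration over group
assignments when ties are present (feasible to $n+m \le 14$), and a
tie-corrected, continuity-corrected normal approximation otherwise.
Bonferroni correction flags $p < \alpha/n_{tests}$ over the six group
pairs. On this generator the expected pattern is MZ > DZ ≈ sib >
unrelated with MZ-vs-unrelated significant and DZ-vs-sib not —
the qualitative twin-structure signature.

Representative subjects are ranked by mean-over-tracts correlation to a
group average and picked at the 10th/50th/90th percentiles under the
nearest-rank rule, ties resolved to the lowest subject id.

## Tracer termination maps

Termination sites carry an injection-ROI label (e.g. frontal, parietal,
temporal, sensorimotor). Per label, sites are binned to nearest voxels of
the target mask and counts divided by that label's in-mask total,
yielding a probability map; out-of-mask sites are dropped and counted.
Smoothing convolves each map with a separable cubic B-spline kernel of a
stated scale (default one voxel — the spline order and support of the
original smoothing are unstated, so the scale is exposed), restricts to
the mask and re-normalises, conserving per-label mass to 1e-9. The
dominant-label map takes the per-voxel argmax with ties broken by
declared label order; on a stratified-nucleus phantom with four bundles
terminating in stacked layers, the tract-based and tracer-based dominant
labels reproduce the generated layer order — the phantom analogue of the
dorsolateral-to-ventromedial correspondence between tractography and
tracer patterns in the putamen.

## What the phantoms do and do not show

The phantom module generates tube bundles (straight, arc, arbitrary
polyline centrelines) with known ground-truth masks, cap-face boundary
locations standing in for the WM–GM boundary, labelled nucleus masks,
matched two-species blueprints, and family cohorts. All generators are
pure functions of their parameters and one root seed; per-object
substreams are derived by hashing small integer keys, so any single
object is reproducible in isolation.

Phantoms have exact geometry, noiseless volume fractions and at most
mild angular dispersion: passing tests demonstrate that the protocol
semantics, the accounting (validity, normalisation, thresholds) and the
statistics are implemented correctly, not that real-brain anatomy would
be reconstructed faithfully. Real data add orientation-estimation error,
partial volume, complex geometry and registration error, none of which
the phantoms emulate. Problem sizes used in the tests and acceptance
script — 24³–32³ voxel grids, 20–100 streamlines per seed voxel, 10
pairs per cohort group — were chosen as the smallest scales at which the
expected effects are unambiguous.

## Known limitations

* Orientation fields must fit in memory as dense per-voxel arrays; no
  sparse or streaming storage.
* No surface (GIFTI/CIFTI) support; boundary locations are labelled
  points.
* The dispersion model is a single wrapped-normal perturbation, not a
  full posterior over fibre orientations.
* Exact Mann–Whitney with ties is limited to $n+m \le 14$ by
  enumeration cost.
* Hemisphere instantiation of bilateral protocols is by mask naming;
  geometric reflection across a template midline is out of scope.
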