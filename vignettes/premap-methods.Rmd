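---
title: "premap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{premap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(premap)
```

This vignette is the package's account of what it computes and why the
open design choices were made the way they were. The worked numbers in
the README are produced by the code shown there; nothing here claims an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Data model

Volumes live on a `VolumeGrid` (dimensions, voxel size in mm, a named
coordinate frame, and a 4x4 voxel-to-world affine over 0-based voxel
indices). `ScalarVolume` carries real values plus a logical analysis
mask; `LabeledVolume` carries integer parcel/ROI labels with names.
NIfTI-1 is the on-disk format; a JSON sidecar stores the frame, label
names, the mask, and the affine at full double precision, because NIfTI
headers hold transforms in single precision and the package promises
bit-exact write/read round trips.

Connectivity profiles are rows of a `ConnectivityMatrix`: one row per
in-mask voxel in ascending column-major linear-index order (the
package's single, documented linearization), one column per feature
(injection volume, or brain voxel). Fingerprints are named numeric
vectors over an ordered target panel; `defaultTargets()` gives the
18-target panel of cross-species homologs (S1, S2, V1, A1,
dorsal/ventral hippocampus, IL, PL, RSC, lateral OFC, basolateral
amygdala, TPJp, CPm, CPl, NAcc, and left-hemisphere S1, S2, M1).

## Preprocessing primitives

**Unit-interval normalization.** Tracer volumes are min-max rescaled to
[0, 1] within the mask, with no further per-feature standardization:
the 0-1 rescaling is the only normalization the clustering input gets.
A constant volume normalizes to all zeros with a warning rather than an
error, so batch ingestion of degenerate injections never aborts.

**Smoothing.** Separable Gaussian convolution with sigma in mm
(converted per axis via the voxel size). The rs-fMRI convention -
sigma equal to twice the voxel size in X and Y and none along Z, i.e.
0.4 mm for 0.2 mm mouse voxels and 4 mm for 2 mm human voxels - is
packaged as `smoothTwiceVoxelXY()`. Boundary handling: with a proper
mask, smoothing is zero-filled outside the mask and renormalized by the
smoothed mask (standard masked smoothing); with a full mask the
boundary is edge-replicated, which keeps a constant volume exactly
constant and exactly preserves the in-volume sum whenever the signal is
padded by at least the kernel radius (4 sigma) of zeros. Kernel radius
is `ceiling(4 * sigma)` voxels.

**ROIs.** Connectivity targets are cubes of `edge^3` voxels (3x3x3 by
default) centered on the voxel nearest the requested world coordinate,
clipped at grid edges with a logged count. ROI boxes are inclusive
voxel sets; there is no half-open ambiguity.

## Parcellation and model selection

Voxels are clustered by k-means under squared Euclidean distance
(Lloyd's algorithm), best of `nRestarts = 50` restarts, each restart
initialized from k distinct sampled rows; restarts that produce an
empty cluster are discarded and resampled. Inertia is the within-
cluster sum of squares of the best restart. On instances small enough
to enumerate, this matches the exhaustive-partition optimum (tested).

Four per-k criteria feed `selectK`:

* **stability** — matched-Dice agreement across 20 runs on random 80%
  subsamples, with clusters matched by the one-to-one assignment that
  maximizes summed Dice (exact: all k! permutations are scored). The
  criterion is named but not formalized in the source literature; the
  subsample fraction, resample count, and threshold (default 0.8) are
  exposed parameters. On high-dimensional pure noise the score sits
  near the label-shuffle chance level; note that in low dimensions
  k-means partitions of even structureless data are geometrically
  reproducible, so the chance comparison is only meaningful when the
  feature count is comparable to the voxel count.
* **silhouette** — mean of (b − a)/max(a, b); singleton clusters score
  0, and a degenerate all-singleton clustering is defined as 0 with a
  warning. Data sets beyond `maxN` rows are scored on a seeded
  subsample (documented approximation; 800 rows in `parcellate`).
* **inertia elbow** — the candidate k with the greatest discrete second
  difference of inertia; ties break to the smallest k, and a curve with
  no positive curvature returns the smallest candidate with a warning.
* **parcel-size variance** — population variance of parcel voxel counts
  divided by the squared mean (CV²), so masks of different sizes are
  comparable; the normalization is a package choice.

`selectK` applies them lexicographically: keep stable k; keep those
within `silhouetteTol` (default 0.05, absolute) of the best silhouette;
prefer the elbow k if present; break ties by minimal size variance,
then smallest k. Every filter step is logged. The silhouette tolerance
is a parameter rather than a constant because the "tie" among top
silhouette scores is not quantified in the source literature. An empty
stable set falls back to the maximum-stability k with a warning.
Candidate k defaults to 2-8.

## Fingerprints and permutation inference

A seed's fingerprint is the Pearson correlation between its mean time
course and each target's mean time course, in panel order. Templates
are elementwise medians across subjects (even counts: mean of the two
middle values). Voxel maps correlate each in-mask voxel's fingerprint
with a template across targets; Fisher z uses r clipped to
±(1 − 1e−6) to avoid infinities. Whether to match on raw-r or
z-transformed fingerprints is configurable; raw r is the default.
Constant fingerprints and zero-variance time courses yield r = 0 with
a single summarizing warning.

Group inference is a one-sample t per voxel with the null built by
sign-flipping whole subject maps, FWE-corrected by the image-wise
maximum statistic. With n ≤ 12 subjects all 2^n flips are enumerated
exactly and p = #(max ≥ observed)/2^n (the identity flip counts
itself); otherwise `nPerm` random flips give p = (b + 1)/(nPerm + 1).
Inference is one-sided positive, because only positive fingerprint
similarity is meaningful for cross-species assignment; this is a
package decision and is configurable at the map level by negating
inputs. TFCE (E = 0.5, H = 2, dh = 0.1, 6-connectivity) is implemented
as an alternative image statistic, but max-stat is the default because
the reference TFCE configuration is not printed in the source
literature.

The Manhattan-distance test compares two groups of unit-by-feature
profiles by the L1 distance between group mean vectors, permuting
unit-to-group labels (default 10,000 permutations; exact enumeration
whenever the total number of assignments is at most 20,000). The
exchangeable unit is whatever the rows are - voxels for expression or
myelin region profiles, subjects for fingerprint comparisons - chosen
per call.

## Cross-species maps

**Winner-take-all.** Each voxel takes the label of the area with the
largest group t; exact ties break to the first area in map order with a
logged count. By default every in-mask voxel is assigned (the main-map
convention); passing significance masks (or
`restrictToSignificant = TRUE`) reproduces the restricted variant in
which voxels significant for no area become "unassigned".

**KL embedding.** Fingerprints are made into strictly positive
distributions by shift-by-minimum plus epsilon (1e−6) and
normalization; a constant fingerprint maps to the uniform distribution.
This normalization is a package decision (the divergence needs
distributions and no normalization is prescribed by the source
literature); `klMatrix(..., normalize = FALSE)` accepts already-valid
distributions. The divergence is the symmetrized KL, giving a
symmetric, non-negative, zero-diagonal matrix. The 2D embedding is
Laplacian eigenmaps: affinity exp(−D/s) with s the median off-diagonal
divergence, coordinates from eigenvectors 2 and 3 of the symmetric
normalized Laplacian, signs fixed by making each axis's first nonzero
loading positive. Eigenmaps rather than full spectral k-means because
the 2D space is used for display and proximity, not hard clusters.
Because the axes are unit-norm eigenvectors, proximity statements are
group-level: for block-structured divergences the first axis separates
the blocks and mean within-block distance falls below mean
between-block distance, but individual within-block pairs can exceed
individual between-block pairs along the second axis.

## Vertical validation

Per-voxel modal correlation uses the exact t transform of r with
df = features − 2 for its two-sided p (the reference analysis reports
"related p value" without naming a method). The conservative null
correlates in-network fMRI profiles with tracer profiles of voxels
sampled outside the network - without replacement until the pool is
exhausted, then with replacement, logged. Distributions are compared
with the asymptotic two-sample Kolmogorov–Smirnov test.

DAM B1+ inversion is
B1+ = (180/π)/α · arccos(A2/(2 A1)) · 100 with α the nominal angle of
the lower-flip-angle scan (40°); the arccos argument is clamped to
[−1, 1] and the clamp count reported as QC, A1 ≤ 0 voxels are masked
out with a warning. Noise-free generator-inversion round trips are
exact to < 1e−6 percentage points (tested).

Perturbation records are assigned to the parcel strictly containing
their (AP, ML) coordinate at the parcel map's reference depth (default:
the middle z-slice, configurable) - no nearest-neighbor snapping,
since off-target attribution is a known limitation of the underlying
experiments; out-of-parcel records are "unassigned". The six task
categories use strict thresholds exactly as prespecified: the three
task-type labels, complexity index strictly above 5, number of actions
strictly above 1, movement complexity equal to 1. Radar percentages
are additionally rescaled per category to [0, 1] across parcels.

## Synthetic data: what it emulates, and what it does not

All generators are deterministic given (parameters, seed), use
Gaussian noise throughout (heavy-tailed options were deliberately
deferred), and emit volumes that satisfy the package's invariants.

* `generateParcelGeometry()` — the "motor-system" preset plants four
  contiguous parcels on a 17 x 14 x 4 grid of 0.2 mm voxels in the
  stereotaxic-bregma frame (952 voxels): a
  lateral strip split antero-posteriorly (M1, ALM) and a medial strip
  split by an oblique border AP > 0.8 − 0.6·ML (aM2 anterior-lateral,
  pM2 posterior-medial), so the internal MOs border runs at an angle to
  the midline. The four published area centers fall inside their
  respective parcels.
* `generateTracerSet()` — per-parcel latent profiles N(0, separation²)
  per injection, plus spatially smoothed noise standardized to
  `noiseSd`, then 0-1 normalization. Defaults (30 injections,
  separation 3, noise 1, 1-voxel noise smoothing) are the package's
  study conditions: chosen once to make the qualitative behavior of the
  reference analysis (a four-parcel optimum) reproducible at desk
  scale, and labeled as package choices - no quantitative tracer SNR
  is available to match.
* `generatePairedModalities()` — both modalities share a latent voxel
  profile; the per-voxel cross-modal correlation is exactly
  sd_s²/√((sd_s² + sd_a²)(sd_s² + sd_b²)), returned as `expectedR`.
  At the default sd_a = sd_b = 1.4 this is 0.338; the calibration is
  checked against the closed form, not claimed to reproduce any
  empirical effect size.
* `generateFmriTimeseries()` — ROI courses from a multivariate normal
  with the requested correlation (PSD enforced via eigendecomposition
  with clamped eigenvalues, so exactly singular targets like perfectly
  correlated ROIs are allowed); voxel series are ROI course plus white
  noise. No hemodynamics, autocorrelation, drift, or physiological
  confounds are modeled.
* `generateExpression()` — N(0, 1) baseline; a chosen fraction of genes
  shifts its mean between two designated regions by a stated number of
  SDs.
* `generateDamPair()` — A1 = m0 sin θ, A2 = m0 sin 2θ with
  θ = α·B1/100 per voxel, plus optional noise.
* `generatePerturbationTable()` — per-parcel study counts with
  coordinates jittered within the sampled voxel (so strict containment
  recovers the planted parcel) and Bernoulli-drawn descriptors.

Passing tests on these generators shows the machinery is correct and
calibrated; it does not show that real tracer, fMRI, expression, or
qMRI data meet the generators' assumptions (Gaussian noise, piecewise
constant parcels, shared latent profiles, white temporal noise).

## Problem sizes and run times

The test suite and the acceptance script are sized for interactive use:
model-selection recovery runs 20 replicates of the full k = 2..8
procedure on the 952-voxel preset (about 7 s each); the bridge uses
500 voxels by 2,000 features; the Manhattan benchmark 100 genes by 400
voxels with 10,000 permutations; permutation-engine checks use grids of
tens to hundreds of voxels. These sizes are package choices that keep
the whole suite in a few minutes while leaving every statistical
conclusion comfortably powered.

## Interfaces and orchestration

The package's interface is its functions; `runPipeline()` +
`validateConfig()` orchestrate the synthetic end-to-end run from a
YAML/list config with a versioned schema (unknown keys are rejected by
name, defaults are explicit, normalization is idempotent) and write a
JSON manifest with parameters, per-stage derived seeds, and MD5
checksums, so every figure-equivalent output is regenerable from the
manifest alone. Real-data runs compose the same stage functions on
volumes read with `readVolume()`.

## Known limitations

* The stability statistic and the silhouette tie tolerance are
  operationalized choices; other formalizations (e.g. ARI-based
  stability) could rank candidate k differently on borderline data.
* Whether tracer features should be injections or voxelwise projection
  fields after concatenation is ambiguous in the source literature;
  `ConnectivityMatrix` supports both column types, and the synthetic
  generator uses injections.
* The embedding is for display/proximity; no statistical comparison of
  embeddings across runs is provided.
* No registration, denoising, or nuisance regression: inputs are
  assumed preprocessed and in a common space.
* The depth at which 2D stereotaxic coordinates meet the 3D parcel map
  is a configurable reference slice; mid-depth by default.
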