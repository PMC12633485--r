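---
title: "Unsupervised particle picking in cryo-electron tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised particle picking in cryo-electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomopick)
```

## The problem

Cryo-electron tomograms are 3D reconstructions of frozen-hydrated
specimens at extremely low signal-to-noise ratio. Downstream analysis
(sub-tomogram averaging, classification) needs the positions of the
macromolecular particles inside each volume. Template matching requires
a known structure; supervised pickers require annotated training data.
`tomopick` instead treats picking as an unsupervised two-class
segmentation problem: describe every voxel by features of its local
neighborhood, split the voxels into two clusters, call the smaller
cluster "particle", and extract instance centroids as picks.

Every run composes three interchangeable stages:

1. **Feature extraction** from the $N_s^3$ ($5^3$ by default)
   neighborhood of each non-peripheral voxel, in one of three modes:
   raw *intensities* (125 values), *FFT* magnitudes of the 3D DFT of
   the neighborhood (125 values), or responses to a bank of 3D *Gabor*
   filters (the 64 most variance-carrying responses out of 1000).
2. **Clustering** with k-means or a 2-component full-covariance
   Gaussian mixture (GMM), giving a binary semantic segmentation.
3. **Instance extraction** with connected-component labeling (CC) or
   marker-based watershed (WS), followed by geometric-centroid
   computation.

The $3 \times 2 \times 2$ grid defines twelve workflows, named
`<mode>-<method>-<extraction>` (e.g. `gabor-kmeans-cc`). `run_all()`
computes the six semantic segmentations once and reuses each for both
extraction algorithms.

## The model, stage by stage

### Preprocessing

The volume is smoothed with an isotropic Gaussian of $\sigma = 2$
voxels and min-max normalized to $[0, 1]$. Smoothing trades resolution
for contrast; $\sigma$ is interpreted in voxels (configurable). The
blur uses reflect padding — zero padding would darken the faces and
bias the two-cluster split near the volume boundary — and truncates
the kernel at $4\sigma$ (mass loss $< 10^{-4}$). A constant volume
normalizes to all zeros with a warning rather than an error, so
degenerate inputs surface in the clustering stage where the message is
more informative.

An optional central Z-slab restricts *model estimation* to the lamella
(cluster parameters fitted on `crop_z()` features, then applied to the
whole volume), and a second, independent slab can restrict where
centroids are reported.

### Gabor bank

A filter is the product of an isotropic 3D Gaussian envelope and a
plane-wave cosine,

$$G(x,y,z) = N_{\mu,\sigma}(x,y,z)\,
  \cos\!\big(2\pi (x f_x + y f_y + z f_z) + \psi\big),$$

evaluated on the integer grid $[0, N_s)^3$ with the envelope centered
at $(\lfloor N_s/2\rfloor, \dots)$, $\sigma = \lfloor N_s/2\rfloor/3$
(= 2/3 for $N_s = 5$) and $\psi = 0$. Ten frequencies per axis span
$[0, 0.5]$ cycles/voxel inclusive — DC through Nyquist, so the bank
contains both a pure low-pass envelope and the checkerboard — giving
$m = 10^3 = 1000$ filters. Filters are L2-normalized after
construction so that the subsequent selection of the $m_{out} = 64$
filters with the largest response standard deviations compares filters
on equal energy footing; both the endpoint inclusion and the
normalization are configurable because other conventions are
defensible. Ties in the selection break toward the lower filter index,
which makes the degenerate constant-volume case (all standard
deviations zero) deterministic.

Internally each filter is evaluated as a separable complex correlation
(one length-$N_s$ complex kernel per axis, real part taken at the
end), which is exact on the non-peripheral interior and turns a dense
$125$-point 3D correlation into three 5-point passes. The test suite
pins this machinery against naive triple-loop correlation and DFT
oracles.

### Clustering

Feature vectors are clustered into exactly two groups. k-means uses
`stats::kmeans()` with 10 restarts under a fixed seed. The GMM is a
2-component full-covariance mixture fitted by EM (at most 200
iterations, relative log-likelihood tolerance $10^{-4}$), initialized
from a k-means partition, with a fixed ridge of $10^{-6}$ added to
every covariance diagonal. The ridge is what keeps the fit well-posed:
after Gaussian smoothing, high-frequency filter responses are
numerically zero, so unregularized covariance estimates are singular.
We fit on a seeded uniform subsample of at most $2^{17}$ voxels — a
two-component model's parameters are estimated accurately from far
fewer vectors than a tomogram holds, and fitting cost is the pipeline's
main time sink — and then assign all voxels with the fitted model
(nearest centroid, or maximum posterior for the GMM).

Per-dimension standardization before clustering is available but *off*
by default. The three feature modes already produce commensurate
dimensions (raw intensities share one scale; filters are
L2-normalized), and rescaling every dimension to unit variance
amplifies exactly those dimensions that carry only noise; on the
bundled phantoms it visibly degrades the FFT-mode segmentations.

The cluster containing fewer voxels becomes the particle class —
particles occupy a minority of a tomogram. The assumption can fail
(e.g. a tomogram dominated by a dense organelle), so an `invert`
switch flips the mapping; an exact tie resolves to the model's first
cluster.

### Instances and centroids

CC labels maximal connected components (26-connectivity by default —
the permissive standard for blob-like particles). WS computes the
Euclidean distance transform of the mask, takes its local maxima as
seeds, thins seeds closer than `min_seed_separation` (set this to the
expected particle radius in voxels; default 3), and floods the negated
distance map from the seeds. Flooding is confined to each connected
component, so WS refines but never merges the CC partition — an
invariant the tests assert. Instances smaller than `min_size_voxels`
(default 5) are dropped to suppress "dusty" false positives; labels
are renumbered in descending size order for reproducible outputs.
Centroids are unweighted means of member-voxel coordinates, reported
0-based in the full-tomogram frame (crop offsets added), convertible
to Angstrom by multiplying with the voxel size.

### Evaluation

A prediction matches a ground-truth particle if their centroids are
within a distance threshold — 100 Å when truth is complete and exact
(simulations), 125 Å for real annotations whose own positions carry
error. Matching is one-to-one greedy by ascending distance, so one
prediction cannot satisfy several truths; on well-separated sets this
equals the exhaustive bipartite optimum (asserted in tests), and it is
never below half the optimum. Precision, recall and F1 follow, with
zero-denominator cases mapped to 0.

When annotations are incomplete, precision is meaningless, so we also
compute the *relative recall*

$$R_{rel} = \frac{2\,R\,(1 - R_{random})}{R + (1 - R_{random})},$$

the harmonic mean of the achieved recall and one minus the recall of
the same number of *uniformly random* predictions (Monte-Carlo, 20
seeded repetitions over the evaluation box). $R_{rel}$ lies in
$[0, 1]$, is monotone in both arguments, and — unlike F1 at constant
precision — *penalizes* overprediction: as predictions grow, random
placement catches up and $1 - R_{random} \to 0$. The tests construct
exactly this regime.

## The phantom generator

Real tomograms cannot ship with a package, so `generate_phantom()`
builds volumes with known truth: dark particles (intensity offset
$-0.25$, the cryo-ET density convention) on a uniform $0.5$ background
with additive Gaussian noise, at 10 Å/voxel. Four analytic shapes —
spheres, 0.7/0.55-axis-ratio ellipsoids, capsule-like rods, and tori —
are placed by rejection sampling with a minimum center separation and
random orientations; the exact analytic centers are the ground truth.
Packing restarts from scratch after 500 consecutive rejections so an
unlucky early placement cannot wedge a feasible configuration. An
optional idealized missing wedge zeroes a Fourier-domain wedge of
given half-angle about the Z axis (the DC term and the tilt-axis line
are kept), mimicking the anisotropy of limited-tilt reconstruction
without simulating a tilt series.

`phantom_suite()` provides four fixed-seed regimes on a
$48 \times 96 \times 96$ volume: `sparse` (20 particles, radius 4–7
voxels, separation 18, noise $\sigma = 0.1$, particle fraction
$\approx 4\%$), `crowded` (70 particles at separation 11), `low_snr`
(sparse geometry, noise $\sigma = 0.5$) and `wedge` (sparse plus a
30° missing wedge). These sizes keep a full twelve-workflow run on one
CPU in minutes while leaving several voxels of clearance around every
particle; the defaults of `phantom_config()` itself
($64 \times 128 \times 128$, 40 particles) describe a more typical
working crop.

**What the phantoms do not emulate:** CTF modulation, dose-dependent
noise correlation, crowding by membranes/filaments, gold fiducials,
and reconstruction artifacts beyond the idealized wedge. Passing the
phantom benchmarks therefore demonstrates the pipeline's mechanics and
its behavior under controlled contrast/noise/packing — not performance
on any particular real dataset.

## Behavior across workflows, honestly

On the sparse preset every k-means workflow recovers essentially all
particles (F1 $\ge 0.95$ at 100 Å), and `gabor-gmm` workflows perform
well. Two systematic weaknesses of the GMM branch are worth knowing
about, and both match its known failure modes on sparse data:

* A maximum-likelihood 2-component mixture fitted to a volume that is
  96% smooth background prefers to spend its second component on the
  background tail plus the partial-volume halo around particles,
  inflating the "particle" cluster several-fold. CC on such a mask
  under-segments (merged blobs), while WS largely rescues it.
* The FFT-GMM combination additionally produces dusty masks with many
  spurious small components; the size filter removes single voxels but
  not all dust clumps.

Both effects are amplified at phantom scale, where the blur width
($\sigma = 2$) is large relative to particle radii (4–7 voxels), so
halo voxels are a bigger fraction of each particle than in a
production-size tomogram. The package reports per-workflow metrics
precisely so that such differences are visible rather than averaged
away; on data like these, the k-means workflows (or `gabor-gmm-ws`)
are the right choices.

## Numerical and design choices

* **Axis order** is `(z, y, x)` internally (MRC section order);
  coordinate *files* use `x,y,z` columns. Coordinates are 0-based
  voxel indices; Angstrom values are voxel coordinates times the
  (scalar, isotropic) voxel size. Anisotropic header voxel sizes are
  rejected beyond a 1% tolerance because the distance thresholds
  assume one scalar.
* **Determinism**: every stochastic step (fit subsampling, k-means
  restarts, Gabor selection subsampling, Monte-Carlo baseline, phantom
  generation) runs under a seed derived from the caller's master seed
  and a per-stage tag, so `run_all()` reproduces twelve independent
  `run_workflow()` calls bit-for-bit.
* **Degenerate inputs**: constant volumes error in `fit_clusters`
  ("no two-cluster structure") with the failing stage named;
  zero-variance feature dimensions are dropped and recorded; an empty
  mask yields zero instances, and empty particle sets evaluate to
  precision = recall = F1 = 0 rather than erroring.
* **Tie-breaks** are all fixed and documented: filter selection by
  lower index, cluster polarity tie to cluster 1, instance relabeling
  by size then first occurrence, matching by distance then prediction
  then truth index, watershed flooding FIFO within equal heights.
* **Problem sizes**: the bundled benchmarks use the
  $48 \times 96 \times 96$ presets above; unit tests use volumes
  $\le 32^3$-scale and brute-force oracles on $\le 9^3$ volumes, where
  naive triple loops are exact and fast.

## Limitations

Centroid-based localization mislocates elongated, branched or lobed
particles (a rod's centroid may lie outside thin curved shapes such as
membranes). The two-cluster model cannot separate particle types, nor
distinguish particles from dense contamination; `k > 2` clustering and
shape-aware extraction are natural extensions but out of scope. The
missing-wedge model is a binary Fourier mask, not a projection
simulation. Only isotropic voxels are supported.
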