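---
title: "owhscreen: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{owhscreen: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`owhscreen` analyses multi-modal neuroprotection screens in organotypic
whole-hemisphere (OWH) brain-slice cultures injured by oxygen–glucose
deprivation (OGD) and treated with two drugs alone and in combination. This
vignette records the science each module implements, the parameters that
matter, what the synthetic generators do and do not emulate, and the design
choices made where the methodology left the design open.

## 1. Nucleus quantification

**Model.** Pyknotic nuclei — condensed, compact chromatin from programmed
cell death — appear in DAPI images as small, bright, round blobs; healthy
nuclei are larger and dimmer. The pipeline is: min–max intensity
normalization to [0, 1]; a high-pass filter (identity minus a σ = 1 px
Gaussian blur, negatives clipped) to remove slowly varying background; a
mask zeroing pixels below 10% relative intensity; multi-scale
Laplacian-of-Gaussian (LoG) detection with 25 scales between σ = 0.863 and
5.179 px, absolute response threshold at 0.5% of the maximum pixel
intensity, and 0.7 overlap pruning; and a marker-seeded watershed that
partitions the foreground among detections so touching nuclei get disjoint
member-pixel sets, each capped at radius 2σ√2 from its centre.

Two numerical points deserve note. First, the LoG is convolved over the
*continuous* high-passed image (kept as an attribute by
`preprocess_image()`), while the 10% mask defines where detections may sit
and which pixels count as nucleus territory; running the convolution over
the hard-masked image would manufacture responses along the mask edge.
Second, the scale bounds are interpreted in pixels as printed; because the
pixel side is 0.863 µm the micrometre reading differs by that factor, and
`sigma_units = "um"` switches to it.

**Features.** Each nucleus gets eight features: area `A = n·a`
(`a = 0.863²` µm²), Crofton four-direction perimeter `P`, ideal radius
`r_I = √(A/π)`, eccentricity `P/(2π·r_I)`, average normalized intensity
`I_M = (1/n)·Σ I_i·d_i`, total `I_T = A·I_M`, weighted
`I_W = Σ I_i·d_i / Σ d_i`, and the detection scale σ. `I_M` includes the
distance factor `d_i` (pixels from the detection centre) by definition —
unusual for something called an average intensity, but it is computed
exactly as stated; for a single-pixel nucleus, where all distances vanish,
`I_W` falls back to that pixel's intensity. The Crofton estimate is
`P = (π/8)·(I₀ + I₉₀ + (I₄₅ + I₁₃₅)/√2)·pixel_size` from boundary-crossing
counts along the four lattice directions; it is within 2% of the analytic
circumference for a radius-20 digital disk and within 10% for squares.

**Classifier.** A random forest (bagged CART trees, per-node feature
subsampling, probability-machine formulation on the 0/1 label) is trained
on all annotated pyknotic nuclei plus a 3× random subsample of non-pyknotic
ones, with an 80:20 holdout and 5-fold CV inside the training partition. No
tree-ensemble package is available in the target environment, so the CART
tree is implemented in C++ with variance splits (equivalent to Gini for
binary 0/1 responses); 200 trees, `mtry = √p`, seeded. Counts are reported
per image with the pyknotic fraction log-transformed as
`log(fraction + 0.5/total)` — a half-count pseudo-fraction guarding zero
counts in a right-skewed quantity.

## 2. Microglial shape modes

**Model.** Cells are segmented by Otsu threshold, holes filled, objects
under 25 px and border-touching cells removed; 512×512 images are split
into four quadrants to multiply training images; a stratified 80:20 split
guarantees at least two images per sex × region × treatment stratum in the
training partition (the spec's constraint is ambiguous about which
partition "remains"; the larger one is used and the choice is an argument).
Nine standard morphology parameters are computed from the pixel set (area,
Crofton perimeter, circularity `4πA/P²`, second-moment ellipse eccentricity
and axes, solidity against the lattice-point count inside the convex hull,
extent, aspect ratio, orientation; a 1/12 Sheppard-style term makes moments
of a w-px bar equal `w²/12` so the aspect ratio of a 30×3 bar is exactly
10).

Shape modes: each cell's closed outer contour (Moore boundary tracing in
C++) is resampled to 50 equally spaced boundary points, registered —
centroid at the origin, unit RMS radius, counter-clockwise orientation,
then rotated so the boundary point farthest from the centroid sits at angle
0 and starts the sequence — flattened to a 100-vector, decomposed by PCA,
and k-means (k = 5, 20 restarts, seeded) clusters the components explaining
95% of the variance. Anchoring both rotation and cyclic phase to the
farthest point is the key numerical choice: principal-axis frames or
Procrustes-to-the-mean leave near-symmetric cells (disks, bumpy disks) at
arbitrary phases, which inflates within-family variance and collapses
cluster recovery. Registration removes size, so modes encode shape only;
size differences are carried by the morphology parameters. Population
totals are estimated by multiplying test-image counts by 5 (the inverse of
the 20% test fraction).

## 3. Drug-combination synergy

Effects are computed on group means of per-slice outcomes with the
untreated OGD group as reference: `delta_X = mean(OGD) − mean(X)` (positive
= protection) and fractional effect `f_X = delta_X / (mean(OGD) −
mean(control))`. Mixed-model inference is out of scope; significance comes
from seeded two-sided label-permutation tests (default 10,000 shuffles).
Four models produce verdicts, all with strict inequalities (ties =
no-synergy, a conservative tie-break):

* **Combination subthresholding** — neither monotherapy significant, the
  combination significant and protective.
* **HSA** — `delta_AB > max(delta_A, delta_B)`.
* **Response additivity** — `delta_AB > delta_A + delta_B`.
* **Bliss independence** — expected `f = f_A + f_B − f_A·f_B`; synergy when
  observed `f_AB` exceeds it. Bliss assumes both drugs protective alone;
  when a mono fractional effect is ≤ 0 the verdict is still reported but
  flagged `NA-conditions-unmet`. Fractional effects are not clipped — the
  flag, not truncation, carries the information.

When planted effects sit exactly on a model's boundary (observed = expected)
the verdict is a coin flip by construction; the test suite treats that
boundary behaviour as a calibration property, not a pass/fail gate.

## 4. Graphical networks

The precision matrix is the inverse of the *n*-denominator (maximum
likelihood) covariance — no regularization; rank-deficiency is an error
rather than a silent ridge fallback. Partial correlations are
`ρ_ij = −θ_ij/√(θ_ii·θ_jj)`. Edges are selected by Fisher-Z confidence
intervals with the partial-correlation degrees-of-freedom correction
`SE = 1/√(n − (p−2) − 3)` (k = p − 2 conditioned variables); an edge is
significant iff its CI excludes zero, and 99% edge sets nest inside 95%
ones. Binary condition indicators (e.g. OGD vs control) enter as numeric
0/1 columns, coded by order of first appearance unless given explicitly —
point-biserial partial correlations; swapping the coding flips
condition-edge signs without changing significance.

## 5. Targeted-panel transcriptomics

Counts are normalized per sample by the geometric mean of housekeeping
transcripts (default: all transcripts positive in every sample), then
`log2(x + 1)`; this makes the result invariant to global per-sample
scaling. The exact scheme used upstream of nCounter data is not specified
anywhere authoritative, so pre-normalized matrices can simply skip the
step. Differential expression is a per-transcript Welch t-test on log2
values vs the reference group, reported at raw p < 0.05 (no multiplicity
correction by default, matching the upstream analysis; BH is an argument).
PCA is computed on transcript-centred values without unit-variance scaling,
keeping contributions (`100·loading²/Σloading²`) on the expression scale;
the selected component count is the smallest k reaching 95% cumulative
variance. The "normalized by the combination only" filter returns
transcripts significant after OGD, still significant under each
monotherapy, but no longer significant under the combination; an
alternative reading ("significantly shifted back toward control") is
implemented behind `definition = "reversed"`. Gene-set enrichment is a
local hypergeometric tail test with BH adjustment — a substitute for
external web tools, not a reproduction of their backends.

## 6. Emergent-synergy detection

For each transcript the mean log2 expression in the combination group is
predicted from the four single-condition group means by a bagged-tree
regressor with 10-fold *pre-validated* predictions: transcripts are
partitioned into seeded folds and each fold is predicted by a model trained
only on the others, so no transcript's own target can leak into its
prediction (the suite verifies that a unique planted outlier cannot be
memorised). A full Bayesian tree ensemble is unnecessary for this
inferential step — only honest out-of-fold point predictions enter the next
stage — so the regressor is the package's bagged CART forest. Measured
values are regressed on predictions by OLS (prediction intervals are for
the measured value; the grammatically ambiguous alternative direction is a
flip of two arguments) and standard 95%/99% prediction intervals flag
outliers; `z_diff` reports |measured − predicted| in units of the SD of
measured expression across transcripts in scope (`sd_reference =
"residual"` switches to the regression residual SD). A numerically exact
fit (residual scale ~0) flags nothing.

## 7. The synthetic stated world

The generators produce every input with known ground truth at the study's
scale: five groups × three regions, n = 12 slices/group for outcomes, a
255-transcript panel with 6 samples per group × region, 512×512 px images
at 0.863 µm/px.

* **Nucleus fields**: isotropic Gaussian spots; pyknotic σ ∈ [1, 2] px with
  peak 1.5–2× the non-pyknotic spots (σ ∈ [3, 5] px); seeded
  rejection-sampled centres with a minimum separation. Noise emulates
  confocal DAPI acquisition: constant background (0.05), a weak σ = 3 px
  autofluorescence texture field (SD 0.005), and Poisson shot noise at 10⁵
  detected photons per unit intensity. DAPI is a bright stain; the defaults
  put images in the structure-limited regime (background-relative peak SNR
  far above the benchmark floor of 10). White pixel noise at percent level
  would defeat the printed detection parameters for *any* implementation —
  a σ = 3–5 px Gaussian blob keeps only ~1/(s²+1) of its amplitude after
  the σ = 1 px high-pass — which is why the noise model is band-limited;
  real confocal backgrounds are photon-limited at roughly the simulated
  level.
* **Microglia**: five parametric families — rod (48×7 px ellipse),
  intermediate1 (moderate ellipse), ramified (disk + 5 thin radial
  branches), intermediate2 (disk + 3 wide bumps), ameboid (disk) — each a
  single prototype with ±10% jitter and random rotation. Branch counts are
  fixed per family so a family is one shape population, not a mixture.
  Prototype sizes were chosen once at a scale where rasterization noise
  does not degenerate thin contours.
* **Expression panel**: additive Gaussian noise (SD 0.25) on the log2
  scale around group × region means; planted DEGs shift the OGD mean by
  ±1 log2 unit with treatments recovering configured fractions (defaults:
  Az and Epo 30%, the combination 90%); planted emergent transcripts add a
  ±6·noise_sd offset to the combination mean only, so they are orthogonal
  to any deterministic map of the four predictor means.
* **Outcomes**: control at 0.4, untreated OGD at 1.0 (LDH-like absorbance
  units), treatment means interpolated by fractional effects, Gaussian
  slice noise SD 0.08 (CV ≈ 12% of the injury span). This value comes from
  a power analysis of the planted synergy scenarios at n = 12/group: the
  binding constraint is the response-additivity margin of the
  Bliss-additive scenario, which requires SD ≲ 0.097 for a ≥ 90%
  correct-verdict rate; percent-level replicate noise is also what
  plate-based cytotoxicity assays actually show.

What a green test does **not** establish: the generators share none of real
histology's texture (no anisotropic nuclei, no stain gradients, no
overlapping tissue layers, no uneven illumination), microglia are binary
masks rather than fluorescence intensities with out-of-focus light, and the
expression model is Gaussian on log2 scale rather than count-based
(negative binomial) — per-transcript variance is homogeneous by
construction. Benchmarks on this world certify the implementation, not
performance on real images.

## 8. Known limitations

* The LoG σ bounds' pixel-vs-µm ambiguity is config-exposed but
  unresolvable from the printed parameters alone.
* The subthresholding benchmark's expected pass rate is ≈ 0.95² ≈ 0.90 by
  construction (two mono type-I gates at α = 0.05), so that acceptance
  bound has essentially no margin; the frozen seeds pass.
* Shape-mode recovery (ARI ≈ 0.77 on the 5-family benchmark) is limited by
  genuine overlap between elongated families after scale-free registration,
  not by the clustering machinery.
* File I/O uses 16-bit grayscale PNG (no TIFF writer exists in the
  dependency set); in-memory matrices are the primary interface.
* NanoString RCC parsing is not implemented; expression enters as CSV
  (counts or pre-normalized log2).
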