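---
title: "Digital biopsies: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital biopsies: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiomic analyses compute large banks of quantitative features from a
volume of interest (VOI) in a CT scan. The bottleneck is the VOI
itself: a quality-controlled tumour segmentation takes an expert many
minutes per nodule, while a rough "digital biopsy" — a contiguous
painted sub-region that captures the tumour's gray-scale heterogeneity
but deliberately ignores its boundary — takes a fraction of that. The
question this package operationalizes: *which intensity and texture
features are robust to that substitution, and how robust do they stay
as simulated readers grow more conservative or more aggressive?*

The pipeline has four stages:

1. **Masks and volumes** (`volume_grid`, `voi_mask`): CT-like scalar
   lattices with explicit voxel spacing in mm, read and written as
   NIfTI-1 or NRRD. All geometry lives in physical units because
   clinical slice thickness varies several-fold (0.625–3 mm) across
   scanners.
2. **Reader simulation** (`simulate_readers`): spherical morphological
   erosion (with a closing to avoid fragmenting the VOI) and
   unconstrained dilation of the biopsy at physical radii 0.5, 1.0 and
   1.5 mm — 3 conservative and 3 aggressive synthetic readers plus the
   original.
3. **Feature extraction** (`extract_all`): a fixed 94-feature bank —
   19 first-order intensity statistics and 75 texture statistics from
   five families (24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM).
   Shape and margin features are excluded by construction: a biopsy
   has no meaningful boundary.
4. **Concordance** (`overlap`, `icc_a1`, `build_report`): volume
   agreement as intersection-over-union, and per-feature agreement as
   the two-way absolute-agreement intraclass correlation (ICC A-1)
   between the reference column and each variant column, aggregated
   into overlap tables, ICC curves, threshold counts and a robustness
   ranking.

## The agreement statistics

**Overlap.** For VOIs on one grid,
\[ O_k = \frac{|\mathrm{VOI}_1 \cap \dots \cap \mathrm{VOI}_k|}
             {|\mathrm{VOI}_1 \cup \dots \cup \mathrm{VOI}_k|}, \]
an exact integer-count ratio in \([0,1]\), permutation-invariant, and
1 iff all VOIs coincide. An empty union is flagged undefined rather
than reported as 0.

**ICC A-1.** Measurements form an \(n \times k\) matrix (subjects by
segmentation variants). With the standard two-way mean squares
\(MS_R\) (rows), \(MS_C\) (columns), \(MS_E\) (residual),
\[ \mathrm{ICC} = \frac{MS_R - MS_E}
   {MS_R + (k-1)\,MS_E + \tfrac{k}{n}(MS_C - MS_E)} . \]
This is the *absolute agreement*, single-measure form: a variant that
is systematically biased relative to the reference is penalized through
the \(MS_C\) term, which a consistency ICC would forgive. Per the
study design, comparisons are pairwise (\(k = 2\): reference versus one
variant); a pooled mode is available but off by default. Rows with any
missing cell are dropped per feature (complete-case). A fully constant
matrix is a 0/0 and is flagged undefined — it must never inflate
agreement counts.

Numerical notes: the residual sum of squares is obtained by
subtraction and clamped at zero against floating-point cancellation;
the statistic is invariant under common affine rescaling of the whole
matrix, which the tests assert.

## Feature-bank conventions

Every convention below is pinned so that values are exactly
reproducible and testable against brute-force oracles.

* **Quantization**: uniform bins over the in-mask intensity range,
  default `n_levels = 32`; `level = 1 + floor((x - min)/(max - min) L)`
  with the maximum mapped to \(L\). A constant region maps to level 1.
  Fixed bin *count* (rather than fixed HU width) is robust to the very
  different intensity ranges of ground-glass and solid nodules.
* **First order**: population variance/SD (divide by \(N\));
  skewness \(m_3/m_2^{3/2}\) and kurtosis \(m_4/m_2^2\) (uncorrected,
  normal \(\to\) 3), both 0 by convention on zero-variance regions;
  percentiles by linear interpolation (R type 7); histogram entropy and
  uniformity use the same 32-bin quantization as the texture families;
  total energy scales energy by the voxel volume in mm³.
* **Texture directions**: the 13 unique 3-D voxel directions at
  Chebyshev distance 1, on the native grid (no isotropic resampling —
  resampling would alter intensities before extraction). Statistics
  are averaged unweighted over directions; for the GLCM, directions
  with no valid in-mask pair (possible on single-slice masks) are
  skipped.
* **GLCM**: symmetric, normalized per direction; 24 statistics. The
  maximal correlation coefficient is excluded (numerically unstable on
  small VOIs); `sum_variance` completes the set of 24. Correlation of
  a zero-variance matrix is 1 by convention; `0·log 0 = 0` throughout
  (logs base 2).
* **GLRLM**: runs are maximal collinear same-level segments lying
  entirely inside the mask; run counts weighted by length sum to the
  in-mask voxel count per direction (asserted).
* **GLSZM**: zones are 26-connected equal-level components; the shared
  run/zone statistics are computed from a sparse (level, size, count)
  triplet form so one huge zone never allocates a dense matrix.
* **GLDM**: dependence of a voxel is defined as 1 plus the number of
  in-mask 26-neighbours with the same quantized level (centre
  included, so the small/large-dependence emphasis weights \(1/j^2\),
  \(j^2\) are always defined). 14 statistics.
* **NGTDM**: per-level counts and summed absolute deviations from the
  mean neighbour tone; voxels with no in-mask neighbour do not
  contribute; coarseness of a perfectly homogeneous VOI is capped at
  10⁶.
* **Undefined policy**: any feature that cannot be computed (texture on
  a single-voxel mask, ICC of a constant column pair) is `NA` plus an
  explicit flag, propagates as missing into the concordance stage, is
  excluded from threshold counts, and ranks below all fully-defined
  features. Silent zeros would manufacture fake agreement.

## Morphology conventions

* **Sphere discretization**: an integer offset belongs to the element
  iff its voxel-centre displacement has Euclidean norm ≤ radius (mm).
  On anisotropic grids the element adapts — at 0.7 × 0.7 × 2.5 mm
  spacing a 1.5 mm "sphere" is a flat in-plane disc. A radius smaller
  than the smallest spacing gives the identity element; in particular,
  on grids with in-plane spacing above 0.5 mm the 0.5 mm sweep step is
  a no-op, which is why the phantom experiment shows
  `erosion_0.5mm == original`.
* **Closing after erosion** uses the same element as the erosion
  (minimal assumption; configurable by calling the primitives
  directly). Closing can locally add voxels relative to the plain
  erosion, so the nesting chain across radii is only guaranteed for
  the plain erosion stage; the composed operation is validated against
  a brute-force composition oracle instead.
* **Boundary convention**: out-of-lattice voxels count as background
  for erosion and clip dilation growth. Phantom lattices carry enough
  padding (≥ 2 × the largest sweep radius) that the border is never
  reached in practice.
* **Emptied variants**: an erosion that consumes the mask is carried
  with an emptiness flag (its features become missing), never dropped,
  so cohort bookkeeping stays aligned.

## The phantom generator

The study's patient scans are not distributable, so the package ships
a generator whose defaults emulate the cohort it models:

| parameter | default | rationale |
|---|---|---|
| nodule volume | 10 cm³ (cohort: log-uniform 0.37–306 cm³) | the documented size range; 10 ≈ geometric mid-range |
| spacing | 0.7 × 0.7 × 2.5 mm (cohort: in-plane U(0.6, 0.9), slice log-U(1.25, 3)) | 512-grid chest CT; slice thickness up to 3 mm |
| background | −850 ± 40 HU | aerated lung |
| nodule texture | mean 0, SD 80 HU, correlation length 3 mm | soft-tissue attenuation with controllable heterogeneity |
| lobulation | 0.15 | non-convex boundaries so erosion/closing paths are exercised |

The nodule support is a lobulated ellipsoid; the realized voxel count
is matched to the volume target by thresholding the normalized radial
field, so the 5% volume contract is met to within one voxel. The
texture is white noise smoothed by a Gaussian of stated physical width
(FFT convolution), rescaled to the target mean/SD; its correlation
length demonstrably drives measured GLCM correlation (a rank
correlation the tests assert), which ties the generator to the feature
bank. All randomness is a pure function of the spec seed; cohort seeds
chain splitmix-style and are recorded in the manifest.

**Biopsy simulator.** A painted biopsy is emulated as a contiguous
axial slab (default 90% of tumour-bearing slices) carved inward from
the in-plane boundary: each slice keeps voxels whose exact Euclidean
distance to the background exceeds a jittered margin, and the global
margin is calibrated per subject by bisection so the realized overlap
with the reference hits the target (default 0.74, the regime of human
painters who cover about three quarters of the tumour). Carving by
distance-transform threshold rather than repeated erosion gives the
near-continuous control the bisection needs on small nodules. Under
the default containment flag the biopsy is a subset of the reference,
so overlap reduces to \(|B|/|R|\) exactly. Very small nodules whose
slab alone caps the overlap below target are calibrated to their
feasible maximum and flagged in the manifest.

**What the phantoms do not emulate** — and hence what passing tests do
*not* show about clinical data: CT reconstruction physics (kernels,
beam hardening, dose/noise coupling), anatomy beyond an optional
chest-wall slab (vessels, pleural attachment), human painting styles
beyond slab + margin + jitter, and inter-scanner protocol effects.
Conclusions about specific clinical ICC values do not transfer; the
pipeline's *behaviour* (trends, invariants, bookkeeping) is what the
phantom experiment certifies. One visible consequence: dilations here
expand into uniform air and depress texture agreement more sharply
than in real anatomy.

## Reporting

`build_report()` emits the per-variant overlap table (mean, SD,
median, minimum, maximum, in percent), the per-feature per-variant ICC
table with curves sorted descending per variant, counts of features
with ICC strictly above 0.6/0.7/0.8/0.9 (strict inequality, the
conventional reading of "ICC > 0.7 = excellent agreement"; undefined
ICCs never counted; denominator fixed at 94), and a cross-variant
ranking by mean ICC with ties broken by minimum ICC then name — a
deterministic rule, chosen because no canonical ranking rule exists
for such lists.

## Problem sizes and tolerances in the test suite

Oracle tests run on exhaustive brute-force reference implementations:
morphology on 200 random ≤ 8³ masks (tolerance: exact equality),
texture families on 50 random ≤ 6³ volumes (1e-9), ICC on 1000 random
matrices against an explicit sum-of-squares decomposition (1e-10) and
against R's `aov()` two-way route. Estimator calibration uses 1000
replicates of a 500 × 2 two-way model with known variance components
(bias < 0.01). The end-to-end experiment uses a 30-phantom cohort over
the full 0.37–306 cm³ size range with default sweep radii; it checks
the 0.74 ± 0.05 calibration, monotone erosion overlap decay, all-ones
copies-as-variants controls, and bit-identical reruns under a fixed
seed. These sizes keep the whole suite in the low minutes on one core
while still exercising every code path at full fidelity.

## Known limitations

* DICOM series are not read; conversion to NIfTI/NRRD happens
  upstream.
* No resampling/registration: volume and mask must share a grid
  (shape exact; spacing/origin within 1e-3 mm).
* The 94-name bank is this package's documented composition of the
  standard five families; other radiomics tools order and name
  features differently, so cross-tool comparisons need a name map.
* ICC confidence intervals are not computed (point estimates only),
  and only the A-1 estimator is exposed.
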