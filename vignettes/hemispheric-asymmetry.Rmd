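---
title: "Hemispheric asymmetry mapping: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric asymmetry mapping: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiAsym)
```

## The biological question and the model

Structural asymmetry between the left and right cerebral hemispheres changes
during the course of degenerative dementia: in early amnestic mild cognitive
impairment the hemispheres tend to become *more* symmetric than in normal
ageing, while established Alzheimer's disease is accompanied by a marked
*increase* in asymmetry, particularly in subcortical structures. hemiAsym
operationalizes this observation for 2D brain-slice images: if a slice can
be brought into a frame where its midsagittal axis coincides with the image's
vertical midline, then the difference between the slice and its mirror image
is a direct picture of hemispheric asymmetry, and summary statistics of that
difference image are candidate biomarkers for classification.

The pipeline has five stages:

1. **Standardization** — resample to 256×256 (bilinear, pixel-center
   aligned), min-max rescale intensities to span [0, 255].
2. **Skull stripping** — retain pixels inside a configurable intensity band
   `[lower, upper]` and keep only the largest 8-connected surviving
   component. This is a deliberate stand-in for interactive threshold
   segmentation; any dedicated brain-extraction tool can be substituted
   upstream, since later stages only require a zero background.
3. **Symmetry alignment** — binarize, move the brain-mask centroid to the
   image center, then grid-search the in-plane rotation that minimizes the
   mirror-difference objective.
4. **Asymmetry map** — `D = clip0(I − mirror(I)) + clip0(mirror(I) − I)`,
   the two-way saturating subtraction of the aligned slice and its vertical
   mirror. Written this way (hemisphere-minus-hemisphere in both directions,
   each floored at zero, then summed) the map equals `|I − mirror(I)|`
   elementwise; bilaterally symmetric pixels are exactly 0, and asymmetric
   structure appears at its own location and its mirrored location.
5. **Features and classification** — a fixed 10-statistic vector and an
   optional bag-of-visual-words encoding per image, evaluated with eight
   classical binary classifiers under 10 runs of stratified 10-fold
   cross-validation.

A note on stage 4: a naive algebraic reading of "(L − R) + (R − L)" cancels
to zero in real arithmetic. The operative definition is 8-bit *saturating*
subtraction, in which each directed difference floors at zero; their sum is
the absolute mirror difference. This reproduces the defining property that
symmetric areas are exactly zero while asymmetric areas carry gray levels
1–255.

## Symmetry alignment: objective and numerical choices

The alignment objective is the mean squared difference between the image and
its vertical mirror over the *union support* (pixels where either is
nonzero). Restricting to the support makes the score insensitive to how much
empty background surrounds the brain; it is zero iff the slice is perfectly
mirror-symmetric there.

Choices that were genuinely open, and what this package does:

* **Centroid.** The unweighted centroid of the binarized brain mask, with an
  intensity-weighted centroid available (`weighted_centroid = TRUE`). For
  alignment the default binarization threshold is 0 — after skull stripping
  the whole nonzero footprint *is* the brain mask, and its centroid is the
  brain center. An Otsu threshold computed on nonzero pixels
  (`threshold = "auto"`) is available for images whose background has not
  been zeroed; note that on a stripped slice Otsu selects a level inside the
  tissue distribution, which biases the centroid toward bright texture and
  costs pose-recovery accuracy.
* **Rotation search.** Exhaustive grid over ±15° in 0.5° steps (both
  configurable), bilinear interpolation about the geometric image center
  `((H−1)/2, (W−1)/2)`, zero fill. Exhaustive search is deterministic,
  testable against its own grid, and immune to local minima; at 256×256 one
  image costs about two seconds, which is acceptable for slice-level
  analysis. Ties are broken toward the smallest |angle|, then toward the
  negative angle, so a circularly symmetric input yields exactly 0°.
* **Coordinates.** 0-based (row, col) everywhere; for even width the mirror
  axis lies between columns W/2−1 and W/2. Rotation by exactly 0° and
  integer-pixel translations are performed without resampling, so the
  no-op path is bit-exact.

## The ten statistics

The feature vector order is fixed:
(MSE, Mean, Std, Entropy, RMS, Variance, Smoothness, Kurtosis, Skewness,
IDM).

* **MSE** is the mean squared difference between the *aligned slice* and its
  vertical mirror — computed from the original intensities, without any
  wavelet transform. It is the single most interpretable number: total
  hemispheric asymmetry energy.
* The remaining nine are computed on the **approximation subband of a
  single-level 2D Haar DWT** of the asymmetry map. Haar (db1) at level 1 is
  the default because it is the simplest orthogonal wavelet, admits exact
  small-case oracles (the approximation of a constant *c* image is the
  constant 2*c*), and conserves energy across subbands; both the wavelet
  name and level are configuration should other families be added.
* Moments (Mean, Std, Variance, RMS, Kurtosis, Skewness) use population
  (biased) estimators; kurtosis is non-excess, so a Gaussian subband scores
  3. The identities `Variance = Std²` and `RMS² = Mean² + Variance` hold to
  numerical precision and are asserted in the test suite on every generated
  map.
* **Entropy** is Shannon entropy in bits of the 256-bin histogram of the
  subband min-max rescaled to [0, 255]; it lies in [0, 8].
* **Smoothness** is `1 − 1/(1 + σ²)` with σ² the variance of the subband
  rescaled to [0, 1] (the Gonzalez–Woods texture convention), so it lies in
  [0, 1).
* **IDM** (inverse difference moment) is `Σ P(i,j)/(1 + (i−j)²)` over a
  *normalized, symmetric* 256-level co-occurrence matrix at offset (0, 1),
  bounded in (0, 1] with 1 attained by a constant image. An unnormalized
  variant (`idm_normalized = FALSE`) is provided for compatibility with
  implementations that report raw co-occurrence sums, which can reach 10³–10⁴
  on a 256×256 map.

Degenerate input is given a defined contract rather than NaNs: an all-zero
map yields zeros for the eight subband statistics (kurtosis/skewness are
undefined for a constant sample and are reported as 0 with a warning) and
IDM 1, while MSE is still computed from the originals.

All ten statistics are invariant under horizontal mirroring of the map —
the mirrored map has the same histogram and a transposed-symmetric
co-occurrence structure — which the suite verifies directly.

## Bag of visual words

Local structure is encoded with the standard detector–descriptor–codebook
chain: a determinant-of-Hessian blob detector over scales σ ∈ {2, 4, 8}
(the detection principle behind SURF), a 64-dimensional descriptor of
gradient sums `(Σdx, Σdy, Σ|dx|, Σ|dy|)` over a 4×4 grid of subregions (the
SURF descriptor layout), retention of the strongest 80% of keypoints, and
K-Means quantization with k-means++ seeding under a fixed seed. Images are
encoded as L1-normalized occurrence histograms; an image with no detectable
structure falls back to a dense keypoint grid, and an image yielding no
descriptors encodes as a uniform histogram with a warning. The default
vocabulary size is k = 500 for realistic corpora; small synthetic studies
use smaller k so that the descriptor pool exceeds the vocabulary.

Descriptors are computed on the asymmetry map (not the aligned slice):
the map is where disease-related signal concentrates, and features collected
there describe exactly the regions that differ between hemispheres.

## Classifiers and the cross-validation protocol

Eight specifications, fixed and untuned: Gaussian naive Bayes; linear
discriminant; SVMs with linear, quadratic, cubic and medium-Gaussian
kernels (box constraint 1, standardized inputs; polynomial kernels
`(1 + ⟨x/s, y/s⟩)^d` with the scale *s* set by the median pairwise-distance
heuristic on the training fold, the Gaussian kernel with the fixed manual
scale 32); 1-NN with Euclidean distance; and 10-NN with cosine distance
(implemented as Euclidean 10-NN on L2-normalized standardized rows, which
induces the same neighbor ranking).

The protocol is 10 runs of stratified 10-fold cross-validation, fold
assignments reshuffled each run from a single master seed, so an identical
seed reproduces an identical report byte for byte. Everything data-dependent
is fitted on training folds only: feature standardization, the SVM kernel
scale, and — when bag-of-features columns are enabled in the pipeline — the
K-Means codebook itself, refitted inside every training fold. The test suite
contains a leakage canary: a feature equal to the class label must drive
accuracy to 100% when present, and a fold-preprocessing hook that only knows
labels of its training rows must stay at chance.

Per-fold confusion counts are kept; accuracy, sensitivity (recall of the
disease class, which is always the positive class of a pair) and specificity
are averaged over all folds of all runs, with standard deviations over run
means. ROC curves are built by a threshold sweep over pooled out-of-fold
scores (SVM margins, KNN vote fractions, NB/LD posteriors); with tied scores
grouped per threshold, the trapezoid AUC equals the rank-average
Mann–Whitney statistic U/(n₁n₂), which the suite checks against a
pair-counting oracle to 10⁻¹².

Whether to average fold-level accuracies or pool confusion matrices was an
open choice; fold-averaging was selected and is recorded in the report
object (pooling gives the same value for balanced folds).

## The phantom generator: what it emulates and what it does not

`generatePhantom()` renders a 256×256 slice from geometric primitives: an
elliptical tissue region with smooth random texture made *exactly*
mirror-symmetric by construction (the texture is averaged with its own
mirror), a mirrored pair of dark medial ventricles, a bright skull ring
separated from tissue by a dark gap, and `n_lesions` unilateral Gaussian
blobs that are the sole source of ground-truth asymmetry. Pose (rotation,
then translation) and additive Gaussian noise are applied after rendering,
in that order, so alignment always faces noisy mirror residuals. Lesion
profiles are truncated where they fall below 10⁻⁶ of peak, giving compact
footprints (radius ≈ 5.26σ) so "the map is nonzero only on lesion footprints
and their mirrors" is an exact, testable statement.

Default study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| class amplitudes | EMCI 2 < NC 6 < AD 14 | reproduces the clinical ordering: early impairment is *more* symmetric than normal ageing, dementia much less |
| lesions | 3 per image, radius 6 px | focal, subcortical-scale perturbations |
| noise | σ = 2 intensity units | visible but not dominant at 8-bit scale |
| cohort pose | none (aligned frame) | see below |
| pose benchmark | ±10°, ±10 px | typical slice misalignment |

Cohorts are rendered in the aligned frame by default because cohort-level
claims (e.g. the Pareto ordering of class mean MSE) are statements about
*lesion content*; residual pose error of even a pixel contributes mirror-MSE
comparable to the smallest class amplitude and would confound the
comparison. Pose perturbation is switched on explicitly
(`pose_max_deg`, `pose_max_shift`) for alignment benchmarks, which assert
recovery to within 1 px and one 0.5° grid step in ≥95% of cases.

What the phantoms do **not** model: MR physics (no bias field, no partial
volume, no Rician noise), anatomical detail (no gyri, no atlas geometry),
bilateral-but-asymmetric structures, and the natural petalia/torque
asymmetry of healthy brains. Passing phantom-based tests therefore
demonstrates that the *algorithms* are correct and the harness is leak-free
— not that the measured effect sizes transfer to clinical MRI, which
remains access-controlled.

## Problem sizes used in validation

The shipped test suite and acceptance script use cohorts of 30 images per
class (the Pareto-ordering replication uses 100 independent 30/class
cohorts), 50 posed phantoms for pose recovery, and the full 10×10
cross-validation protocol on the synthetic binary datasets. These sizes were
chosen so the entire validation runs in minutes on a single core while
keeping Monte-Carlo error well below every asserted margin.

## Known limitations

* The rotation search is exhaustive on a fixed grid; accuracy is bounded by
  the grid step, and the translation estimate is bounded by centroid
  accuracy under noise (no joint refinement of pose).
* Skull stripping by intensity banding fails on slices where brain and
  skull intensities overlap; it is a placeholder for proper brain
  extraction.
* The printed reference feature vector that circulates for this kind of
  pipeline is internally inconsistent under any single set of standard
  formulas (its variance does not square its standard deviation, and its
  IDM exceeds 1 by orders of magnitude); hemiAsym adopts the canonical
  definitions above and documents the compatibility flag rather than
  attempting to reverse-engineer a non-reproducible convention.
* Single 2D slices only: no midsagittal-plane fitting in 3D, no nonrigid
  registration, no atlas normalization.

## A minimal end-to-end example

```{r example, eval = FALSE}
co <- generateCohort(10, seed = 7)
out <- runPipeline(co, pipelineConfig(runs = 2, folds = 5, seed = 7),
                   out_dir = tempfile("hemiasym"))
out$pareto          # class totals of mirror MSE, Pareto-ordered
out$reports[["AD vs. NC | C-SVM"]]
```
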