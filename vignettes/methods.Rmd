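---
title: "Methods: texture descriptors, rebalancing, selection and LM training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture descriptors, rebalancing, selection and LM training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammotex)
```

This vignette is the package's account of its own methods: the models
and procedures it implements, the parameters that matter, the numerical
conventions that make results bit-reproducible, and what the synthetic
test conditions do and do not demonstrate.

## The problem

Computer-aided diagnosis of mammograms by hand-crafted texture:
each grayscale image is reduced to an 88-dimensional descriptor vector,
the strongly imbalanced multiclass label distribution (eight BI-RADS
assessment categories, reference counts 67/220/24/13/8/21/50/8) is
rebalanced by adaptive synthetic oversampling, the feature set is cut
to the ten most discriminative attributes, and a feedforward network
trained by Levenberg–Marquardt produces the class decision, evaluated
with one-vs-rest confusion-matrix metrics.  No segmentation or other
preprocessing is applied: descriptors see the full image.

## Texture descriptors

**Quantization.** Co-occurrence and run-length matrices are computed at
32 gray levels (`feature_config(glcm_levels = 32)`).  At native 12- or
16-bit depth these matrices are almost empty and their statistics
meaningless; 32 levels is standard texture practice and keeps an
8-bit or deeper mammogram's matrix densely populated.  Quantization is
the monotone map `floor(v * n_levels / old_levels)`.

**GLCM.** Distance-1 offsets in the four directions (0°, 45°, 90°,
135°), symmetric and normalized; features are averaged over directions
rather than concatenated, which keeps the vector at 22 entries while
respecting all four adjacency paths.  The 22 statistics are the
canonical Haralick/Soh/Clausi set, with gray index counted from 1,
entropies in bits (0·log 0 := 0), information measures of correlation
with natural logs, and guarded degenerate denominators (a constant
image yields correlation 0, not NaN).  The 22nd distinct statistic is
Haralick's maximal correlation coefficient (second eigenvalue of the
transition-style matrix Q), so no statistic appears twice.

**LBP.** 8 neighbors at radius 1, ordered counterclockwise from east,
threshold rule `s(g_p − g_c) = 1` iff `g_p ≥ g_c` (ties count as 1, so
a constant image codes 255).  Border pixels are dropped.  The
histogram uses the rotation-invariant uniform mapping: patterns with at
most two circular 0/1 transitions are binned by their number of set
bits (9 bins), everything else shares a tenth bin.  A 90° image
rotation permutes neighbors cyclically by two positions, so this
histogram is exactly invariant — one of the property tests.

**LBGLCM.** The 22 GLCM statistics of the LBP code image, after the
codes (0–255) are re-quantized to 32 levels; a pure composition with no
new mathematics, asserted in tests as identical to the explicit
two-step computation.

**GLRLM.** Maximal runs per direction; the seven Galloway/Chu features
in their normalized forms (SRE, LRE, GLN, RLN, RP, LGRE, HGRE) with
gray index from 1 and `n` the number of runs.  Run conservation
`ΣΣ j·P(i,j) = n_pixels` is asserted for every direction.

**SFTA.** `nt = 5` thresholds from a dynamic-programming multilevel
Otsu (exact maximizer of between-class variance for any `nt`;
ties broken toward the smallest threshold vector; a threshold `t`
separates `≤ t` from `> t`).  The binary stack has the `nt − 1`
contiguous band images `t_i < v ≤ t_{i+1}` and `nt` upper images
`v > t_i` — `2·nt − 1 = 9` images, each contributing border fractal
dimension, foreground mean gray level and foreground size, hence 27
features and the 88 total (22 + 22 + 7 + 10 + 27).  Conventions:
border pixels are foreground pixels with a background 4-neighbor
*inside* the image (so a half-plane's border is the separating line,
not the image frame); an empty foreground contributes (0, 0, 0) rather
than NaN; box counting uses dyadic box sizes from 1 to half the
smaller image side, grid anchored at the top-left corner, and the
least-squares slope of log N versus log(1/s).  Images with fewer
distinct levels than `nt` (e.g. constant images) fall back to their
distinct levels padded with the maximum, leaving degenerate bands
empty — feature vectors are always finite and of fixed length.

## ADASYN

Every class whose imbalance ratio `d = m_s/m_l` against the largest
class is below `d_threshold = 1` receives
`G = round((m_l − m_s)·β)` synthetic rows, `β = 1` by default (full
balancing, e.g. 67 → 220 via `G = 153`).  Difficulty weights are the
fraction of each minority point's `K = 5` Euclidean nearest neighbors
— searched over the whole dataset on features standardized to zero
mean and unit variance, so no large-magnitude feature dominates — that
carry a different label; weights are normalized (uniform fallback when
all are zero) and converted to integer counts by largest-remainder
rounding with lowest-index ties, so the counts sum to `G` exactly and
harder points never receive fewer synthetics than easier ones.
Synthesis interpolates `s = x_i + λ(x_z − x_i)`, `λ ~ U(0,1)`, with
`x_z` drawn from the `K` nearest *same-class* neighbors in original
feature space — every synthetic row is a convex combination of two
same-class originals, asserted per coordinate in tests.  Single-sample
classes duplicate their seed with a warning.  K = 5 is the original
ADASYN default; the reference study does not state its value.

## ReliefF

Weights accumulate over a deterministic full sweep of the data
(`m = "all"`, index order) — random instance sampling is supported but
a full sweep at desk scale costs little and removes one seed.  For each
instance: `k = 3` nearest hits, and per other class `k = 3` nearest
misses, weighted by `P(C)/(1 − P(class(T)))` (the standard multiclass
prior correction).  Distances are Manhattan sums of range-normalized
attribute differences — the metric implied by the update rule itself —
making weights invariant to any affine rescaling of a feature column
(tested at ×1000).  Constant features get weight exactly 0.  Selection
keeps the `n_select = 10` top-ranked features, ties toward the lower
index.  `weight_curve()` provides the cross-validated
accuracy-versus-feature-count diagnostic with a 1-NN default
classifier.

## The network and its training

Architecture `p`–40–20–10–8: tanh hidden layers, softmax output, one
unit per class.  A literal reading of the reference design gives the
first hidden layer a linear transfer; since stacked linear layers
collapse, tanh is the default and `layer1_linear = TRUE` reproduces
the literal variant.

Levenberg–Marquardt needs residual structure, so training minimizes
the sum of squared residuals `e = target − output` over one-hot
targets; multinomial cross-entropy — the loss a softmax classifier
would normally use — is computed and logged per epoch as a monitoring
metric, resolving the tension between the two conventions explicitly.
The residual Jacobian is assembled by per-output backpropagation
(columns ordered layer by layer, `vec(W)` then bias), and verified
against central finite differences to 1e-5 in tests.  The update
solves `(JᵀJ + μI) Δw = Jᵀe` by Cholesky, applied as `w ← w − Δw`
(the descent direction for a residual Jacobian); at `μ = 0` on a
linear problem a single step lands on the least-squares optimum, also
a frozen test.  Damping: `μ0 = 1e-3`, ×10 on rejection, ×0.1 on
acceptance, overflow at 1e10 — conventional values.  Stopping: 100
epochs by default, gradient norm below 1e-7, damping overflow, or six
consecutive validation-error increases on the stratified 60/20/20
split.  Inputs are standardized by training-split statistics.
Accepted-step training error is strictly decreasing by construction;
the recorded history exposes error, cross-entropy, μ and gradient norm
per epoch for `plot()`.

## Synthetic data: what it shows and what it cannot

`make_texture_dataset()` draws stationary Gaussian random fields —
seeded white noise circularly convolved (via FFT) with a Gaussian
kernel of per-class correlation length, scaled by a contrast around a
base level, quantized to 8 bits.  Random fields expose exactly the
second-order statistics the descriptors measure, so classes differing
in correlation length are separable by GLCM contrast (asserted at a
>2× margin between correlation lengths 1 and 8), while nothing about
the images resembles anatomy.  The default specification reproduces
the reference counts (411 images, eight classes).

`make_tabular_dataset()` is the desk-scale surrogate for the extracted
feature table: 10 informative + 78 noise features.  Class means for
informative coordinates are seeded Gaussian draws standardized so each
coordinate's spread across class means is exactly `class_sep`; samples
add unit-variance noise.  This guarantees each informative feature is
individually informative — what the ReliefF ranking invariants
require — and makes the typical distance between two class means
`class_sep·√(2·d)` for `d` informative features.  Conditions used in
the test suite, chosen once: `class_sep = 4` ("nearly separable") for
the end-to-end accuracy check, and `class_sep = 1` ("moderate
overlap": pairwise mean distance ≈ 4.5 at `d = 10` against noise of
unit sd) for the comparison of minority-class recall with and without
ADASYN, where errors must occur for an improvement to be visible.

Passing these tests shows the machinery is correct and the pipeline
behaves as the method intends under known statistical structure.  It
does not show clinical performance: real mammograms have nonstationary
texture, correlated descriptors, label noise and acquisition effects
none of which the generators emulate, and the reference study's
headline accuracies on its image archive are not reproducible from
synthetic data.

## Problem sizes and determinism

The test suite runs the full imbalanced table (411 → 1760 rows after
balancing, 88 features, 10 selected, 40-20-10-8 network) for the
end-to-end checks and scaled-down variants (quarter-size class counts,
one hidden layer of 8) for the separability-monotonicity property;
descriptor oracles use exhaustive enumeration on 8×8 images.  Every
stochastic step — generators, splits, initialization, interpolation —
is driven by explicit seeds; the pipeline derives per-stage seeds from
one global seed, and identical seeds give bit-identical feature
vectors, resampled tables, weights and reports (asserted in tests).

## Known limitations

- The DICOM reader covers uncompressed explicit-VR little-endian
  monochrome files only — enough for decompressed archive images and
  for the paired PNG/DICOM fixtures; compressed transfer syntaxes need
  external conversion.
- `glcm_features()` requires a normalized matrix; unnormalized input is
  an error rather than a silent renormalization.
- Dense `JᵀJ` formation bounds the practical parameter count to a few
  thousand; with the 40-20-10-8 architecture and ten inputs
  (1,558 parameters) an epoch is a second-scale operation, but very
  wide input layers would need a batched accumulation.
- ADASYN's `G` rounding means classes reach the majority count only up
  to rounding; the balance invariant in tests allows exactly that
  slack.
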