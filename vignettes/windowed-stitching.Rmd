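---
title: "Windowed overlap-add stitching: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed overlap-add stitching: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WindowStitch)
```

## The model

Patch-based pixel classification degrades toward patch borders and corners:
the classifier sees less context there, and after naive tiling the errors
line up into a visible grid. WindowStitch treats recombination as an
overlap-add problem from signal processing. Patches are taken at a stride of
half a patch side, each per-patch class-probability output is multiplied by
a 2-D window `W`, and the weighted patches are summed at their absolute
positions. If the tiled windows sum to 1 at every pixel (a *partition of
unity*), the weighted sum is a convex combination of the overlapping
predictions — centre-weighted, so border-corrupted estimates are
down-weighted exactly where they are least reliable — and a patchwise
consistent predictor is reproduced exactly, with no renormalization step and
no associated floating-point error.

Two assumptions are inherited from this construction:

* the predictor's reliability is (approximately) a fixed function of
  position within the patch — highest at the centre — for every patch;
* the output being stitched is additive (probabilities or logits per class);
  hard labels must be argmax-ed *after* stitching.

## Window functions and the periodic convention

The separable windows are built as `W(i,j) = w(i) w(j)` from the 1-D
profiles listed in `?makeWindow1D`. All profiles are evaluated in their
**periodic** form, dividing by the patch side `I` rather than `I − 1`. This
is deliberate: only the periodic samples satisfy the exact two-term identity
`w(i) + w(i + I/2) = 1`, and hence only they tile to a constant at 50%
overlap. The symmetric forms (denominator `I − 1`), which are common in
spectral analysis and appear in some published formulations, leave a ripple
of several permille in the tiled sum; they are available behind
`strictPaper = TRUE` so the difference can be inspected, and
`assembleWindowField()` is the measurement surface:

```{r}
range(assembleWindowField("hann", 512, 512, 128))
range(assembleWindowField("hann", 512, 512, 128, strictPaper = TRUE))
```

The Bartlett-Hann profile is implemented with a **negative** `a1` term,
`0.62 − 0.48·|i/I − 1/2| − 0.38·cos(2πi/I)`: this is the standard form, it
vanishes at the patch border, and it preserves the partition of unity. (The
sign of that term is occasionally misprinted as positive; that variant does
not taper and is likewise reproduced by `strictPaper = TRUE` only for
comparison.)

## Border and corner variants, and the quadrant boundary

Patches on the image border have no neighbour on one side, so the plain
window would under-weight those pixels. The border windows are flat
(constant 1) on the half facing the image border and tapered elsewhere;
corner windows are flat on the quadrant facing the image corner. Because a
patch side `I` is even and positions are 0-based, the flat/tapered split
needs a convention at `i = I/2`: WindowStitch uses half-open intervals — the
flat region covers indices `0 .. I/2−1` and the taper starts at `I/2`. This
is the unique choice under which the assembled field is exactly 1 (the tests
verify `< 1e−6` deviation over every geometry they touch, machine epsilon in
practice). A consequence worth knowing: under the periodic convention the
`down`/`right`/`down_*` variants are *not* bitwise mirror images of their
`up`/`left` counterparts — they reuse the same periodic samples with the
branch condition flipped, which is what the partition of unity requires.

Degenerate geometry is handled by the same rule: when a single patch spans
the whole image along an axis, its profile is flat along that axis, so a
one-patch image gets the all-ones window and is returned unchanged.

Patch sides must be **even**; odd sizes are rejected rather than rounding
the half stride. Images whose extent is not a multiple of the patch are
reflect-padded to the next multiple and cropped back after reconstruction
(reflection avoids creating an artificial intensity edge of its own).

## The pyramidal window

The distance-ratio window `W(i,j) = α·Dᵉ/(Dᶜ + Dᵉ)` is included as the main
point of comparison. Its source formulation leaves the two distance metrics
unspecified; WindowStitch uses the Chebyshev (chessboard) distance to the
nearest patch border for `Dᵉ` — which makes `Dᵉ = 0` exactly on the
outermost pixel ring — and the Euclidean distance to the patch centre at
`((I−1)/2, (J−1)/2)` for `Dᶜ`; both are configurable. `α` is defined so the
mean weight is exactly 1. Two consequences drive the implementation:

* the tiled pyramidal field is far from constant, so
  `reconstructPyramidal()` divides by the assembled field after summing —
  the extra normalization step the separable windows avoid;
* the window is zero on every patch's border ring, so the one-pixel outer
  ring of the image receives zero total weight. The divisor is clamped at
  machine-epsilon scale and those pixels are filled from their nearest
  covered neighbour, with a message; `guardZeros = FALSE` turns this into an
  error for pipelines that prefer to fail loudly.

## The synthetic benchmark

`generateScene()` emulates the *structure* of a nucleus-segmentation ground
truth: elliptical blobs (semi-axes 8–20 px by default) with a 3-pixel
`object_edge` ring on a background, rendered at three intensities with mild
i.i.d. noise. `noisyEdgePredictor()` emulates the *failure mode* that
motivates windowing: it returns the true one-hot classes corrupted by
additive Gaussian noise whose standard deviation rises from `baseNoise`
(default 0.05) at the patch centre to `baseNoise + edgeNoise` (default
0.05 + 0.35) on the patch border ring, following a quadratic profile of the
normalized Chebyshev distance to the border, then clips at zero and
renormalizes each pixel to the probability simplex. Noise is drawn
independently per patch origin (a dedicated RNG substream per
`(seed, origin)`, leaving the caller's RNG untouched), so overlapping
patches disagree near borders — the regime where tapering helps and where
plain averaging accumulates artefacts from four patches instead of one.

A `softness` parameter can blend the one-hot truth toward uniform before
corruption; it defaults to 0 so that the zero-noise predictor is *exact*,
tying the simulator to the identity property of the reconstruction: with
`baseNoise = edgeNoise = 0` every method must return the ground truth.

What the simulator does **not** emulate: realistic stain/texture appearance,
spatially correlated classifier errors, systematic class confusion, or
miscalibrated probabilities. Passing the benchmark shows that the stitching
machinery suppresses border-localized, independent noise; it does not certify
improvements on any particular real dataset or network.

## Evaluation protocol

* **SSIM** is computed per class channel and averaged
  (`ssimClasswise()`), on soft probabilities rather than binarized maps.
  The implementation uses a uniform 7×7 sliding window, unbiased sample
  (co)variances, stabilizing constants `C1 = (0.01·L)²`, `C2 = (0.03·L)²`
  with data range `L = 1` for probability maps, and averages only fully
  interior window positions. All of this is configurable; the defaults are
  the common convention, and the test suite pins the implementation to an
  independent brute-force oracle.
* **Adjusted scores** subtract the no-overlap baseline per image, metric and
  region, isolating the recombination effect from predictor quality.
* **Dice** is computed after a deterministic argmax (ties to the lowest
  class index — stochastic tie-breaking would make method comparisons
  noisier for no benefit), both micro (pooled counts) and macro (mean of
  per-class ratios), separately for the edge-vicinity and patch-centre
  regions of `makeGridMask()`. A class absent from both prediction and truth
  within a region contributes a macro term of 1 by default (correct absence
  is not punished); `absentClass = "skip"` drops it instead.
* The **grid mask** marks `halfWidth` pixels on each side of every interior
  no-overlap tile boundary. The half-width is a free parameter of the
  protocol; the default of 5 px comfortably covers the border band where
  the artefacts live at patch size 128 and is reported in the benchmark
  metadata.
* **Hypothesis tests**: a paired one-sample t-test on per-image differences
  (df = n − 1; with 14 images, t(13)) and a two-sided exact sign test (ties
  dropped). Both are reported for every method pair; the sign test is the
  robust headline (14/14 positive signs gives p ≈ 1.22e−4), the t-test adds
  effect-size context. Zero-variance differences are reported as degenerate
  rather than NaN.

## Problem sizes

The shipped defaults are chosen to exercise the reference geometry while
staying desk-sized: benchmark scenes are 512×512 with 128×128 patches
(7×7 = 49 overlapping patches per scene) over 14 seeds; the
partition-of-unity and identity checks run at the full 1024×1024 / 128
geometry (225 patches); property tests sweep patch counts `n, m = 1..8`
exhaustively. A full 14-seed benchmark takes a couple of minutes on one
core; scale `SceneSpec` up freely for larger studies.

## Known limitations

* Square patches and the fixed half-patch stride only: the partition-of-unity
  guarantee is specific to 50% overlap, and other stride ratios would need
  different window families (e.g. Tukey windows with a tunable flat top).
* The overlapping pipeline costs `(2n−1)(2m−1) ≈ 4nm` predictor calls versus
  `nm` for naive tiling.
* Windows are applied to the predictor *output* only; feeding weighted
  inputs to the classifier is a different method with different semantics.
* The pyramidal path's outer-ring fill is a pragmatic guard, not part of the
  window's definition; its one-pixel ring is best treated as unreliable.
* Per-patch adaptive windows (e.g. uncertainty-weighted) are out of scope.
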