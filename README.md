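# WindowStitch

Windowed overlap-add recombination of patch-based image segmentation.

## The problem

Pixel classifiers (CNNs in particular) cannot ingest gigapixel images —
whole-slide images in digital pathology being the canonical case — so the
image is cut into fixed-size patches, each patch is classified, and the
per-patch outputs are re-assembled. Prediction quality is known to degrade
toward patch borders and corners, so naive concatenation of patch outputs
leaves a visible grid of artefacts in the recombined class map.

WindowStitch removes these edge effects *post hoc*, with no change to the
classifier: patches are extracted at a stride of half a patch, every
prediction is multiplied by a 2-D window function that tapers its borders,
and the weighted patches are summed at their absolute positions:

    P(x, y) = sum over patches k covering (x, y) of
              W_role(k)(x - x_k, y - y_k) * pred_k(x - x_k, y - y_k)

The separable windows are built as `W(i, j) = w(i) w(j)` from 1-D profiles
in their periodic form (denominator `I`, the patch side):

| kind          | `w(i)` |
|---------------|--------|
| Hann          | `(1 − cos(2πi/I)) / 2` |
| Bartlett-Hann | `a0 − a1·abs(i/I − 1/2) − a2·cos(2πi/I)`, `a0 = 0.62, a1 = 0.48, a2 = 0.38` |
| Triangular    | `1 − abs(2i/I − 1)` |
| Average       | `1/2` (the 2-D window is the constant 1/4) |

Each profile satisfies `w(i) + w(i + I/2) = 1`, so at half-patch stride the
tiled windows sum to exactly 1 at every pixel (*partition of unity*) once
patches touching the image border get flat-sided variants: border windows
are constant 1 on the half facing the image border, corner windows constant
1 on the quadrant facing the image corner. Reconstruction therefore needs no
renormalization and introduces no extra rounding error. The non-separable
pyramidal window `W(i,j) = α·Dᵉ/(Dᶜ + Dᵉ)` (edge distance over
centre-plus-edge distance, mean normalized to 1 by `α`) is included for
comparison; it does *not* tile to a constant and takes a post-hoc division
by the assembled window field.

A synthetic benchmark (three-class nuclei-like scenes plus a simulated
predictor whose error grows toward patch borders) and an evaluation protocol
(class-wise SSIM, micro/macro Dice restricted to an edge-vicinity grid mask,
baseline adjustment, paired t-test, exact sign test) let the whole pipeline
be exercised without any dataset or trained network.

## Worked example

```r
library(WindowStitch)

makeWindow1D("hann", 8)
#> [1] 0.0000000 0.1464466 0.5000000 0.8535534 1.0000000 0.8535534 0.5000000
#> [8] 0.1464466

range(assembleWindowField("hann", 1024, 1024, 128))  # partition of unity
#> [1] 1 1

planGrid(1024, 1024, 128)
#> PatchGrid: 1024 x 1024 image, 128 x 128 patches at stride 64 -> 225 patches
#>   roles: down=13, down_left=1, down_right=1, interior=169, left=13,
#>          right=13, up=13, up_left=1, up_right=1

# synthetic scene + border-degraded predictor, Hann vs no-overlap baseline
sc   <- generateScene(SceneSpec(height = 256, width = 256, nBlobs = 8, seed = 3))
pred <- noisyEdgePredictor(sc$truth, ArtefactProfile(seed = 3))
recH <- reconstructWindowed(sc$image, pred, "hann", 128)
recN <- reconstructNoOverlap(sc$image, pred, 128)

round(c(hann = ssimClasswise(recH, sc$truth),
        no_overlap = ssimClasswise(recN, sc$truth)), 4)
#>       hann no_overlap
#>     0.1390     0.1037

mask <- makeGridMask(256, 256, 128, halfWidth = 5)
diceScores(asLabelMask(recN), sc$labels, mask, nClasses = 3)
#>          region dice_micro dice_macro
#> 1        centre  0.9894243  0.9387463
#> 2 edge_vicinity  0.9442231  0.8428520
diceScores(asLabelMask(recH), sc$labels, mask, nClasses = 3)
#>          region dice_micro dice_macro
#> 1        centre  0.9936546  0.9627996
#> 2 edge_vicinity  0.9966135  0.9894639
```

The Hann window raises the class-wise SSIM of the recombined probability map
(0.139 vs 0.104 for straight concatenation) and, where it matters most —
the pixels near the no-overlap tile boundaries — lifts the micro Dice from
0.944 to 0.997 while patch centres barely move: exactly the signature of
suppressed edge artefacts. `runBenchmark(nSeeds = 14)` repeats this over 14
seeded scenes for all six methods and returns the per-image score table plus
pairwise paired-t and exact-sign-test matrices.

## Command-line tools

```sh
Rscript inst/scripts/simulate.R  --height 1024 --width 1024 --n-blobs 120 --seed 7 --out scene.tif --gt gt.tif
Rscript inst/scripts/reconstruct.R --input gt.tif --method hann --patch-size 128 --output prob.tif
Rscript inst/scripts/benchmark.R --seeds 14 --patch-size 128 --mask-half-width 5 --out scores.csv
```
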