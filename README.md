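# dsaddle

Feature-based registration of retinal fundus image pairs, built around the
**D-Saddle** detector: saddle-point ring tests run on a multiresolution
difference-of-Gaussian (DoG) pyramid. The package implements the full
pipeline — detection, HOG description, ratio-test matching, MSAC-robust
transformation estimation — together with landmark-based evaluation
(target registration error) and a synthetic fundus phantom generator, so
every stage is testable end to end with exactly known ground truth and no
external data.

It is written for researchers in retinal image analysis who need a
self-contained, deterministic reference implementation of saddle-based
registration to evaluate against, extend, or generate calibrated synthetic
benchmarks with.

## The method

A candidate pixel `p` of the (normalized, absolute) DoG image
`D = G(kσ₀)∗I − G(σ₀)∗I` (σ₀ = 1.0, k = 1.6, four octaves of halved
resolution) is a D-Saddle point when:

1. **Inner ring** — among its 8-neighborhood, one opposed pixel pair
   (axial `+` or diagonal `×`) strictly dominates the orthogonal pair in
   either polarity; the central level β is the median of the passing
   shape's pixels;
2. **Outer ring** — the 16 pixels of the radius-3 digital circle, labeled
   `d` (`< β − ε`), `s` (within `β ± ε`), `l` (`> β + ε`) with
   ε = 0.0010, form alternating dark/light arcs of length 2–8 separated
   by at most two `s` — the sector signature of an intensity saddle.

Surviving points are non-maxima suppressed (octave 0), refined to
subpixel precision, lifted to input coordinates, described with
324-dimensional HOG vectors, matched by a 0.9 nearest/second-nearest
ratio test, and aligned by MSAC over four inlier thresholds
(1, 20, 60, 80 px) with the final model — similarity, affine, or full
second-order polynomial — selected from the inlier count. Accuracy is the
target registration error

    TRE = (1/n) Σᵢ ‖T(xᵢ_moving) − xᵢ_fixed‖ ,

the mean Euclidean distance over n = 10 landmark correspondences, with
success below 1 px (super-resolution) or 5 px (mosaicking, longitudinal).

## Worked example

```r
library(dsaddle)

# a synthetic super-resolution pair with known ground truth
pair <- generate_pair(phantom_config(seed = 5), category = "S")
round(pair$overlap_fraction, 3)
#> [1] 0.999

pts <- detect_dsaddle(pair$fixed)
nrow(pts)
#> [1] 8696

res <- register_pair(pair$fixed, pair$moving,
                     register_config(repeats_per_distance = 50),
                     landmarks = pair$landmarks, seed = 7)
res
#> registration: success
#>   model: polynomial2, inliers: 1588, distance: 1 px
#>   TRE: 0.074 px
```

The detector found 8696 saddle points across the four octaves of the
fixed image; registration selected the second-order polynomial model
(1588 inliers at the 1-px MSAC threshold) and lands the ten ground-truth
landmarks with a mean error of 0.074 px — comfortably below the 1-px
success threshold for super-resolution pairs.
`classify_success(res$tre, "super_resolution")` accordingly returns
`TRUE`.

The methods vignette (`vignettes/dsaddle-methods.Rmd`) documents the
model, every tunable parameter, the phantom's acquisition model, and the
design decisions in detail.

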