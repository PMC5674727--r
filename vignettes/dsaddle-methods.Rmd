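---
title: "Saddle-point detection and fundus image registration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saddle-point detection and fundus image registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsaddle)
```

## The problem

Registering two fundus photographs of the same retina — for
super-resolution, mosaicking, or longitudinal follow-up — requires feature
points that are detected *on vessels of every contrast and calibre*, not
only on the few strongest arcades. Plain saddle detectors find vessel
points, but cluster them on high-contrast vessels and are confused by the
degradations typical of clinical images: illumination falloff near the
frame boundary, nonuniform intensity, and dark-spot artifacts.

The D-Saddle detector implemented here addresses this by running the
saddle ring tests not on the image itself but on a multiresolution
difference-of-Gaussian (DoG) pyramid. The DoG acts as a band-pass filter
that suppresses both slow illumination fields and pixel noise while
emphasizing vessel-scale structure; the octave pyramid repeats the test at
halved resolutions so vessels of different calibres all appear, at some
octave, at the scale the ring geometry probes.

## Stage 1: detection

1. **Pyramid.** Each of 4 octaves is blurred afresh with Gaussians of
   width `sigma0 = 1.0` and `k * sigma0` (`k = 1.6`, a good Laplacian
   approximation); their difference is taken, made absolute, and min–max
   normalized to [0, 1] per octave. Octave `o + 1` is the bilinear
   downsample of octave `o` to `ceiling(dim / 2)` (the ceiling keeps the
   last row of odd-sized images; the default working resolution 583 is
   odd). The whole pyramid costs at most 4/3 of the input pixels.
2. **Candidates.** All pixels with `x` in `[4, M − 3]`, `y` in
   `[4, N − 3]` (1-based) — exactly the positions where the radius-3 outer
   ring fits.
3. **Inner ring.** The 8-neighborhood is tested for the `+` shape (axial
   pair vs lateral pair) and the `×` shape (the two diagonal pairs): a
   shape passes when one pair's minimum strictly exceeds the other's
   maximum, in either polarity. The central level `β` is the median of the
   4 pixels of the passing shape, or of all 8 when both shapes pass. This
   test removes the bulk of the candidates (the acceptance script reports
   the measured fraction, about three quarters under the phantom's
   conditions).
4. **Outer ring.** The 16 pixels of the radius-3 digital circle are
   labeled `d` / `s` / `l` relative to `β ± ε` (boundaries inclusive into
   `s`; `ε = 0.0010` on the normalized absolute DoG). The candidate passes
   when the maximal `d`/`l` arcs, after dropping `s`-runs of at most 2,
   alternate cyclically with lengths in [2, 8] and at least two arcs of
   each polarity — a dark/bright/dark/bright sector pattern, the signature
   of an intensity saddle. Two same-label arcs separated only by an
   `s`-gap fail: a saddle's sectors must interleave.
5. **Response and suppression.** Each passing point gets the response
   `mean(β − I_d) + mean(I_l − β)` (the mean dark deficit plus mean light
   excess — monotone in local contrast, which is all non-maxima
   suppression needs). 3×3 suppression is applied only at octave 0;
   coarser octaves are already sparse. Exact response ties are broken
   toward the smaller `(y, x)` for determinism.
6. **Subpixel and lifting.** A 1D quadratic through the centre row and
   column of the 3×3 `|DoG|` patch moves the point to the vertex, clamped
   to ±0.5 px; degenerate (flat or non-concave) profiles keep the integer
   position. Octave coordinates are lifted to input coordinates about the
   pixel-centre origin, `x_in = (x − 0.5)·s + 0.5` with `s` the exact
   ratio of input to octave dimensions. The pixel-centre form matters:
   lifting by plain multiplication leaves a half-pixel bias per octave
   that breaks rotation covariance of the detections, which the test
   suite checks explicitly.

## Stages 2–4: description, matching, estimation

Each point is described by an unsigned-gradient HOG over a 32×32 window:
8×8 cells, 2×2-cell blocks at one-cell stride, 9 orientation bins, L2
block normalization — 324 values. The window size is chosen to cover
roughly ±2 vessel widths at the working resolution; the paper-level
protocol fixes only the cell and block geometry. Unsigned gradients make
the descriptor invariant to constant intensity offsets.

Descriptors are matched one-directionally by the nearest/second-nearest
Euclidean ratio test with threshold 0.9 (boundary inclusive). The default
search is an approximate nearest-neighbour scheme (shortlist in a 24-dim
PCA projection, exact re-ranking of 8 candidates), matching the
protocol's use of approximate search; an exact search is available and
the test suite checks that the two agree on structured descriptors.

Outliers are rejected by MSAC: two-point similarity hypotheses, scored by
truncated squared reprojection error, inliers at the current distance
threshold. The trial budget is 8000 with adaptive 99%-confidence early
termination. The protocol sweeps four thresholds (1, 20, 60, 80 px) with
1000 seeded rounds each (configurable down to desk scale); each round
derives its child seed from (threshold, round) so that raising the round
count strictly extends the set of rounds already run. The final model is
chosen from the inlier count — at most 8 inliers: similarity; 9–30:
affine; above 30: full second-order polynomial (12 parameters). At the
boundary counts the simpler model is preferred.

With landmarks supplied, the round with the smallest target registration
error (TRE, the mean Euclidean landmark distance after mapping) wins —
this is the evaluation protocol. Without landmarks no oracle exists, so
the application mode selects the round with the most inliers, ties broken
by the smallest mean inlier residual; this deviation is deliberate and
the two modes are kept separate in the API.

Success thresholds follow the application: TRE strictly below 1 px for
super-resolution, below 5 px for mosaicking and longitudinal study.

## The fundus phantom

The generator produces image pairs with exactly known ground truth so the
whole pipeline is testable without any external data. It emulates, at the
583-px working resolution:

* a circular field of view on a constant dark frame (the aperture is an
  optical mask: no photon noise outside it, and residual dark current is
  crushed by black-level quantization);
* a branching vessel tree (random walks from the disc with curvature
  noise and probabilistic branching), widths 2–12 px and Gaussian-valley
  cross-sections — smooth dark ridges reproduce the saddle structure the
  detector targets — and contrasts 0.05–0.5;
* a bright optic disc, multiplicative illumination falloff toward the
  boundary, dark-spot occlusions;
* spatially correlated background texture (choroidal mottle /
  pigmentation, amplitude 0.04, correlation length 4 px) that is part of
  the anatomy and therefore warps with the scene between the two views of
  a pair;
* additive sensor noise of 0.005 — 8-bit capture noise of roughly 0.025
  attenuated by the 5× area-averaging downsample from native (2912 px) to
  working resolution — followed by 8-bit quantization.

Ground-truth warps are similarity, affine, or mild second-order
polynomial maps about the image centre; the translation magnitude is
solved from the requested field-of-view overlap by the circular lens-area
formula, and the recorded overlap is re-measured on the actual masks.
Landmarks (10 per pair) are sampled on vessel centerlines visible in both
fields of view and are consistent with the true warp to better than
10⁻⁶ px (Newton inversion for polynomial truths). Category S/P/A pairs
follow the application regimes (overlap 86–100% / 17–89% / 95–100%,
rotation up to 5°/7°/4°, category A additionally jitters vessel
tortuosity and adds small lesions to the second visit).

**What the phantom does not model:** saturated disc regions, crushed
vignetting rings, surface wrinkling, real pathology, lens distortion, and
resolution-dependent blur. Passing tests therefore demonstrate the
pipeline's correctness and its qualitative behavior (overlap dependence,
category ordering), not clinical-grade performance on real data. Two
consequences observed in the validation suite are worth stating plainly:
the measured inner-ring rejection (~73%) sits a few points below the
figure reported for real clinical images, plausibly because the phantom
lacks the large saturated and crushed-black regions real images have;
and on clean phantoms the pipeline saturates at ~0.1 px TRE at every
overlap level, so the overlap effect is only measurable on low-quality
phantoms (strong vignetting and dark spots), which is also the regime of
the clinical data where that effect was described.

## Numerical choices

* Gaussian kernels are truncated at `ceiling(4σ)` and renormalized;
  convolution uses reflect padding, which avoids spurious DoG edges at
  the frame boundary that would mimic the illumination artifact.
* A DoG range at numerical-noise level (≤ 10⁻⁹, e.g. a constant octave)
  normalizes to all zeros rather than stretching rounding noise.
* The `ε` band is applied on the normalized absolute DoG, so one default
  (0.0010) is comparable across images and octaves.
* Least squares go through QR with explicit rank checks; degenerate
  geometries (coincident points, collinearity, rank-deficient quadratic
  basis) raise errors naming the degeneracy rather than returning junk.
* `warp_image` uses inverse-mapped bilinear resampling; polynomial warps
  are inverted by fitting the inverse polynomial on a grid. A 10⁻⁶ px
  tolerance keeps boundary pixels that floating-point rounding pushes
  just outside the source domain.
* MSAC hypotheses are similarity maps from two-point samples regardless
  of the final model class (the cheapest geometric hypothesis; the final
  fit refines with the selected model).

## Problem sizes in the test suite

The validation batteries are sized for a single CPU: the known-warp
battery uses 20 pairs (7 similarity, 7 affine, 6 polynomial) at ≥ 75%
overlap plus 10 near-identity pairs, with 50 MSAC rounds per distance;
the overlap battery uses 4 seeds per overlap level at 25 rounds; the
category success-rate checks use 6 S and 4 A pairs at 20 rounds. The full
4 × 1000-round protocol is a configuration flag
(`register_config(repeats_per_distance = 1000)`).

## Known limitations

* The detector's ring tests are ordinal: detection counts are largely
  contrast-independent (by design — faint vessels must be found), so
  contrast only enters through the response used for non-maxima
  suppression.
* One-directional matching admits many-to-one matches; MSAC is relied on
  to remove them.
* The polynomial model has no exact inverse; warping and landmark
  inversion use fitted or Newton inverses, exact to well below the
  evaluation tolerances for the mild quadratic terms generated here.
* Native-resolution evaluation is supported by coordinate scaling
  (`export_fixture(native_scale = ...)`), not by rendering full native
  images.
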