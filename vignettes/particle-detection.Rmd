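---
title: "Detecting particles and fibers for single-point spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting particles and fibers for single-point spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partseg)
```

## The problem

Chemical identification of microplastics (roughly 1 µm–1 mm plastic
fragments and fibers on a filter substrate) by Raman microspectroscopy is
slow when done as chemical imaging: every pixel of a large filter area
must be measured. The single-point alternative measures one spectrum per
object, at one well-chosen coordinate inside it — but that presupposes an
image-analysis step that (i) finds every object despite uneven
illumination, (ii) measures its size and shape, (iii) picks a coordinate
the laser cannot miss, and (iv) decides how many of the thousands of
detected objects actually need a spectrum. `partseg` implements that
pipeline.

## Segmentation model

The core assumption is that objects are *locally* brighter than their
background (darkfield scattering, secondary-electron emission,
fluorescence staining), while the background level itself may drift
across the field of view. Segmentation therefore uses an adaptive
threshold: pixel p is foreground iff

$$ g(p) > \bar g_\sigma(p; b) - C $$

with $\bar g_\sigma$ the Gaussian-weighted mean over a $b \times b$
window and $C$ an offset in 8-bit intensity units. A negative $C$ demands
local contrast of at least $|C|$, suppressing noise; a positive $C$
detects ever-fainter objects at the cost of false positives. Dark
objects on bright backgrounds (backscatter SEM) are handled by the
`sem_dark` mode, which inverts intensities first; fluorescence modes
isolate one RGB channel, stretch it to the full range and threshold
globally by Otsu, since a stained image has a near-black background with
no gradient, and per-channel isolation is what separates differently
stained populations.

The window size interacts with object size: a window much smaller than an
object sees only its interior (local mean ≈ object brightness, so the
interior drops below threshold), while a window much larger than a faint
object dilutes it. Hence the image is analyzed twice — once with a large
window keeping only objects of filled area at least the *size boundary*,
once with a small window keeping the rest. Large-window interiors that
do fall below threshold are recovered by filling each component's outer
contour. A small-pass object whose corrected center lies inside a
large-pass object is suppressed; this center-containment rule is the
simplest deduplication that guarantees nothing is counted twice, and we
chose it because it is insensitive to small contour disagreements between
the passes.

### Parameters

| Parameter | Unit | Default (at 0.5 px/µm) | Rationale |
|---|---|---|---|
| `block_large` | px, odd | 51 | smallest "large" window above the 49-px floor that detects 10–30 px radius objects well |
| `block_small` | px, odd | 11 | just above the 9-px floor for small-object sensitivity |
| `c_large`, `c_small` | intensity | −8 | demands ~8 units of local contrast, above the residual noise after blurring |
| `size_boundary` | px² | 300 | ≈ area of a radius-10 px object; splits the two window regimes |
| `min_pixels` | px² | 20 | user filter; objects below it are unreliable at this resolution |
| `min_feret` | px | 5 | user filter on the box long side |
| `blur_kernel` | px, odd | 3 | Gaussian pre-blur; suppresses single-pixel noise, keeps runtime low |

All length defaults scale linearly with resolution (areas quadratically),
because the same physical object covers proportionally more pixels at
higher magnification; explicitly supplied values are never rescaled. The
window's standard deviation is tied to its size by the common kernel
convention $\sigma = 0.3((b-1)/2 - 1) + 0.8$; only the window *type* is
part of the method, so a convention was fixed once for determinism. The
C defaults were calibrated with the package's own grid search on
synthetic scenes at the default study conditions (the calibration
procedure below), mirroring how the method is parametrized on real
expert-annotated images.

Even block sizes are rejected rather than rounded: silent parameter
adjustment would make reported settings unreproducible.

## Morphology

Feret diameters are defined here as the side lengths of the
minimum-area enclosing rotated rectangle — the definition used for
sizing measurement boxes, not the classical caliper extremes (the
classical maximum diameter can exceed the box's long side; for convex
shapes the two agree closely). The search is exact: the optimal
rectangle has a side flush with a convex-hull edge. For pixel contours,
vertices are expanded to pixel corners, so a 1-px-wide line measures
1 × n, and a degenerate collinear contour is reported with unit
thickness.

Area is the count of lattice pixels inside or on the outer contour.
Holes are detected (`has_holes`) but their area is *not* subtracted —
subtracting it reliably is an open problem for nested and partial rings,
so the choice is documented rather than half-solved. Consequently a
thin ring is classified by its filled disc: the box-fill criterion
applied to the *material* area calls it a fiber, applied to the filled
area it may be a particle. Classification is the stated either/or rule
(aspect ratio > 2.0, or box area > 4.0 × object area) and is scale
invariant by construction.

The corrected measurement center keeps the centroid when it lies on
material at depth ≥ 2 px (a laser-spot-scale margin; the depth floor is
a package choice, as only the intent — never hitting the edge — is
specified by the method). Otherwise it returns the argmax of the
interior Euclidean distance transform, with ties broken by smallest
(y, x) so repeated runs are identical.

## Validation protocol

Expert annotations are saturated-red overdrawings; a pixel counts as
annotation when red ≥ 150 and red ≥ 2·max(green, blue), a rule chosen to
tolerate JPEG chroma bleed. A detection corresponds to a truth object
when either corrected center lies inside the other object; matches are
resolved one-to-one greedily by center distance. A matched detection
containing further unmatched truth centers is one true positive plus an
*incorrect separation* of k truths in one instance — those truths are
neither TPs nor FNs, which matches how merged agglomerates are
bookkept in practice. Rates are normalized by the truth count and
averaged unweighted across images, so small test images count as much as
crowded ones; `fp_rate` may therefore exceed 1 on pathological inputs.

## Calibration by grid search

All combinations of the five hyperparameters over a user grid are
evaluated on every calibration image; each run is summarized by object
count, total area, and summed Feret minima and maxima, scored by the
mean of the four relative errors against the consensus summary, and
averaged with equal weight per image. Invalid combinations (e.g.
`block_small ≥ block_large`) are skipped, not clamped. The ranking is
deterministic: ties are broken lexicographically. Internally components
are cached per (window, C) pair — the size boundary only re-partitions
already-measured components — which the tests verify to be
indistinguishable from independent per-combination runs.

## Subsampling

The minimum representative sample size uses the normal-approximation
formula for a proportion with finite-population correction,
$n_0 = z^2 p(1-p)/m^2$, $n = \lceil n_0/(1 + (n_0-1)/N) \rceil$, clamped
to N. Whether the source method applies the correction and how it
rounds is not documented; correcting and rounding up was chosen and is
printed in the function documentation so users can audit it. Selection
is uniform without replacement under a user seed — unweighted, because
the sampling frame is "objects", not "area".

## What the synthetic scenes emulate — and what they do not

`generate_scene()` renders ellipses and constant-width quadratic Bézier
strokes (the simplest curve family giving bow-shaped fibers) on a dark
background with a smooth linear or radial illumination ramp and additive
Gaussian pixel noise. Object intensity is drawn per object but always at
least `min_contrast` (default 40) above the local background, so scenes
are detectable by construction; by default objects are ≥ 3 px apart.
Ground truth is measured from the rendered masks with the same
morphology definitions as detections, and an annotated copy overdraws
objects in saturated red. The default study conditions are a 320 × 320
canvas, 8 particles of 5–15 px radius, 3 fibers of 40–90 px length and
4–7 px width, background 40 with gradient amplitude 60, noise σ = 6 and
object intensities 150–220.

Passing tests on these scenes show that the *algorithmic* claims hold:
local thresholding survives gradients that defeat any global threshold,
measurements agree with independent brute-force oracles, and
bookkeeping is exact. They do not show robustness to out-of-focus
regions, filter texture, touching agglomerates (deliberately generated
only with `overlap_allowed = TRUE` to assert the documented
merged-detection behavior), sub-resolution objects, or real sensor
noise — on real material the hyperparameters must be recalibrated
against expert annotations with the grid search.

## Numerical and degenerate-input choices

* Border neighborhoods use edge replication; objects touching the border
  are kept but flagged `on_border`.
* A constant image has no Otsu threshold: all-background plus a warning.
* 16-bit rasters are rescaled to [0, 255] on load because the C offsets
  are defined on the 8-bit scale.
* Contours with no interior pixel raise `unmeasurable object` instead of
  returning fake morphology.
* The scene generator, subsampler and all tests scope their RNG: a seed
  given to a function never perturbs the caller's random stream.

Test problem sizes were chosen to keep the full suite fast while leaving
each property falsifiable: 100 random polygons for the Feret oracle, 20
gradient scenes for the adaptive-vs-Otsu comparison, 10 repeats of a
3⁵-point grid search on 200 × 200 scenes, 1000 fuzzed matching
scenarios, and 200 Monte-Carlo subsampling repeats over 10 000 objects.

## Known limitations

* Hole area is not subtracted from ring-shaped objects.
* Touching or agglomerated objects merge into one detection (watershed
  splitting was considered and rejected: it performs poorly on fibers);
  the validation module quantifies this as incorrect separation instead
  of hiding it.
* Fiber length is the enclosing-box side, not the arc length a
  skeletonization would give; curled fibers are under-measured.
* Tile stitching assumes non-overlapping, row-major tiles; there is no
  overlap registration.
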