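# partseg

Automated detection and morphological characterization of particles and
fibers in microscopy images, built for preparing **single-point
spectroscopy** campaigns — most prominently Raman microspectroscopy of
microplastics collected on filter substrates. Instead of chemically
imaging an entire filter, the workflow is: segment every object in an
optical darkfield, fluorescence or SEM image, measure it, pick a laser
target *inside* each object, and measure only a statistically
representative random subset. The package covers the whole image-analysis
side of that workflow: segmentation, morphology, target correction,
validation against expert annotations, hyperparameter calibration,
subsampling, stitching, and a seeded synthetic-scene generator with exact
ground truth.

## The method

**Two-pass adaptive thresholding.** A global threshold fails on
microscopy images whenever illumination or background drifts across the
field of view. Here a pixel with gray value g(p) is foreground iff

    g(p) > mean_G(p; b) − C

where `mean_G(p; b)` is the Gaussian-weighted mean of the b × b
neighborhood of p and C is a constant offset: the threshold tracks the
local background. Because a large window detects large objects well and
small objects poorly (and vice versa), the image is analyzed twice — a
large-window pass keeps objects of area ≥ the *size boundary*, a
small-window pass keeps the rest — giving five trainable hyperparameters:
two neighborhood sizes, two C values, and the size boundary. For
fluorescence images (near-black background, no gradient) a global Otsu
threshold is used instead, after isolating the stain's RGB channel.

**Morphology.** Each object's Feret diameters are the side lengths of the
smallest rotated rectangle enclosing its contour; area is the filled
pixel count (holes are not subtracted); and an object is a **fiber** iff

    feret_max / feret_min > 2.0   or   (feret_min · feret_max) / area > 4.0,

otherwise a **particle**. The measurement center is corrected: if the
contour centroid falls outside the material (bow-shaped fibers), inside a
hole (rings), or too close to the boundary, it is replaced by the
interior point furthest from the boundary, so a laser aimed there cannot
miss.

**Validation and calibration.** Expert-annotated images (objects marked
in saturated red) provide a consensus value; detections are scored
TP/FP/FN by center containment, with merged agglomerate detections
tracked separately as *incorrect separation*. The five hyperparameters
are calibrated by exhaustive grid search, ranked by the mean relative
error of four summaries (object count, total area, summed Feret min,
summed Feret max) against the consensus, averaged with equal weight per
image.

**Subsampling.** The minimum number of objects to identify chemically is
n₀ = z²·p(1−p)/m² with finite-population correction
n = n₀ / (1 + (n₀−1)/N), rounded up — then that many detections are drawn
uniformly at random with a fixed seed.

## Worked example

```r
library(partseg)

sc  <- generate_scene(scene_spec(seed = 7))   # synthetic darkfield scene
p   <- detection_params()
p
#> Detection parameters (mode: optical )
#>   blocks 51/11  C -8/-8  size boundary 300 px
#>   filters: min_pixels 20 px, min_feret 5 px; resolution 0.5 px/um; blur 3

det <- detect_particles(sc$image, p)
length(det)
#> [1] 11

head(detections_to_df(det, p$resolution)[, c("id","x_px","y_px","area_um2",
     "feret_min_um","feret_max_um","class","pass")], 5)
#>   id  x_px  y_px area_um2 feret_min_um feret_max_um    class  pass
#> 1  1  86.0  63.0     1248        24.02       111.18    fiber large
#> 2  2 110.0  92.0     1988        28.24       164.16    fiber large
#> 3  3 199.7 229.7     1688        44.00        48.00 particle large
#> 4  4 245.0 218.0     1376        26.48        97.66    fiber large
#> 5  5  28.0  74.0      640        28.00        30.00 particle small

unlist(match_and_rate(det, sc$truth)$rates)   # against exact ground truth
#> tp_rate fp_rate fn_rate
#>       1       0       0

required_sample_size(200000, confidence = 0.95, margin = 0.05, p_est = 0.5)
#> [1] 384
```

The coordinates are 0-based pixels (x rightward, y downward) and
micrometers (pixel / resolution, plus an optional stage offset); `pass`
records which window claimed the object. `write_outputs()` saves the
overlay (contours green for large-pass particles, yellow for small-pass
particles, blue for fibers, plus a cross at each corrected center), the
black-and-white mask, and this csv. A command-line front end with
`detect`, `validate`, `grid` and `synth` subcommands is installed under
`inst/scripts/partseg-cli.R`.

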