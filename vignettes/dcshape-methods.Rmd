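---
title: "Label-free deformability cytometry analysis with dcshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free deformability cytometry analysis with dcshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcshape)
```

## The measurement and the analysis problem

Deformability cytometry (DC) drives a cell suspension through a narrow
microfluidic constriction in a high-viscosity buffer while a stroboscopic
brightfield camera captures sub-microsecond exposures at several hundred
frames per second, 8-bit grayscale.  Shear deforms each cell as it transits,
so a single frame carries both the cell's morphology and its mechanical
response.  The analysis task is: find every object ("event") in the frame
stream, trace its contour, quantify its shape, decide what kind of object it
is — an intact cell, a visibly aberrant (anomalous) cell, a dead cell, an
aggregate of cells, or debris — and aggregate per-sample statistics.  Not
every event is a cell, and in stressed samples most are not, so the
classification step replaces the manual scatter-plot gating of classical
cytometry.  dcshape additionally counts dark cytoplasmic inclusions (lipid
droplets) inside cells, a label-free readout of intracellular lipid
accumulation.

Because instrument data are bulky and annotation is costly, the package
ships a synthetic frame generator that renders all five event classes with
exact ground truth (contour, class, droplet count).  Every stage of the
pipeline is validated against that generator; the same code paths then run
unchanged on real frame sequences.

## Event segmentation

The detection pipeline is deliberately classical and fully parameterized
(`segmentationParams()`):

1. **Background.**  Per-pixel temporal median over up to `bg_window`
   (default 100) frames sampled evenly from the sequence.  Objects in flow
   are transient at any fixed pixel, so the median recovers the static
   illumination field, including lateral intensity gradients and channel
   walls.  A single background image is used for the whole sequence — the
   model assumes static illumination, which holds for stroboscopic
   acquisitions; slow drifts would require re-estimating per block.
2. **Difference, smoothing, threshold.**  The absolute difference
   `|frame - background|` is Gaussian-smoothed (`smooth_sigma`, default
   1 px) and thresholded at a fixed offset (default 8 gray levels).
3. **Morphology and labeling.**  Binary opening (radius 1) then closing
   (radius 2), 8-connected component labeling, an area gate
   (default 50–15000 px^2), and exclusion of components touching the frame
   border.
4. **Half-amplitude refinement.**  The fixed threshold must sit near the
   noise floor to catch faint objects, which places the detected boundary a
   fraction of the smoothing scale *outside* the true edge (the smoothed
   edge profile crosses a low threshold early).  Each accepted component is
   therefore re-thresholded at half its robust amplitude — the median of
   the smoothed difference over the eroded component interior — which is
   the classic half-maximum edge localization and removes the dilation.
   Two guards keep this safe: components whose interior plateau is not
   resolved (area < 500 px^2) are left untouched, and a refinement that
   fragments the component (keeping < 80% of its area, as happens in
   strongly textured cells) is discarded in favor of the original mask.
   The stage can be disabled (`refine_mask = FALSE`).
5. **Hole filling and cropping.**  Each component is hole-filled and
   cropped with a 5 px margin; aggregates are *not* split — they are a
   class of their own for the classifier, not a segmentation failure.

On synthetic scenes with 200 planted objects at default contrast the
pipeline recovers objects with recall and precision above 0.95 at a strict
mask IoU of 0.8 (typically 0.98–0.99, mean IoU about 0.97), and detects
nothing on 100 blank frames; the acceptance script recomputes these numbers.

## Contours and the deformation statistic

Morphometry rests on the contour.  Pixel-edge (chain-code) contours
overestimate the perimeter of smooth shapes by up to ~27%, which would turn
the deformation of a perfect circle into ~0.2 and swamp the biology.
dcshape instead extracts a sub-pixel contour: the binary mask is smoothed
with a Gaussian (sigma 1 px) and the iso-level-0.5 curve is traced by
marching squares with linear interpolation (`extractContour()`).  On a
digitized disk of radius 30 px this leaves a perimeter bias of about +0.4%
and a deformation of about 0.006; without the smoothing the raw marching
squares polygon is biased +6% (deformation 0.06).  Contours are closed,
simple, counter-clockwise polygons in 0-based (row, col) pixel-center
coordinates with the first vertex repeated last — one convention everywhere.

From the contour, the projected area $A$ (shoelace formula) and perimeter
$l$ (Euclidean edge sum) give the deformation

$$D = 1 - \frac{2\sqrt{\pi A}}{l},$$

zero for a circle by the isoperimetric identity, $1-\sqrt{\pi}/2 \approx
0.1138$ for a square, and increasing with elongation and boundary
irregularity.  $D$ is scale invariant; digitization can push it marginally
negative, so values are clamped to $[0, 1)$ with the raw value and clamp
count preserved in attributes — the estimator's bias is never silently
hidden.  Masks below 5 px are rejected outright: they carry no meaningful
morphometry.

Per-sample location summaries use the *mode*, not the mean: DC samples mix
populations, and the mode of the intact-cell deformation (and projected
area) is robust against the tails that dead cells and debris would
contribute.  The mode is computed from a Gaussian kernel density estimate
with Silverman's rule-of-thumb bandwidth, evaluated on a 512-point grid
spanning the sample range — deterministic and binning-free, unlike a
histogram mode.  On 9,000 draws from a unimodal law the KDE mode lands
within 0.005 of the true location.  Summaries (`summarizeSample()`) report
class fractions over **all** events (they sum to one), and restrict the
deformation/area modes and droplet means to **intact-labeled** events: reference
per-experiment statistics in this field do not state which classes enter
them, and intact-only is the physiologically sensible reading.  A warning flags
samples with fewer than 900 intact events, the per-experiment floor used
for such summaries.

## Classification without gating

The classifier is a convolutional network over raw event crops.  Crops of
any size are bilinearly resized to a square input (224 px by default, the
reference geometry), kept single-channel, and standardized with a mean and
standard deviation computed **from training pixels only** — validation data
never leak into the normalization.  Training follows the reference recipe:
up to 100 epochs, batch 64, Adam, weighted cross-entropy with
inverse-frequency class weights $w_c = N/(K n_c)$ (their count-weighted
mean is exactly 1), stratified 80/20 train/validation split (validation
count per class `max(1, round(0.2 n_c))`), dropout 0.3 in the head, early
stopping on validation loss with best-epoch weight restoration, and
learning-rate halving on validation plateau.  The training stream is
augmented with six transform families — random cropping, rotation,
horizontal flip, affine, perspective, brightness/contrast — implemented as
seeded inverse warps with bilinear resampling; validation and inference are
never augmented.  The initial learning rate (1e-4 default), hidden width
(256), and patience values (10/5) have no standard values; they are
configurable in `trainConfig()`.

The architecture is a ResNet18-style backbone (7x7/2 stem, max pooling,
four stages of two basic residual blocks) whose final global pooling and
fully connected layer are replaced by flatten → dense(256) → ReLU →
dropout(0.3) → dense(5).  No pretrained weights are used — transfer
learning is not part of the reference recipe — so runs are reproducible
from a seed alone.  The engine is implemented in R on BLAS matrix algebra
(im2col convolutions with precomputed index maps, sparse-matrix col2im in
the backward pass, batch normalization, Adam); a "tiny" two-stage variant
of the same design exists for CPU-scale work and is what the tests train.
At desk scale — 200 synthetic images per class, 64 px inputs, learning rate
1e-3, at most 10 epochs on one CPU core, augmentation off (a 10-epoch
budget underfits under heavy augmentation, which is a full-scale training
device) — the tiny variant reaches balanced validation accuracy of roughly
0.95–0.98.  This validates the
training machinery; confusion-matrix accuracies achieved on thousands of
manually labeled instrument images with GPU-scale training are a property
of those data and budgets, and reproducing them is out of scope here.
On a 9:1 imbalanced toy, inverse-frequency weighting strictly raises
minority-class recall over unweighted training under identical seeds —
the property the weights exist for.

## Droplet counting

Lipid droplets appear as compact dark inclusions in the cytoplasm.
`detectDroplets()` is a deliberately simple relative-threshold procedure:
erode the cell mask by 2 px (excluding the bright diffraction rim), compute
the median $m$ and range $r$ of the interior intensities, mark pixels
darker than $m - \max(0.35\,r, 15)$, take 8-connected components, and keep
those with area between 4 px^2 and 25% of the cell area.  The range-scaled
term adapts to illumination differences between runs; the absolute floor of
15 gray levels stops interior texture from reading as inclusions in cells
whose intensity range is small.  Counts are integers per cell; sample
reports average them over intact cells (hence non-integer means) and also
provide the mean droplet *area fraction* per cell as an alternative
abundance measure that is less sensitive to merging of adjacent droplets.
On 500 synthetic cells with 0–5 planted droplets at default contrast, exact
count recovery is about 99%.

## The synthetic generator

Objects are star-convex radial shapes: an ellipse (polar form about the
center) times a sinusoidal boundary perturbation, rendered dark on a light
background with a bright rim just inside the boundary — the brightfield
appearance.  Class-typical parameters (all configurable per object):

| class | semi-axis a (px) | interior offset | texture | boundary perturbation |
|---|---|---|---|---|
| intact | 18–28 | −35 | fine, sd 5 | none |
| anomalous | 16–30 | −30 | blotchy, sd 12 | 15–30% amplitude, 3–7 lobes |
| dead | 8–12 | −18 | granular, sd 15 | 4–10% |
| aggregate | union of 2–4 ellipses, a 12–20 | −32 | fine, sd 6 | — |
| debris | 7–10 | −25 | fine, sd 8 | 10–20%, 3–4 lobes |

Frames default to 96x256 px (a channel-like field of view) with background
level 190, a 10-gray-level lateral gradient, Gaussian noise sd 3, optional
dark channel-wall bands, and at least 4 px separation between placed
objects.  Droplets are anti-aliased dark disks (radius 3 px, contrast 60)
planted disjointly inside the eroded mask.  The ground-truth manifest
records each object's exact polygon (720 vertices; for aggregates, the
traced union boundary), analytic area and perimeter, class, and droplet
positions.

Design notes, made once and kept:

* No quantitative pixel-level description of the five classes exists, so the
  renderings are parameterized caricatures; contrasts, textures and
  perturbations are dials, and a `hard_mode` narrows the
  intact-vs-anomalous gap (the hardest boundary) for stress testing.
* Boundary irregularity is kept at wavelengths resolvable at the imaging
  scale.  Early debris settings used ±25–40% perturbations with up to 8
  lobes on ~7 px objects — structure below the smoothing scale of the
  detector, which no segmentation at that scale can recover; the phantom
  was recalibrated to 10–20% with 3–4 lobes, which is also the more
  realistic rendition of small debris.
* Some aggregates are smaller in total area than large intact cells, so
  size alone cannot separate the classes — a property the classifier must
  and does handle.
* What passing tests show: the pipeline recovers the truth its generator
  encodes.  What they cannot show: robustness to optical effects the
  generator does not model (defocus, motion blur, flow physics,
  photorealistic texture).  Results on real data should be spot-checked
  against the deposited raw images of a real instrument.

## Event store and formats

Frames travel as multi-page 8-bit TIFF stacks or PNG directories; non-8-bit
input is rejected rather than silently rescaled.  Segmented events live in
an HDF5 event store (`writeEventStore()`): ragged crops, masks and contours
(flattened data plus per-event dimensions), aligned `/features/*` arrays,
and a JSON metadata snapshot (pixel size, flow-rate annotations,
configuration).  The layout is documented and round-trips bit-exactly, but
is not claimed to be `.rtdc`-compatible.  The pixel size (default 0.147
um/px) is a configuration value: the sensor and objective names of an
instrument do not determine it reliably, so it is never derived from
hardware identifiers.  Flat per-event tables export to CSV for plotting;
`deformAreaHistogram()` provides the binned (area, deformation) table
behind the standard DC scatter/density plot.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed: generation, splitting,
initialization, shuffling, augmentation, dropout.  Pipeline commands
(`dcSimulate()` … `dcReport()`, or the `inst/scripts/dcshape` wrapper) are
idempotent given a configuration and seed, and their data outputs are
byte-identical across re-runs; provenance files (configuration hash,
package version, timestamp) are written separately so timestamps never
break determinism.  The test suite and the acceptance script size their
simulations for a single CPU core: 50 frames / 200 objects for
segmentation recovery, 500 cells for droplet recovery, 200 images per class
and 10 epochs at 64 px for the classifier, 9,000 draws for the mode — the
package's chosen desk-scale reference conditions.

## Known limitations

* The temporal-median background assumes static illumination across the
  sequence.
* Touching cells not flagged as aggregates by the experimenter are still
  detected as single events; there is deliberately no watershed splitting.
* The droplet counter merges inclusions closer than the smoothing scale
  and is blind to droplets overlapping the excluded rim; the area-fraction
  metric partially compensates.
* The synthetic phantom omits optics (PSF, defocus, motion blur) and flow
  physics; classifier accuracies on it do not transfer to instrument data
  without retraining on labeled real crops.
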