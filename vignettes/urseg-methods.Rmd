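---
title: "Tracing ulna and radius contours with dynamic programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing ulna and radius contours with dynamic programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urseg)
```

## The problem

Single X-ray absorptiometry estimates forearm bone mineral density from a
plain radiograph, and it needs the ulna and radius (UR) outlined first.
Clinical forearm radiographs are hostile to naive pixel classification: the
exposure, orientation and collimation vary between machines, the global
background intensity is uneven under the anode heel effect, and near the
wrist the bone contours become weak and diffuse. `urseg` implements a
deliberately simple, robust pipeline for this task: standardize the image,
find four seed points on the bone shaft (diaphysis) edges, and trace the
contours as minimum-cost paths through gradient-based cost maps with 1-D
dynamic programming (DP), the same machinery as seam carving or the
non-interactive cousin of intelligent scissors.

## The pipeline

### Standardization

`preprocess()` chains five steps, each exposed separately for testing:

1. **Polarity check.** Bone must be brighter than soft tissue, which must be
   brighter than background; if the border median exceeds the center median
   the image is inverted. Vendors disagree on polarity, and nothing
   downstream works if it is wrong.
2. **Crop** (`crop_valid_region()`). Row/column mean-intensity projections
   are thresholded at 5% of their maximum; the maximal surviving interval,
   expanded by a 2% margin, is kept. This removes dark collimation bands.
3. **Direction correction** (`correct_direction()`). Portrait frames are
   rotated 90° clockwise. For exactly square frames, where a width/height
   rule cannot decide, the aspect of the thresholded-foreground bounding box
   is used instead. Horizontal direction is then decided by double
   thresholding at 0.2 and 0.6 of the maximum intensity: the pixels *between*
   the thresholds are soft tissue without bone, and their mass concentrates
   at the wrist/hand end; if that mass sits in the left half the image is
   rotated 180°. The standard frame is forearm horizontal, wrist at the
   right.
4. **Background cleaning** (`extract_and_clean()`). Otsu threshold, largest
   8-connected component, dilation by a 5 px disk, and everything outside
   the mask is set exactly to 0. The dilation guarantees the forearm
   (including its blurred skin line) stays inside the mask.
5. **Denoising and enhancement** (`denoise_enhance()`). A bilateral filter
   (spatial sigma 3 px, range sigma 0.1) suppresses noise without smearing
   edges, then histogram equalization over *mask pixels only* (256 bins)
   normalizes contrast. Restricting the histogram to the mask matters: the
   zeroed background would otherwise dominate the equalization map.
6. **Downsampling** at ratio 0.7 by pixel-center-aligned bilinear
   interpolation. 0.7 is the operating point at which accuracy is stable
   while cost drops; the acceptance suite checks that 1.0 and 0.7 give
   equivalent accuracy on phantoms.

Every geometric operation (crop offset, rotation, scale) is recorded, and
`std_to_orig()` / `orig_to_std()` map coordinates between the standardized
and original frames; round-tripping is exact to floating point. The package
uses 1-based `(row, col)` coordinates and inclusive crop boxes throughout —
the idiomatic R convention.

### Seeds

`locate_distal_end()` finds the wrist: the per-column sum of the forearm
mask has its maximum at the hand and a local minimum at the wrist neck. The
profile is smoothed with a width-7 moving average and the deepest interior
local minimum left of the maximum is taken. Two robustness details that a
naive argmin misses: the search is restricted to genuine dips (flat zero
margins left by the crop are not candidates), and since shallow dips bottom
out in a noise-fragmented flat valley, the midpoint of the contiguous run
within one projection pixel of the minimum is returned rather than whichever
jagged column happens to be lowest.

`detect_seed_points()` probes the column halfway between the proximal edge
and the distal end `x0`, where the four diaphysis edges are well separated
and near-horizontal. The absolute vertical Sobel gradient, averaged over a
7-column window (edges are coherent across columns, noise is not) and
lightly smoothed, is searched for its most prominent local maxima with a
minimum row separation of 8 px. Candidate peaks must *classify* as bone
edges: the inner side of a true diaphysis edge is bone, the brightest tissue
class, so it must be clearly brighter than the outer side and sit at the
probe column's bone intensity level — above the midpoint of the column's
30th and 85th masked-intensity quantiles (roughly the soft-tissue and bone
levels; an absolute threshold fails under background-field tilt). This one
test rejects the three impostors a plain
top-4-by-prominence rule falls for — the skin line (soft tissue inside), the
artificial cliff at the dilated-mask boundary (background inside), and
equalization-amplified noise ridges in soft tissue (no contrast). The four
retained rows must alternate upper/lower/upper/lower; otherwise the probe
column is shifted by ±10% of `x0` (up to two retries per side) before a seed
error is raised.

### Cost maps

`build_cost_maps()` combines, per pixel,

$$I_1 = \lambda_1 f_{G_y} + (1-\lambda_1) f_c, \qquad
  I_2 = \lambda_2 f_{G_x} + (1-\lambda_2) f_c,$$

where $f_G = 1 - |G|/\max|G|$ is the scaled, inverted Sobel gradient and
$f_c$ is 0 on Canny edge pixels, 1 elsewhere. Defaults
$\lambda_1 = 0.3, \lambda_2 = 0.7$. $I_1$ uses the vertical gradient (the
near-horizontal diaphysis edges), $I_2$ the horizontal gradient (the
near-vertical wrist-joint edges). The gradient term provides a continuous
cue along weak edges where Canny breaks up; the Canny term sharpens
localization where edges are strong. Numerical choices: the absolute Sobel
response is used so both edge polarities cost equally; a constant image
(zero gradient everywhere) gets cost 1 with a warning rather than a division
by zero; Canny thresholds are scale-free (high = 90th percentile of nonzero
gradient magnitudes, low = 0.4 × high, Gaussian pre-smoothing σ = 1.4); and
the outermost 1-px frame of every term is forced to cost 1 so paths do not
hug the crop border where padded gradients are unreliable.

### DP tracing

A path advances one slice (column, or row for joint segments) per step and
moves at most one pixel sideways — 3-connectivity. `cumulative_cost()` fills
the standard seam recurrence (each cell adds its own cost to the cheapest of
its up-to-three predecessors, border rows dropping out-of-range neighbors)
and `backtrack_path()` recovers the optimal path from the minimum of the
stop slice. All ties resolve toward the smallest row (or column), making the
whole pipeline deterministic. Acceptance criterion 1 checks DP optimality
against exhaustive enumeration of every 3-connected path on 100 random maps.

Each of the four diaphysis edges is traced from its seed in both directions
(to column 1, and to `x0`) in chained 64-column windows
(`trace_diaphysis_edge()`): each window's endpoint re-seeds the next, as the
method's sub-segment scheme prescribes; with a window wider than the span
this reduces exactly to a single DP trace, and on noiseless phantoms the
windowed and global traces are verified identical. The two wrist-joint
segments are traced top-to-bottom through $I_2$ in the column band
`x0 ± n/10` (`trace_joint_segment()`). Because the joint must connect two
specific diaphysis endpoints, the DP is seeded only at the upper endpoint
and backtracked from the lower one (endpoint-constrained), which guarantees
a closed contour; if an endpoint falls outside the band the band is widened
with a warning rather than failing.

`assemble_contours()` concatenates upper edge, joint, and reversed lower
edge, closes the polygon with a straight vertical segment at the leftmost
traced column (the proximal end is clipped by the image border, so some
closure rule is required to rasterize masks), maps all vertices back to
original-image coordinates, and rasterizes with an even-odd scanline fill
that includes boundary pixels. Upper/lower paths that cross raise an
assembly error naming the column.

## Evaluation metrics

`confusion_counts()`, `dsc()`, `sens()`, `fpr()` are the standard overlap
metrics. `contour_mad()` is the symmetric mean minimum Euclidean distance
between two contour *pixel sets* (polygons are densified to 8-connected
boundary chains first — summing over sparse vertices would bias the mean).
`contour_msd()` is its signed analogue: each contour pixel contributes its
distance signed by whether it lies inside the other contour's region. As
printed in the source material the inside-positive sign convention
contradicts the stated interpretation ("positive means the ground truth is
larger"); this package fixes the overall sign so the interpretation holds:
`MSD(gt, pred) > 0` when the ground truth is larger, `MSD(A, A) = 0`,
`MSD(A, B) = -MSD(B, A)`. `regional_report()` splits the ground-truth
longitudinal extent into proximal/middle/distal thirds (equal column bands,
both bones pooled, a band with no ground truth reported as missing) and
computes all five metrics per band and for the whole, at original-image
pixel scale.

## The phantom: what it emulates and what it does not

`generate_phantom()` renders a forearm-like scene with exact ground truth:
two bright tapered bone bands (linear taper plus a Gaussian metaphyseal
flare and an elliptical distal cap) inside a soft-tissue band that necks at
the wrist and widens into the hand; a smooth multiplicative background
field (the global intensity nonuniformity of real radiographs); collimation
borders that follow the anatomy; additive clipped Gaussian noise; four
orientations; and an affine exposure model. Defaults sit on a 704×704
canvas, a quarter of the ~2816 px clinical resolution, so full-pipeline
tests run in seconds. `generate_suite()` jitters the geometry over
documented ranges and alternates a normal-exposure regime (noise σ = 0.03,
full contrast) with a low-exposure regime (noise σ = 0.08, exposure scale
0.6 + offset 0.25, i.e. genuinely lower Michelson contrast), emulating a
mixed-dose clinical sample.

The phantom deliberately does **not** model beam hardening, scatter,
overlapping carpal bones at the wrist, pathology (fractures, implants), or
Poisson noise statistics. A green phantom suite therefore establishes that
the algorithmic chain is implemented correctly and is robust to noise,
orientation, exposure and background nonuniformity — not that the method
reaches any particular accuracy on clinical images. For the same reason the
original study's clinical accuracy figures are out of scope here: its
dataset is private, and this package asserts no number it cannot compute.

```{r example, eval = FALSE}
ph  <- generate_phantom(phantom_params(seed = 42))
seg <- segment_image(ph$image)
evaluate_on_phantom(seg, ph)
```

## Design choices made where the design was open

* **Coordinates.** 1-based `(row, col)`, inclusive boxes: the R convention,
  applied uniformly.
* **Crop rule.** The projection-threshold rule (5% of profile maximum, 2%
  margin) is a documented choice; the source material shows the crop points
  only graphically.
* **Square frames.** The portrait test falls back to the foreground
  bounding-box aspect when width equals height exactly.
* **Probe column.** "Middle of the UR" is implemented as `round(x0 / 2)`.
* **Seed-peak strength.** "Strong" peaks are ranked by prominence, which is
  robust to plateaus; the bone-edge classification above decides which
  strong peaks are anatomy.
* **Endpoint anchoring.** The joint segment is endpoint-constrained DP; the
  alternative (free endpoint) cannot guarantee closed contours.
* **Tie-breaks.** Smallest row/column everywhere. One visible consequence,
  asserted in the tests: on an all-zero cost map the traced path climbs to
  the topmost reachable row rather than staying at the seed row, because the
  endpoint minimum is also tied and resolves to the smallest row.
* **Windows.** 64 columns at the downsampled scale; any value wide enough
  reduces to a global trace, and the equivalence is tested.
* **File formats.** The environment provides no PNG/TIFF/DICOM codec, so
  file I/O is netpbm PGM (P2/P5, 8/16-bit) and CSV; in-memory matrices are
  the primary interface.

## Known limitations

* The proximal contour closure is a straight segment at the leftmost traced
  column; if the forearm does not reach the image edge the closure is
  arbitrary there.
* Bones are labeled `bone1`/`bone2` top-to-bottom, not anatomically
  (radius/ulna assignment depends on laterality and projection).
* The distal cap of each bone is recovered only as well as a 3-connected
  path can follow it; sharp cap corners are slightly chamfered.
* Skin-line (soft-tissue) contours are not traced.
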