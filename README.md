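# urseg — automatic ulna and radius segmentation in forearm radiographs

`urseg` segments the two forearm long bones (ulna and radius, UR) in 2-D
grayscale radiographs. Outlining the UR is the prerequisite for single X-ray
absorptiometry bone-mineral-density measurement, and it is hard to do
robustly: clinical radiographs vary in orientation, exposure and
collimation, carry strong global background nonuniformity, and the bone
contours fade near the wrist.

The package implements a deterministic contour-tracing pipeline:

1. **Standardize** the radiograph — crop the valid region from intensity
   projections, rotate the forearm to horizontal with the wrist at the right,
   extract the forearm mask (Otsu + largest component + dilation) and zero
   the background, bilateral-filter and histogram-equalize over the mask,
   downsample (default ratio 0.7).
2. **Detect seeds** — the wrist column `x0` at the deepest interior minimum
   of the mask's vertical projection (left of its maximum), then the four
   diaphysis-edge seed points as the most prominent peaks of the vertical
   gradient profile at the mid-diaphysis column.
3. **Build cost maps** — per-pixel costs in [0, 1] where edges are cheap:
   `I1 = 0.3 f_Gy + 0.7 f_c` and `I2 = 0.7 f_Gx + 0.3 f_c`, with `f_G` the
   scaled inverted absolute Sobel gradient and `f_c` an inverted Canny edge
   mask.
4. **Trace** — minimum-cost 3-connected paths by 1-D dynamic programming
   (the seam recurrence): four diaphysis edges traced in chained 64-column
   windows from each seed to the image edge and to `x0`, two wrist-joint
   segments traced top-to-bottom in the `x0 ± n/10` band with
   endpoint-constrained backtracking, then assembly into two closed polygons
   mapped back to original-image coordinates.
5. **Evaluate** — Dice (DSC), sensitivity, false-positive rate on masks;
   mean absolute distance (MAD) and signed mean distance (MSD) on contour
   pixel sets; whole image plus proximal/middle/distal thirds.

A synthetic phantom generator (`generate_phantom()`, `generate_suite()`)
renders forearm-like images with exact ground truth (bone masks, contours,
edge rows, wrist column) across orientations and exposure regimes, so the
entire pipeline is testable without clinical data.

## Worked example

```r
library(urseg)

ph  <- generate_phantom(phantom_params(seed = 42))   # 704 x 704 phantom
seg <- segment_image(ph$image)                       # full pipeline
seg
#> UR contours: bone1 760 vertices (area 20659 px), bone2 758 vertices (area 19376 px)

evaluate_on_phantom(seg, ph)
#> Segmentation evaluation (fractions; distances in original-image pixels)
#>    region    dsc   sens    fpr    mad     msd  n_gt
#>     whole 0.9843 0.9996 0.0314 0.6888 -0.6742 37874
#>  proximal 0.9858 0.9988 0.0275 0.8527 -0.8134 12042
#>    middle 0.9831 1.0000 0.0344 0.6447 -0.6447 12616
#>    distal 0.9841 0.9999 0.0322 0.5719 -0.5678 13216
```

Reading: both bones overlap the ground truth at DSC ≈ 0.98 with every
boundary on average within 1 px (MAD) of the true contour; the slightly
negative MSD says the traced contours sit a fraction of a pixel *outside*
the true bone edges. `attr(seg, "seed_set")` holds `x0` and the four seeds;
`attr(seg, "preprocessed")` the standardized image and the transform used to
map results back to input coordinates.

Real images: `segment_image(read_radiograph("forearm.pgm"))`, or from the
shell via the CLI launcher:

```sh
Rscript inst/cli/urseg.R run --input forearm.pgm --out outdir --ratio 0.7
Rscript inst/cli/urseg.R eval --gt gt.pgm --pred outdir/mask_bone1.pgm --report report.json
Rscript inst/cli/urseg.R phantom --n 20 --seed 1 --out phantoms/
```

## Acceptance

The original study's quantitative results were computed on a private
clinical dataset, so no printed number is reproducible here; acceptance is
property-based and lives in `tests/testthat/test-acceptance.R` (DP
optimality vs exhaustive enumeration, metric formula checks, parameter
recovery on a 20-phantom suite, exposure robustness, downsample stability,
determinism/geometry). The report script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs a seeded pipeline self-check and writes the (empty) target report —
see `vignettes/urseg-methods.Rmd` for the full methods account.
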