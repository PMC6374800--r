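# Preprocessing: standardize a raw forearm radiograph so that the forearm lies
# horizontal, pointing left-to-right with the wrist at the right, on a clean
# zero background, denoised, contrast-enhanced and downsampled. All later
# stages (seed detection, cost maps, DP tracing) assume this standard frame.

stop_urseg <- function(msg, class = "urseg_error") {
  cond <- structure(class = c(class, "urseg_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

#' Preprocessing configuration
#'
#' @param downsample_ratio linear downsampling factor in (0, 1\]; 0.7 is the
#'   operating point at which accuracy is stable while computation drops.
#' @param low_threshold,high_threshold direction-correction double thresholds,
#'   as fractions of the maximum image intensity. The difference mask
#'   (pixels between the two thresholds) isolates soft-tissue-only regions,
#'   whose mass concentrates at the wrist/hand end.
#' @param mask_threshold global threshold for the forearm mask as an intensity
#'   in \[0, 1\], or `NULL` to use Otsu's method.
#' @param dilation_radius disk radius (pixels) for enlarging the forearm mask.
#' @param bilateral_sigma_s,bilateral_sigma_r bilateral filter spatial sigma
#'   (pixels) and range sigma (intensity units).
#' @param crop_profile_fraction fraction of the projection-profile maximum
#'   above which a row/column counts as image content.
#' @param crop_margin fractional expansion of the detected valid interval.
#' @param eq_bins histogram bins for masked equalization.
#' @return a list of class `ur_preprocess_config`.
#' @export
preprocess_config <- function(downsample_ratio = 0.7,
                              low_threshold = 0.2,
                              high_threshold = 0.6,
                              mask_threshold = NULL,
                              dilation_radius = 5,
                              bilateral_sigma_s = 3,
                              bilateral_sigma_r = 0.1,
                              crop_profile_fraction = 0.05,
                              crop_margin = 0.02,
                              eq_bins = 256L) {
  if (downsample_ratio <= 0 || downsample_ratio > 1)
    stop("downsample_ratio must be in (0, 1]")
  if (low_threshold >= high_threshold)
    stop("low_threshold must be smaller than high_threshold")
  structure(list(downsample_ratio = downsample_ratio,
                 low_threshold = low_threshold,
                 high_threshold = high_threshold,
                 mask_threshold = mask_threshold,
                 dilation_radius = dilation_radius,
                 bilateral_sigma_s = bilateral_sigma_s,
                 bilateral_sigma_r = bilateral_sigma_r,
                 crop_profile_fraction = crop_profile_fraction,
                 crop_margin = crop_margin,
                 eq_bins = as.integer(eq_bins)),
            class = "ur_preprocess_config")
}

# Maximal index interval where the profile exceeds frac * max(profile),
# expanded by floor(margin * length) on each side.
valid_interval <- function(prof, frac, margin) {
  th <- frac * max(prof)
  idx <- which(prof > th)
  if (!length(idx)) return(NULL)
  lo <- min(idx); hi <- max(idx)
  pad <- floor(margin * (hi - lo + 1L))
  c(max(1L, lo - pad), min(length(prof), hi + pad))
}

#' Crop the valid image region
#'
#' Detects the valid coordinate ranges from the vertical and horizontal mean
#' intensity projections: the valid rows (columns) are the maximal interval
#' where the row (column) mean exceeds `crop_profile_fraction` of the profile
#' maximum, expanded by a `crop_margin` fraction of the interval length. This
#' removes dark collimation bands and unexposed borders.
#'
#' @param image radiograph matrix.
#' @param config [preprocess_config()].
#' @return list with `image` (the cropped sub-image) and `crop_box`
#'   `c(r0, c0, r1, c1)` in 1-based inclusive original coordinates.
#' @export
crop_valid_region <- function(image, config = preprocess_config()) {
  image <- as_radiograph(image)
  rr <- valid_interval(rowMeans(image), config$crop_profile_fraction, config$crop_margin)
  cc <- valid_interval(colMeans(image), config$crop_profile_fraction, config$crop_margin)
  if (is.null(rr) || is.null(cc) ||
      (rr[2] - rr[1] + 1L) < 32L || (cc[2] - cc[1] + 1L) < 32L)
    stop_urseg("crop_valid_region: detected valid region is degenerate (smaller than 32x32)",
               "urseg_preprocess_error")
  list(image = image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
       crop_box = c(rr[1], cc[1], rr[2], cc[2]))
}

#' Correct the forearm direction to left-to-right
#'
#' If the cropped region is portrait (width < height) it is first rotated 90
#' degrees clockwise. The horizontal direction is then decided by double
#' thresholding: the difference of the low- and high-threshold binary masks
#' (pixels between `low_threshold` and `high_threshold` times the maximum
#' intensity) captures soft-tissue-only areas, which concentrate at the
#' wrist/hand end; if that mass lies in the left half, the image is rotated
#' 180 degrees so the wrist ends up at the right.
#'
#' @param image cropped radiograph.
#' @param config [preprocess_config()].
#' @return list with `image` and `rotation` (0, 90, 180 or 270 degrees
#'   clockwise).
#' @export
correct_direction <- function(image, config = preprocess_config()) {
  rot <- 0L
  portrait <- if (ncol(image) != nrow(image)) {
    ncol(image) < nrow(image)
  } else {
    # exactly square frame: the width/height rule cannot decide, so fall back
    # to the aspect of the thresholded-foreground bounding box
    fg <- image >= otsu_threshold(image)
    rr <- range(which(rowSums(fg) > 0))
    cc <- range(which(colSums(fg) > 0))
    diff(cc) < diff(rr)
  }
  if (portrait) {
    image <- rot90cw(image)
    rot <- 90L
  }
  mx <- max(image)
  lo <- config$low_threshold * mx
  hi <- config$high_threshold * mx
  diffmask <- image >= lo & image < hi
  if (!any(diffmask))
    stop_urseg("correct_direction: difference mask is empty; thresholds are degenerate for this image",
               "urseg_preprocess_error")
  n <- ncol(image)
  left <- sum(diffmask[, seq_len(n %/% 2L), drop = FALSE])
  right <- sum(diffmask) - left
  if (left > right) {
    image <- rot_mat(image, 180)
    rot <- (rot + 180L) %% 360L
  }
  list(image = image, rotation = rot)
}

#' Extract and clean the forearm mask
#'
#' Global threshold (Otsu unless `mask_threshold` is set), largest
#' 8-connected component, morphological dilation by `dilation_radius`, then
#' all intensities outside the mask are set exactly to 0.
#'
#' @param image direction-corrected radiograph.
#' @param config [preprocess_config()].
#' @return list with `image` (background-cleaned) and `mask` (logical).
#' @export
extract_and_clean <- function(image, config = preprocess_config()) {
  th <- if (is.null(config$mask_threshold)) otsu_threshold(image) else config$mask_threshold
  fg <- image >= th
  if (!any(fg))
    stop_urseg("extract_and_clean: empty mask after global thresholding",
               "urseg_preprocess_error")
  mask <- dilate_disk(largest_component(fg), config$dilation_radius)
  image[!mask] <- 0
  list(image = image, mask = mask)
}

#' Denoise and enhance contrast
#'
#' Edge-preserving bilateral smoothing followed by histogram equalization
#' computed over forearm-mask pixels only (so the zeroed background does not
#' dominate the histogram). Zeros outside the mask are preserved exactly.
#'
#' @param image background-cleaned radiograph.
#' @param config [preprocess_config()].
#' @param mask forearm mask; `NULL` treats the whole frame as foreground.
#' @return enhanced radiograph in \[0, 1\].
#' @export
denoise_enhance <- function(image, config = preprocess_config(), mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  out <- bilateral_cpp(image, config$bilateral_sigma_s, config$bilateral_sigma_r)
  out[!mask] <- 0
  out <- hist_equalize_masked(out, mask, config$eq_bins)
  pmin(pmax(out, 0), 1)
}

#' Downsample by bilinear interpolation
#'
#' Output dimensions are `round(ratio * dim(image))`.
#'
#' @param image radiograph.
#' @param ratio linear scale factor in (0, 1\].
#' @return downsampled matrix.
#' @export
downsample_image <- function(image, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1)
    stop("downsample_image: ratio must be a scalar in (0, 1]")
  if (ratio == 1) return(image)
  resize_bilinear(image, max(1L, round(ratio * nrow(image))),
                  max(1L, round(ratio * ncol(image))))
}

#' Standardize a raw forearm radiograph
#'
#' Runs the full preprocessing chain: polarity check (invert if the border is
#' brighter than the center), crop of the valid region, direction correction,
#' forearm-mask extraction and background cleaning, bilateral denoising with
#' masked histogram equalization, and bilinear downsampling. The composite
#' geometric transform (crop offset, rotation, scale) is recorded so contours
#' traced in the standardized frame can be mapped back to original-image
#' coordinates (see [std_to_orig()]).
#'
#' @param image raw radiograph matrix (see [as_radiograph()]).
#' @param config [preprocess_config()].
#' @return an object of class `ur_preprocessed` with elements `pixels`,
#'   `mask`, `transform` and `provenance`.
#' @export
preprocess <- function(image, config = preprocess_config()) {
  image <- as_radiograph(image)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_urseg(sprintf("preprocess[%s]: %s", name, conditionMessage(e)),
                 class(e)[1L])
    })
  }
  m <- nrow(image); n <- ncol(image)
  # polarity: bone must be brighter than soft tissue than background
  bw <- max(1L, round(0.05 * min(m, n)))
  border <- c(image[seq_len(bw), ], image[(m - bw + 1L):m, ],
              image[, seq_len(bw)], image[, (n - bw + 1L):n])
  center <- image[round(m / 4):round(3 * m / 4), round(n / 4):round(3 * n / 4)]
  inverted <- stats::median(border) > stats::median(center)
  if (inverted) image <- 1 - image

  cr <- stage("crop", crop_valid_region(image, config))
  cd <- stage("direction", correct_direction(cr$image, config))
  cl <- stage("clean", extract_and_clean(cd$image, config))
  enh <- stage("enhance", denoise_enhance(cl$image, config, cl$mask))
  ratio <- config$downsample_ratio
  std <- stage("downsample", downsample_image(enh, ratio))
  mask_std <- if (ratio == 1) cl$mask else
    resize_bilinear(cl$mask + 0, nrow(std), ncol(std)) >= 0.5
  std[!mask_std] <- 0

  transform <- list(
    crop = cr$crop_box,
    rot = cd$rotation,
    ratio = ratio,
    dims = list(orig = c(m, n),
                cropped = dim(cr$image),
                rotated = dim(cd$image),
                std = dim(std)))
  structure(list(pixels = std,
                 mask = mask_std,
                 transform = transform,
                 provenance = list(inverted = inverted,
                                   rotation = cd$rotation,
                                   crop_box = cr$crop_box,
                                   ratio = ratio)),
            class = "ur_preprocessed")
}

#' @export
print.ur_preprocessed <- function(x, ...) {
  d <- x$transform$dims
  cat(sprintf("Standardized radiograph %dx%d (from %dx%d; crop [%s], rot %d, ratio %g%s)\n",
              d$std[1], d$std[2], d$orig[1], d$orig[2],
              paste(x$transform$crop, collapse = ","), x$transform$rot,
              x$transform$ratio,
              if (isTRUE(x$provenance$inverted)) ", inverted" else ""))
  invisible(x)
}

#' Map points between the standardized and original frames
#'
#' Points are `(row, col)` pairs (matrix rows), 1-based, pixel centers at
#' integers; fractional coordinates are allowed. `std_to_orig()` applies the
#' inverse preprocessing geometry (upscale, un-rotate, un-crop);
#' `orig_to_std()` is its inverse. Round-tripping reproduces coordinates to
#' floating-point accuracy, well within the 0.5 px contract.
#'
#' @param pts numeric matrix with columns (row, col).
#' @param transform the `transform` element of a `ur_preprocessed` object.
#' @return transformed points matrix.
#' @export
std_to_orig <- function(pts, transform) {
  pts <- as.matrix(pts)
  d <- transform$dims
  sm <- d$rotated[1] / d$std[1]
  sn <- d$rotated[2] / d$std[2]
  out <- cbind((pts[, 1] - 0.5) * sm + 0.5, (pts[, 2] - 0.5) * sn + 0.5)
  out <- unrotate_points_cw(out, transform$rot, d$cropped)
  out[, 1] <- out[, 1] + transform$crop[1] - 1
  out[, 2] <- out[, 2] + transform$crop[2] - 1
  colnames(out) <- c("row", "col")
  out
}

#' @rdname std_to_orig
#' @export
orig_to_std <- function(pts, transform) {
  pts <- as.matrix(pts)
  d <- transform$dims
  out <- cbind(pts[, 1] - transform$crop[1] + 1, pts[, 2] - transform$crop[2] + 1)
  out <- rotate_points_cw(out, transform$rot, d$cropped)
  sm <- d$rotated[1] / d$std[1]
  sn <- d$rotated[2] / d$std[2]
  out <- cbind((out[, 1] - 0.5) / sm + 0.5, (out[, 2] - 0.5) / sn + 0.5)
  colnames(out) <- c("row", "col")
  out
}
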