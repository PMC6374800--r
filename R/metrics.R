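# Segmentation evaluation: overlap metrics (DSC, sensitivity, false positive
# rate) on masks and boundary-distance metrics (MAD, signed MSD) on contour
# pixel sets, with a proximal/middle/distal regional breakdown.

#' Confusion counts between two binary masks
#'
#' @param gt_mask,pred_mask same-shape logical matrices (ground truth,
#'   prediction).
#' @return list with `TP`, `FP`, `FN` pixel counts.
#' @export
confusion_counts <- function(gt_mask, pred_mask) {
  if (!identical(dim(gt_mask), dim(pred_mask)))
    stop("confusion_counts: mask shapes differ")
  list(TP = sum(gt_mask & pred_mask),
       FP = sum(!gt_mask & pred_mask),
       FN = sum(gt_mask & !pred_mask))
}

check_counts <- function(counts) {
  if (counts$TP + counts$FN == 0)
    stop("metric undefined: ground truth has no foreground pixels (TP + FN = 0)")
  counts
}

#' Overlap metrics
#'
#' `dsc = 2 TP / (2 TP + FN + FP)` (Dice similarity coefficient),
#' `sens = TP / (TP + FN)` (sensitivity) and `fpr = FP / (TP + FN)`
#' (false positives relative to the ground-truth foreground size).
#'
#' @param counts list from [confusion_counts()].
#' @return scalar fraction.
#' @export
dsc <- function(counts) {
  counts <- check_counts(counts)
  2 * counts$TP / (2 * counts$TP + counts$FN + counts$FP)
}

#' @rdname dsc
#' @export
sens <- function(counts) {
  counts <- check_counts(counts)
  counts$TP / (counts$TP + counts$FN)
}

#' @rdname dsc
#' @export
fpr <- function(counts) {
  counts <- check_counts(counts)
  counts$FP / (counts$TP + counts$FN)
}

#' Contour pixel set
#'
#' Densifies a polygon or polyline to unit steps and rounds to an ordered
#' 8-connected chain of boundary pixels; distance metrics sum over these
#' pixel sets rather than over the sparse vertices.
#'
#' @param contour matrix of (row, col) vertices, or an already-densified
#'   pixel set.
#' @param closed close the polyline before densifying.
#' @param densify interpolate unit steps between consecutive vertices; set to
#'   `FALSE` when the input is already a pixel set rather than a polygon (the
#'   rows are then only rounded and deduplicated).
#' @return integer matrix of boundary pixels.
#' @export
contour_pixels <- function(contour, closed = TRUE, densify = TRUE) {
  pts <- as.matrix(contour)
  if (!nrow(pts)) stop("contour_pixels: empty contour")
  if (!densify) return(unique(round(pts)))
  if (closed && nrow(pts) > 1L && any(pts[1L, ] != pts[nrow(pts), ]))
    pts <- rbind(pts, pts[1L, ])
  px <- polyline_pixels(pts)
  if (nrow(px) > 1L && all(px[1L, ] == px[nrow(px), ]))
    px <- px[-nrow(px), , drop = FALSE]
  px
}

#' Mean absolute distance between two contours
#'
#' `MAD = (sum_{p in S(A)} d(p, S(B)) + sum_{p in S(B)} d(p, S(A))) /
#' (|S(A)| + |S(B)|)` where `S(.)` are contour pixel sets and `d` is the
#' minimum Euclidean distance to a set. Symmetric, non-negative, zero iff the
#' pixel sets coincide.
#'
#' @param contourA,contourB polygons or pixel sets (see [contour_pixels()]).
#' @param closed treat inputs as closed polygons when densifying.
#' @param densify interpolate polygon edges to pixel chains; use `FALSE` for
#'   inputs that are already pixel sets.
#' @return scalar distance in pixels.
#' @export
contour_mad <- function(contourA, contourB, closed = TRUE, densify = TRUE) {
  A <- contour_pixels(contourA, closed, densify)
  B <- contour_pixels(contourB, closed, densify)
  if (!nrow(A) || !nrow(B)) stop("contour_mad: empty contour")
  (sum(min_dists(A, B)) + sum(min_dists(B, A))) / (nrow(A) + nrow(B))
}

# Signed distances of pixel set P to contour pixels S with interior mask
# inside: positive for p outside the region, negative inside, 0 on S.
signed_dists <- function(P, S, inside) {
  d <- min_dists(P, S)
  s <- ifelse(inside[cbind(pmin(pmax(round(P[, 1]), 1), nrow(inside)),
                           pmin(pmax(round(P[, 2]), 1), ncol(inside)))], -1, 1)
  d * s
}

#' Mean signed distance between two closed contours
#'
#' Signed analogue of [contour_mad()]: each contour pixel contributes its
#' distance to the other contour, signed by whether it lies inside the other
#' contour's region. The sign convention is fixed so that a positive value
#' means the first (ground-truth) contour is on average larger than the
#' second: `MSD(A, A) = 0` and `MSD(A, B) = -MSD(B, A)`.
#'
#' @param contourA,contourB closed polygons (ground truth first).
#' @param dim raster dimensions used for the inside test; defaults to the
#'   joint bounding box.
#' @return scalar signed distance in pixels.
#' @export
contour_msd <- function(contourA, contourB, dim = NULL) {
  A <- as.matrix(contourA); B <- as.matrix(contourB)
  if (nrow(A) < 3L || nrow(B) < 3L)
    stop("contour_msd: contours must be closed polygons")
  if (is.null(dim)) {
    dim <- c(ceiling(max(A[, 1], B[, 1])) + 2L, ceiling(max(A[, 2], B[, 2])) + 2L)
  }
  maskA <- fill_polygon(A, dim)
  maskB <- fill_polygon(B, dim)
  SA <- contour_pixels(A)
  SB <- contour_pixels(B)
  # signed_dists is + outside / - inside; when A is larger, A's pixels lie
  # outside B (+) and B's pixels inside A (-), so the difference is positive.
  (sum(signed_dists(SA, SB, maskB)) - sum(signed_dists(SB, SA, maskA))) /
    (nrow(SA) + nrow(SB))
}

band_metrics <- function(gt_mask, pred_mask, gt_px, pred_px, gt_inside, pred_inside,
                         cols) {
  sel <- function(mask) {
    out <- mask & FALSE
    out[, cols] <- mask[, cols, drop = FALSE]
    out
  }
  g <- sel(gt_mask); p <- sel(pred_mask)
  if (!any(g))
    return(data.frame(dsc = NA_real_, sens = NA_real_, fpr = NA_real_,
                      mad = NA_real_, msd = NA_real_, n_gt = 0L))
  counts <- confusion_counts(g, p)
  gpx <- gt_px[gt_px[, 2] >= min(cols) & gt_px[, 2] <= max(cols), , drop = FALSE]
  ppx <- pred_px[pred_px[, 2] >= min(cols) & pred_px[, 2] <= max(cols), , drop = FALSE]
  if (nrow(gpx) && nrow(ppx)) {
    madv <- (sum(min_dists(gpx, pred_px)) + sum(min_dists(ppx, gt_px))) /
      (nrow(gpx) + nrow(ppx))
    msdv <- (sum(signed_dists(gpx, pred_px, pred_inside)) -
               sum(signed_dists(ppx, gt_px, gt_inside))) / (nrow(gpx) + nrow(ppx))
  } else {
    madv <- NA_real_; msdv <- NA_real_
  }
  data.frame(dsc = dsc(counts), sens = sens(counts), fpr = fpr(counts),
             mad = madv, msd = msdv, n_gt = counts$TP + counts$FN)
}

#' Regional evaluation report
#'
#' Computes DSC, sensitivity, FPR, MAD and MSD for the whole image and for the
#' proximal, middle and distal thirds of the ground-truth longitudinal extent
#' (equal column bands from left to right, widths differing by at most one
#' column). Both bones are pooled per region. Distance metrics restrict each
#' contour pixel set to the band but measure distances against the full other
#' contour. A band with no ground-truth pixels is reported as missing (`NA`).
#'
#' @param gt_mask,pred_mask binary masks in a common (original-image) frame.
#' @param gt_contours,pred_contours lists of closed polygons (one per bone) in
#'   the same frame.
#' @return data.frame of class `ur_eval_report`, one row per region.
#' @export
regional_report <- function(gt_mask, pred_mask, gt_contours, pred_contours) {
  if (!identical(dim(gt_mask), dim(pred_mask)))
    stop("regional_report: mask shapes differ")
  gt_px <- do.call(rbind, lapply(gt_contours, contour_pixels))
  pred_px <- do.call(rbind, lapply(pred_contours, contour_pixels))
  cols_any <- which(colSums(gt_mask) > 0)
  if (!length(cols_any)) stop("regional_report: empty ground truth")
  c0 <- min(cols_any); c1 <- max(cols_any)
  L <- c1 - c0 + 1L
  b <- c0 - 1L + round(seq_len(3L) * L / 3)
  bands <- list(whole = c0:c1,
                proximal = c0:b[1],
                middle = (b[1] + 1L):b[2],
                distal = (b[2] + 1L):b[3])
  out <- do.call(rbind, lapply(names(bands), function(nm) {
    cbind(region = nm,
          band_metrics(gt_mask, pred_mask, gt_px, pred_px, gt_mask, pred_mask,
                       bands[[nm]]))
  }))
  rownames(out) <- NULL
  class(out) <- c("ur_eval_report", "data.frame")
  out
}

#' @export
print.ur_eval_report <- function(x, ...) {
  cat("Segmentation evaluation (fractions; distances in original-image pixels)\n")
  y <- x
  for (cn in c("dsc", "sens", "fpr", "mad", "msd")) y[[cn]] <- round(y[[cn]], 4)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Evaluate a segmentation against phantom ground truth
#'
#' Convenience wrapper: pools the two predicted bone masks and contours from a
#' `ur_contours` object and the phantom's stored truth, and calls
#' [regional_report()]. Also attaches per-bone DSC values (bones matched top
#' to bottom).
#'
#' @param contours `ur_contours` from [segment_image()].
#' @param phantom `ur_phantom` from [generate_phantom()].
#' @return `ur_eval_report` with attribute `per_bone_dsc`.
#' @export
evaluate_on_phantom <- function(contours, phantom) {
  gt_mask <- phantom$bone_masks[[1]] | phantom$bone_masks[[2]]
  pred_mask <- contours$masks$bone1 | contours$masks$bone2
  rep <- regional_report(gt_mask, pred_mask,
                         phantom$bone_contours,
                         list(contours$bone1, contours$bone2))
  per_bone <- vapply(1:2, function(i) {
    dsc(confusion_counts(phantom$bone_masks[[i]], contours$masks[[i]]))
  }, numeric(1))
  attr(rep, "per_bone_dsc") <- per_bone
  rep
}
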