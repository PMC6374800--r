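# Seed detection: the distal-end column x0 of the ulna/radius and the four
# diaphysis-edge seed points from which DP tracing starts.

#' Locate the distal end of the ulna/radius
#'
#' The vertical projection (per-column sum) of the forearm mask has a global
#' maximum at the hand (`p_max`) and a local minimum at the wrist neck; the
#' distal end column `x0` is the deepest interior local minimum of the
#' smoothed projection restricted to columns `[1, p_max]`: the smallest
#' interior value with strictly larger values somewhere on both sides of it
#' within the search range (projection values tie frequently, so a fixed-width
#' window test is too brittle). The projection is smoothed with a centered
#' moving average of width `smooth_width` first. If the minimum bottoms out in
#' a flat plateau, the plateau center is returned; ties between distinct dips
#' resolve to the smallest column.
#'
#' @param mask logical forearm mask from [preprocess()].
#' @param smooth_width moving-average width for the projection.
#' @return list with integer `x0` and `p_max` (column indices) and the
#'   smoothed `profile`.
#' @export
locate_distal_end <- function(mask, smooth_width = 7L) {
  if (!any(mask))
    stop_urseg("locate_distal_end: empty forearm mask", "urseg_seed_error")
  prof <- moving_average(colSums(mask), smooth_width)
  p_max <- which.max(prof)
  # interior local minima of the projection restricted to [1, p_max], found
  # as positive-prominence peaks of the negated profile (robust to the flat
  # zero margins the crop leaves at the image edges)
  dips <- find_peaks(-prof[seq_len(p_max)])
  dips <- dips[dips$prominence > 0 & prof[dips$idx] > 0, , drop = FALSE]
  x0 <- NA_integer_
  if (nrow(dips)) {
    i <- dips$idx[which.min(prof[dips$idx])]  # deepest; ties -> smallest column
    # shallow dips bottom out in a flat, noise-fragmented valley floor; take
    # the midpoint of the contiguous run within one projection pixel of the
    # minimum rather than whichever jagged column happens to be lowest
    tol <- 1
    l <- i; while (l > 1L && prof[l - 1L] <= prof[i] + tol) l <- l - 1L
    r <- i; while (r < p_max && prof[r + 1L] <= prof[i] + tol) r <- r + 1L
    x0 <- (l + r) %/% 2L
  }
  if (is.na(x0)) {
    cond <- structure(
      class = c("urseg_seed_error", "urseg_error", "error", "condition"),
      list(message = "locate_distal_end: projection has no interior local minimum in [1, p_max] (monotone or flat profile)",
           call = sys.call(), profile = prof, p_max = p_max))
    stop(cond)
  }
  list(x0 = as.integer(x0), p_max = as.integer(p_max), profile = prof)
}

# Vertical gradient magnitude profile at a probe column, averaged over a
# small column window: the near-horizontal diaphysis edges are coherent
# across neighboring columns while noise responses are not, so the average
# suppresses spurious peaks without moving the edge peaks.
gradient_profile <- function(pixels, col, halfwin = 3L) {
  cols <- max(1L, col - halfwin):min(ncol(pixels), col + halfwin)
  moving_average(rowMeans(abs(sobel_y(pixels))[, cols, drop = FALSE]), 3L)
}

# Classify a candidate gradient peak as a bone edge. A true diaphysis edge
# has bone on its inner side: clearly brighter than the outer side (contrast
# margin in equalized units; true edges differ by ~0.3) and at the bone
# intensity level of the probe column. `bone_level` is supplied per column as
# the midpoint between the column's 30th and 85th masked-intensity quantiles
# (roughly the soft-tissue and bone levels), which stays valid under
# background-field tilt and exposure changes. Skin-line and mask-boundary
# edges have soft tissue or background on the inner side and fail the level
# test; soft-tissue noise ridges fail the contrast test. Returns "upper"
# (bone below the edge), "lower", or NA.
classify_edge <- function(pixels, row, col, offsets = 3:7,
                          contrast_margin = 0.05, bone_level = 0.5) {
  cols <- max(1L, col - 2L):min(ncol(pixels), col + 2L)
  below <- mean(pixels[pmin(nrow(pixels), row + offsets), cols])
  above <- mean(pixels[pmax(1L, row - offsets), cols])
  if (below - above > contrast_margin && below > bone_level) return("upper")
  if (above - below > contrast_margin && above > bone_level) return("lower")
  NA_character_
}

# Peak search at one probe column. Returns seed rows (sorted) or NULL when no
# qualifying quartet exists. Candidate peaks are ranked by prominence, must
# classify as bone edges, respect the minimum row separation, and the four
# retained rows must alternate upper/lower/upper/lower.
seeds_at_column <- function(pre, col, min_distance, margin) {
  prof <- gradient_profile(pre$pixels, col)
  inmask <- which(pre$mask[, col])
  if (length(inmask) < 2L * margin + 4L) return(NULL)
  lo <- min(inmask) + margin
  hi <- max(inmask) - margin
  if (hi - lo < 3L * min_distance) return(NULL)
  windowed <- prof
  windowed[seq_along(prof) < lo | seq_along(prof) > hi] <- 0
  pk <- find_peaks(windowed)
  pk <- pk[pk$idx >= lo & pk$idx <= hi & pk$prominence > 0, , drop = FALSE]
  if (nrow(pk) < 4L) return(NULL)
  cols <- max(1L, col - 2L):min(ncol(pre$pixels), col + 2L)
  colvals <- pre$pixels[min(inmask):max(inmask), cols]
  qs <- stats::quantile(colvals, c(0.3, 0.85), names = FALSE)
  lev <- mean(qs)
  pk$role <- vapply(pk$idx, function(r)
    classify_edge(pre$pixels, r, col, bone_level = lev), character(1))
  pk <- pk[!is.na(pk$role), , drop = FALSE]
  pk <- pk[order(-pk$prominence, pk$idx), , drop = FALSE]
  keep <- integer()
  for (i in seq_len(nrow(pk))) {
    if (!length(keep) || all(abs(pk$idx[i] - pk$idx[keep]) >= min_distance)) {
      keep <- c(keep, i)
      if (length(keep) >= 4L) break
    }
  }
  if (length(keep) < 4L) return(NULL)
  sel <- pk[keep, , drop = FALSE]
  sel <- sel[order(sel$idx), , drop = FALSE]
  if (!identical(sel$role, c("upper", "lower", "upper", "lower"))) return(NULL)
  sel$idx
}

#' Detect the four diaphysis-edge seed points
#'
#' At the probe column (the midpoint between the proximal image edge and the
#' distal end, `round(x0 / 2)`), the absolute vertical Sobel gradient profile
#' is searched for its 4 most prominent local maxima subject to a minimum
#' inter-peak row distance. The top and bottom `margin` pixels of the forearm
#' mask extent along the probe column are excluded so the skin line and the
#' dilated-mask boundary cliff are not picked up; the four returned peaks are
#' the bone diaphysis edges, ordered top to bottom and labeled
#' `bone1_upper, bone1_lower, bone2_upper, bone2_lower`.
#'
#' If fewer than 4 qualifying peaks are found, the detection is retried at
#' `probe_col` shifted by up to twice 10\% of `x0` on either side.
#'
#' @param pre `ur_preprocessed` object.
#' @param x0 distal-end column from [locate_distal_end()] (standardized frame).
#' @param p_max optional maximum-projection column, stored in the result.
#' @param min_distance minimum row separation between peaks (pixels).
#' @param margin excluded band at the mask boundary (pixels).
#' @return object of class `ur_seed_set` with `x0`, `p_max`, `probe_col` and
#'   `seeds` (4 x 2 matrix of (row, col), rows increasing).
#' @export
detect_seed_points <- function(pre, x0, p_max = NA_integer_,
                               min_distance = 8L, margin = 10L) {
  stopifnot(inherits(pre, "ur_preprocessed"))
  n <- ncol(pre$pixels)
  if (x0 < 1L || x0 > n) stop("detect_seed_points: x0 out of range")
  probe0 <- max(2L, round(x0 / 2))
  step <- max(1L, round(0.1 * x0))
  offsets <- c(0L, step, -step, 2L * step, -2L * step)
  tried <- integer()
  for (off in offsets) {
    col <- probe0 + off
    if (col < 2L || col >= x0) next
    tried <- c(tried, col)
    rows <- seeds_at_column(pre, col, min_distance, margin)
    if (!is.null(rows)) {
      seeds <- cbind(row = rows, col = rep(col, 4L))
      rownames(seeds) <- c("bone1_upper", "bone1_lower", "bone2_upper", "bone2_lower")
      return(structure(list(x0 = as.integer(x0), p_max = as.integer(p_max),
                            probe_col = as.integer(col), seeds = seeds),
                       class = "ur_seed_set"))
    }
  }
  stop_urseg(sprintf(
    "detect_seed_points: fewer than 4 qualifying gradient peaks at probe columns %s",
    paste(tried, collapse = ", ")), "urseg_seed_error")
}

#' @export
print.ur_seed_set <- function(x, ...) {
  cat(sprintf("Seed set: x0 = %d, probe column = %d\n", x$x0, x$probe_col))
  print(x$seeds)
  invisible(x)
}
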