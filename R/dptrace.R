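# Minimum-cost path tracing by 1-D dynamic programming (seam recurrence).
#
# A path advances exactly one slice (column for diaphysis edges, row for the
# wrist-joint edges) per step and may move at most one pixel sideways
# (3-connectivity). The cumulative minimum cost is
#
#   c(i, j) = I(i, j) + min over the 3-connected cells of the previous slice,
#
# with the border branches dropping out-of-range rows. Tracing back from the
# minimum of the stop slice recovers the optimal path; ties always resolve to
# the smallest row (or column, when tracing along rows).

# Internal: view a matrix in the "column-advancing" working orientation.
work_view <- function(x, axis) if (axis == "col") x else t(x)
work_pt <- function(p, axis) if (axis == "col") p else c(p[2], p[1])

#' Cumulative minimum cost from a seed point
#'
#' Computes the DP table of cumulative minimum 3-connected path cost from
#' `seed` toward `stop` along the tracing axis. Slices before the seed
#' (against the direction) and cells outside the reachable cone hold `Inf`.
#'
#' @param costmap numeric cost matrix.
#' @param seed `(row, col)` seed point.
#' @param axis `"col"` (path advances along columns) or `"row"`.
#' @param direction +1 or -1 along the tracing axis.
#' @param stop slice index (column for `axis = "col"`) at which to stop.
#' @return object of class `ur_cumcost` with the cumulative matrix `cum` (in
#'   the original orientation) plus `seed`, `axis`, `direction`, `stop`.
#' @export
cumulative_cost <- function(costmap, seed, axis = c("col", "row"),
                            direction = 1L, stop = NULL) {
  axis <- match.arg(axis)
  stopifnot(direction %in% c(-1L, 1L))
  M <- work_view(costmap, axis)
  s <- work_pt(seed, axis)
  m <- nrow(M); n <- ncol(M)
  if (is.null(stop)) stop <- if (direction > 0) n else 1L
  if (s[1] < 1 || s[1] > m || s[2] < 1 || s[2] > n || stop < 1 || stop > n)
    stop("cumulative_cost: seed or stop outside the cost map")
  if (sign(stop - s[2]) == -direction && stop != s[2])
    stop("cumulative_cost: stop lies against the tracing direction")
  cum <- matrix(Inf, m, n)
  cum[s[1], s[2]] <- M[s[1], s[2]]
  js <- if (stop == s[2]) integer() else seq(s[2] + direction, stop, by = direction)
  for (j in js) {
    prev <- cum[, j - direction]
    up <- c(Inf, prev[-m])       # predecessor one row above
    down <- c(prev[-1], Inf)     # predecessor one row below
    cum[, j] <- M[, j] + pmin(up, prev, down)
  }
  structure(list(cum = if (axis == "col") cum else t(cum),
                 seed = seed, axis = axis, direction = direction, stop = stop),
            class = "ur_cumcost")
}

#' Trace back the optimal path
#'
#' The endpoint is the minimum of the stop slice (or a caller-supplied point,
#' used for endpoint-constrained joint tracing); walking back, each step picks
#' the 3-connected predecessor attaining the minimum cumulative cost, with
#' ties broken toward the smallest row.
#'
#' @param cum `ur_cumcost` object.
#' @param endpoint optional `(row, col)` endpoint in the stop slice.
#' @return object of class `ur_traced_path` with `points` (ordered from seed
#'   to endpoint), `axis` and `total_cost`.
#' @export
backtrack_path <- function(cum, endpoint = NULL) {
  stopifnot(inherits(cum, "ur_cumcost"))
  C <- work_view(cum$cum, cum$axis)
  s <- work_pt(cum$seed, cum$axis)
  m <- nrow(C)
  j <- cum$stop
  if (is.null(endpoint)) {
    r <- which.min(C[, j])  # ties -> smallest row
    if (!is.finite(C[r, j]))
      stop_urseg("backtrack_path: stop slice is unreachable from the seed",
                 "urseg_trace_error")
  } else {
    e <- work_pt(endpoint, cum$axis)
    if (e[2] != j) stop("backtrack_path: endpoint is not in the stop slice")
    r <- e[1]
    if (!is.finite(C[r, j]))
      stop_urseg("backtrack_path: endpoint is unreachable from the seed (outside the 3-connected cone)",
                 "urseg_trace_error")
  }
  total <- C[r, j]
  len <- abs(j - s[2]) + 1L
  rows <- integer(len)
  rows[len] <- r
  if (len > 1L) {
    for (k in seq(len - 1L, 1L)) {
      jprev <- s[2] + (k - 1L) * cum$direction
      cand <- (r - 1L):(r + 1L)
      cand <- cand[cand >= 1L & cand <= m]
      r <- cand[which.min(C[cand, jprev])]
      rows[k] <- r
    }
  }
  cols <- seq(s[2], j, by = if (len > 1L) cum$direction else 1L)[seq_len(len)]
  pts <- cbind(row = rows, col = cols)
  if (cum$axis == "row") pts <- cbind(row = pts[, 2], col = pts[, 1])
  structure(list(points = pts, axis = cum$axis, direction = cum$direction,
                 total_cost = total),
            class = "ur_traced_path")
}

#' Check 3-connectivity of a traced path
#'
#' Consecutive points must advance exactly one pixel along the tracing axis
#' and move at most one pixel on the other axis.
#'
#' @param path `ur_traced_path` (or a points matrix plus `axis`).
#' @param axis tracing axis if `path` is a bare matrix.
#' @return logical scalar.
#' @export
is_three_connected <- function(path, axis = NULL) {
  pts <- if (inherits(path, "ur_traced_path")) path$points else as.matrix(path)
  if (is.null(axis)) axis <- path$axis
  if (nrow(pts) < 2L) return(TRUE)
  d <- diff(pts)
  along <- if (axis == "col") d[, 2] else d[, 1]
  across <- if (axis == "col") d[, 1] else d[, 2]
  all(abs(along) == 1L) && length(unique(sign(along))) == 1L && all(abs(across) <= 1L)
}

#' Trace one diaphysis edge through chained DP windows
#'
#' Starting from a seed point, `window_w`-column sub-segments are traced
#' repeatedly: each window's DP endpoint (minimum of its last column) becomes
#' the seed of the next window, until `stop_col` is reached (column 1 toward
#' the proximal edge, `x0` toward the distal end). With `window_w` at least
#' the full span this reduces to a single DP trace.
#'
#' @param I1 vertical cost map.
#' @param seed `(row, col)` seed point.
#' @param direction -1 (toward column 1) or +1 (toward `stop_col`).
#' @param window_w sub-segment width in columns.
#' @param stop_col final column.
#' @return `ur_traced_path` with points ordered from the seed outward.
#' @export
trace_diaphysis_edge <- function(I1, seed, direction, window_w = 64L, stop_col) {
  cur <- as.integer(seed)
  pts <- matrix(cur, 1L, 2L)
  while (cur[2] != stop_col) {
    target <- if (direction > 0) min(cur[2] + window_w, stop_col)
              else max(cur[2] - window_w, stop_col)
    seg <- backtrack_path(cumulative_cost(I1, cur, "col", direction, target))
    pts <- rbind(pts, seg$points[-1L, , drop = FALSE])
    cur <- as.integer(seg$points[nrow(seg$points), ])
  }
  colnames(pts) <- c("row", "col")
  structure(list(points = pts, axis = "col", direction = direction,
                 total_cost = sum(I1[pts])),
            class = "ur_traced_path")
}

#' Trace a wrist-joint segment between two diaphysis endpoints
#'
#' DP along rows (top to bottom) in the horizontal cost map, restricted to the
#' column band `x0 +/- n/10`, seeded only at `from_pt` and backtracked from
#' `to_pt` (endpoint-constrained), which guarantees the contour closes. If an
#' endpoint lies outside the band the band is widened to include it with a
#' warning.
#'
#' @param I2 horizontal cost map.
#' @param from_pt,to_pt distal endpoints of a bone's upper and lower diaphysis
#'   paths; `from_pt[1] < to_pt[1]`.
#' @param x0 distal-end column (standardized frame).
#' @param n width of the standardized image (defaults to `ncol(I2)`).
#' @return `ur_traced_path` (axis `"row"`), points from `from_pt` to `to_pt`.
#' @export
trace_joint_segment <- function(I2, from_pt, to_pt, x0, n = ncol(I2)) {
  from_pt <- as.integer(from_pt); to_pt <- as.integer(to_pt)
  if (from_pt[1] >= to_pt[1])
    stop("trace_joint_segment: from_pt must lie above to_pt")
  half <- floor(n / 10)
  c_lo <- x0 - half; c_hi <- x0 + half
  if (from_pt[2] < c_lo || from_pt[2] > c_hi ||
      to_pt[2] < c_lo || to_pt[2] > c_hi) {
    warning("trace_joint_segment: endpoint outside the x0 +/- n/10 band; widening band")
    c_lo <- min(c_lo, from_pt[2], to_pt[2])
    c_hi <- max(c_hi, from_pt[2], to_pt[2])
  }
  c_lo <- max(1L, c_lo); c_hi <- min(ncol(I2), c_hi)
  sub <- I2[, c_lo:c_hi, drop = FALSE]
  off <- c_lo - 1L
  cum <- cumulative_cost(sub, c(from_pt[1], from_pt[2] - off), "row", 1L,
                         stop = to_pt[1])
  path <- backtrack_path(cum, endpoint = c(to_pt[1], to_pt[2] - off))
  path$points[, 2] <- path$points[, 2] + off
  path$total_cost <- sum(I2[path$points])
  path
}

# Last point of a traced path.
path_end <- function(path) path$points[nrow(path$points), ]

#' Assemble closed bone contours from traced paths
#'
#' Per bone, the upper diaphysis path (left to right), the joint path (top to
#' bottom) and the reversed lower diaphysis path are concatenated, junction
#' vertices deduplicated, and the contour is closed with a straight vertical
#' segment at the leftmost traced column. All vertices are then mapped through
#' the inverse preprocessing transform into original-image coordinates and
#' rasterized to binary masks.
#'
#' @param paths nested list `list(bone1 = list(upper, lower, joint), bone2 =
#'   ...)` of `ur_traced_path` objects in the standardized frame.
#' @param transform `transform` element of the `ur_preprocessed` object.
#' @return object of class `ur_contours`: closed polygons `bone1`, `bone2`
#'   (original coordinates, first vertex repeated last), `masks`, and the
#'   constituent `components`.
#' @export
assemble_contours <- function(paths, transform) {
  orig_dim <- transform$dims$orig
  build_one <- function(b, label) {
    up <- b$upper$points; lo <- b$lower$points; jt <- b$joint$points
    shared <- intersect(up[, 2], lo[, 2])
    if (length(shared)) {
      ur <- up[match(shared, up[, 2]), 1]
      lr <- lo[match(shared, lo[, 2]), 1]
      bad <- which(ur >= lr)
      if (length(bad))
        stop_urseg(sprintf(
          "assemble_contours: %s upper and lower paths cross at column %d",
          label, shared[bad[1]]), "urseg_trace_error")
    }
    lo_rev <- lo[nrow(lo):1, , drop = FALSE]
    poly <- rbind(up, jt[-1L, , drop = FALSE], lo_rev[-1L, , drop = FALSE])
    # straight proximal closure at the leftmost traced column
    r_from <- lo[1, 1]; r_to <- up[1, 1]; c_close <- up[1, 2]
    if (abs(r_from - r_to) > 1L) {
      rows <- seq(r_from - 1L, r_to + 1L, by = -1L)
      poly <- rbind(poly, cbind(row = rows, col = rep(c_close, length(rows))))
    }
    poly_orig <- std_to_orig(poly, transform)
    poly_orig <- rbind(poly_orig, poly_orig[1L, ])
    list(poly = poly_orig, mask = fill_polygon(poly_orig, orig_dim))
  }
  b1 <- build_one(paths$bone1, "bone1")
  b2 <- build_one(paths$bone2, "bone2")
  if (any(b1$mask & b2$mask))
    warning("assemble_contours: bone interiors overlap after rasterization")
  structure(list(bone1 = b1$poly, bone2 = b2$poly,
                 masks = list(bone1 = b1$mask, bone2 = b2$mask),
                 components = paths),
            class = "ur_contours")
}

#' @export
print.ur_contours <- function(x, ...) {
  cat(sprintf("UR contours: bone1 %d vertices (area %d px), bone2 %d vertices (area %d px)\n",
              nrow(x$bone1), sum(x$masks$bone1), nrow(x$bone2), sum(x$masks$bone2)))
  invisible(x)
}

#' Segment the ulna and radius in a forearm radiograph
#'
#' Full pipeline: [preprocess()], [locate_distal_end()],
#' [detect_seed_points()], [build_cost_maps()], DP tracing of the four
#' diaphysis edges (each seed traced leftward to column 1 and rightward to
#' `x0`), endpoint-constrained tracing of the two wrist-joint segments in the
#' `x0 +/- n/10` band, and contour assembly. Fully deterministic.
#'
#' @param image raw radiograph matrix.
#' @param config [preprocess_config()].
#' @param lambda1,lambda2 cost-map weights, see [build_cost_maps()].
#' @param window_w diaphysis DP window width (columns, standardized frame).
#' @return `ur_contours` object with attributes `seed_set` and `preprocessed`.
#' @export
segment_image <- function(image, config = preprocess_config(),
                          lambda1 = 0.3, lambda2 = 0.7, window_w = 64L) {
  pre <- preprocess(image, config)
  de <- locate_distal_end(pre$mask)
  ss <- detect_seed_points(pre, de$x0, de$p_max)
  cm <- build_cost_maps(pre$pixels, lambda1, lambda2)
  x0 <- de$x0; n <- ncol(pre$pixels)

  trace_full_edge <- function(seed) {
    left <- trace_diaphysis_edge(cm$I1, seed, -1L, window_w, 1L)
    right <- trace_diaphysis_edge(cm$I1, seed, 1L, window_w, x0)
    pts <- rbind(left$points[nrow(left$points):1, , drop = FALSE],
                 right$points[-1L, , drop = FALSE])
    structure(list(points = pts, axis = "col", direction = 1L,
                   total_cost = sum(cm$I1[pts])),
              class = "ur_traced_path")
  }
  wrap_trace <- function(expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "urseg_error")) stop(e)
      stop_urseg(paste0("segment_image[trace]: ", conditionMessage(e)),
                 "urseg_trace_error")
    })
  }
  paths <- wrap_trace({
    edges <- lapply(seq_len(4L), function(i) trace_full_edge(ss$seeds[i, ]))
    joint1 <- trace_joint_segment(cm$I2, path_end(edges[[1]]), path_end(edges[[2]]), x0, n)
    joint2 <- trace_joint_segment(cm$I2, path_end(edges[[3]]), path_end(edges[[4]]), x0, n)
    list(bone1 = list(upper = edges[[1]], lower = edges[[2]], joint = joint1),
         bone2 = list(upper = edges[[3]], lower = edges[[4]], joint = joint2))
  })
  out <- assemble_contours(paths, pre$transform)
  attr(out, "seed_set") <- ss
  attr(out, "preprocessed") <- pre
  out
}
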