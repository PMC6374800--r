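# Low-level raster operations shared across the pipeline.
#
# Conventions: images are base R numeric matrices indexed [row, col], 1-based,
# origin at the top-left, intensities in [0, 1]. Binary rasters are logical
# matrices of the same shape.

#' @useDynLib urseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# y[r, c] = x[r + dr, c + dc] with symmetric (reflected) or zero padding.
neighbor_mat <- function(x, dr, dc, pad = c("reflect", "zero", "clamp")) {
  pad <- match.arg(pad)
  m <- nrow(x); n <- ncol(x)
  ri <- seq_len(m) + dr
  ci <- seq_len(n) + dc
  if (pad == "reflect") {
    ri <- ifelse(ri < 1L, 1L - ri, ifelse(ri > m, 2L * m + 1L - ri, ri))
    ci <- ifelse(ci < 1L, 1L - ci, ifelse(ci > n, 2L * n + 1L - ci, ci))
    x[ri, ci, drop = FALSE]
  } else if (pad == "clamp") {
    ri <- pmin(pmax(ri, 1L), m)
    ci <- pmin(pmax(ci, 1L), n)
    x[ri, ci, drop = FALSE]
  } else {
    y <- matrix(0, m, n)
    rok <- ri >= 1L & ri <= m
    cok <- ci >= 1L & ci <= n
    y[rok, cok] <- x[ri[rok], ci[cok], drop = FALSE]
    y
  }
}

#' Sobel gradients
#'
#' 3x3 Sobel operators with reflected-boundary padding. `sobel_x()` is the
#' horizontal gradient (differences across columns, responds to vertical
#' edges); `sobel_y()` is the vertical gradient (differences across rows,
#' responds to horizontal edges such as the bone diaphysis contours).
#'
#' @param img numeric matrix.
#' @return numeric matrix of signed gradient responses.
#' @export
sobel_x <- function(img) {
  d <- neighbor_mat(img, 0L, 1L) - neighbor_mat(img, 0L, -1L)
  neighbor_mat(d, -1L, 0L) + 2 * d + neighbor_mat(d, 1L, 0L)
}

#' @rdname sobel_x
#' @export
sobel_y <- function(img) {
  d <- neighbor_mat(img, 1L, 0L) - neighbor_mat(img, -1L, 0L)
  neighbor_mat(d, 0L, -1L) + 2 * d + neighbor_mat(d, 0L, 1L)
}

# Separable Gaussian smoothing, kernel truncated at 3 sigma.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq(-rad, rad)) out <- out + k[i + rad + 1L] * neighbor_mat(img, i, 0L)
  out2 <- matrix(0, nrow(img), ncol(img))
  for (j in seq(-rad, rad)) out2 <- out2 + k[j + rad + 1L] * neighbor_mat(out, 0L, j)
  out2
}

#' Otsu global threshold
#'
#' Classic maximum between-class-variance threshold over a fixed-bin histogram
#' of the supplied intensities. Returns the threshold value; foreground is
#' `img >= otsu_threshold(img)`.
#'
#' @param v numeric vector or matrix of intensities in \[0, 1\].
#' @param nbins number of histogram bins.
#' @return scalar threshold in \[0, 1\].
#' @export
otsu_threshold <- function(v, nbins = 256L) {
  v <- as.numeric(v)
  v <- v[is.finite(v)]
  if (!length(v)) stop("otsu_threshold: no finite values")
  edges <- seq(0, 1, length.out = nbins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- (mu_t * omega - mu)^2 / ifelse(denom > 0, denom, NA_real_)
  k <- which.max(ifelse(is.na(sigma_b), -Inf, sigma_b))
  edges[k + 1L]
}

#' Connected-component labeling
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  cc_label_cpp(mask, as.integer(connectivity))
}

# Largest connected component of a binary mask (8-connectivity).
largest_component <- function(mask) {
  lab <- label_components(mask, 8L)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

#' Binary dilation with a disk structuring element
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels.
#' @return logical matrix.
#' @export
dilate_disk <- function(mask, radius) {
  if (radius <= 0) return(mask)
  r <- as.integer(floor(radius))
  out <- mask
  for (dr in seq(-r, r)) for (dc in seq(-r, r)) {
    if (dr * dr + dc * dc > radius * radius || (dr == 0L && dc == 0L)) next
    out <- out | neighbor_mat(mask, dr, dc, pad = "zero")
  }
  out
}

# Histogram equalization restricted to mask pixels (256 bins over [0,1]).
# Pixels outside the mask are untouched. A single occupied bin maps to itself.
hist_equalize_masked <- function(img, mask, nbins = 256L) {
  v <- img[mask]
  if (!length(v)) return(img)
  edges <- seq(0, 1, length.out = nbins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  h <- tabulate(bin, nbins)
  cdf <- cumsum(h) / sum(h)
  occ <- which(h > 0L)
  cdf_min <- cdf[occ[1L]]
  if (cdf_min >= 1) return(img)  # single gray level: equalization is identity
  img[mask] <- (cdf[bin] - cdf_min) / (1 - cdf_min)
  img
}

#' Bilinear resize
#'
#' Pixel-center-aligned bilinear interpolation, as used for the downsampling
#' preprocessing stage. Output pixel i samples source position
#' `(i - 0.5) * size_in / size_out + 0.5` (1-based centers), clamped to the
#' image.
#'
#' @param img numeric matrix.
#' @param m2,n2 output dimensions.
#' @return `m2 x n2` numeric matrix.
#' @export
resize_bilinear <- function(img, m2, n2) {
  m <- nrow(img); n <- ncol(img)
  if (m2 == m && n2 == n) return(img)
  rs <- pmin(pmax((seq_len(m2) - 0.5) * (m / m2) + 0.5, 1), m)
  cs <- pmin(pmax((seq_len(n2) - 0.5) * (n / n2) + 0.5, 1), n)
  r0 <- pmin(pmax(floor(rs), 1), max(m - 1, 1))
  c0 <- pmin(pmax(floor(cs), 1), max(n - 1, 1))
  fr <- rs - r0
  fc <- cs - c0
  r1 <- pmin(r0 + 1, m)
  c1 <- pmin(c0 + 1, n)
  tmp <- img[r0, , drop = FALSE] * (1 - fr) + img[r1, , drop = FALSE] * fr
  a <- tmp[, c0, drop = FALSE]
  b <- tmp[, c1, drop = FALSE]
  sweep(a, 2, 1 - fc, "*") + sweep(b, 2, fc, "*")
}

# Rotate a matrix by k*90 degrees clockwise.
rot90cw <- function(x) t(x[nrow(x):1, , drop = FALSE])
rot_mat <- function(x, deg) {
  deg <- deg %% 360
  if (deg == 0) return(x)
  for (i in seq_len(deg / 90)) x <- rot90cw(x)
  x
}

# Map 1-based (row, col) points through a k*90-degree clockwise rotation of an
# image whose PRE-rotation dimensions are dims = c(m, n). Forward direction:
# point coordinates in the rotated frame.
rotate_points_cw <- function(pts, deg, dims) {
  deg <- deg %% 360
  pts <- as.matrix(pts)
  m <- dims[1]; n <- dims[2]
  if (deg == 0) return(pts)
  r <- pts[, 1]; c <- pts[, 2]
  if (deg == 90) {
    out <- cbind(c, m + 1 - r)
  } else if (deg == 180) {
    out <- cbind(m + 1 - r, n + 1 - c)
  } else if (deg == 270) {
    out <- cbind(n + 1 - c, r)
  } else stop("rotation must be a multiple of 90")
  colnames(out) <- c("row", "col")
  out
}

# Inverse of rotate_points_cw: rotated-frame points -> pre-rotation frame.
unrotate_points_cw <- function(pts, deg, dims) {
  deg <- deg %% 360
  if (deg == 0) return(as.matrix(pts))
  rotate_points_cw(pts, 360 - deg, dims = if (deg %in% c(90, 270)) rev(dims) else dims)
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and hysteresis thresholding. Thresholds are
#' scale-free: `high` is the `high_quantile` quantile of the nonzero gradient
#' magnitudes and `low = low_fraction * high`.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param sigma Gaussian pre-smoothing standard deviation (pixels).
#' @param high_quantile quantile of nonzero gradient magnitudes for the strong
#'   threshold.
#' @param low_fraction weak threshold as a fraction of the strong threshold.
#' @return logical edge mask.
#' @export
canny_edges <- function(img, sigma = 1.4, high_quantile = 0.9, low_fraction = 0.4) {
  sm <- gaussian_blur(img, sigma)
  gx <- sobel_x(sm)
  gy <- sobel_y(sm)
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  bin <- findInterval(ang, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)) %% 4L
  # neighbor offsets along the gradient direction for each bin
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(img), ncol(img))
  for (b in 0:3) {
    o <- offs[[b + 1L]]
    n1 <- neighbor_mat(mag, o[1], o[2], pad = "zero")
    n2 <- neighbor_mat(mag, -o[1], -o[2], pad = "zero")
    keep <- keep | (bin == b & mag >= n1 & mag > n2)
  }
  nz <- mag[mag > 0]
  high <- stats::quantile(nz, high_quantile, names = FALSE)
  low <- low_fraction * high
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  if (!any(strong)) return(strong)
  lab <- label_components(weak, 8L)
  good <- unique(lab[strong])
  weak & matrix(lab %in% good, nrow(lab), ncol(lab))
}

# --- 1-D profile utilities -------------------------------------------------

# Centered moving average; the window shrinks near the ends.
moving_average <- function(v, width = 7L) {
  half <- width %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Local maxima of a profile with prominences (scipy-style): for each strict
# local maximum, walk out left/right to the nearest higher value; the
# prominence is peak height minus the higher of the two interval minima.
find_peaks <- function(v) {
  n <- length(v)
  if (n < 3L) return(data.frame(idx = integer(), height = numeric(), prominence = numeric()))
  idx <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
  # drop plateau repeats: keep the first index of any flat run
  if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) > 1L | v[idx[-1L]] != v[idx[-length(idx)]])]
  prom <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    j <- i - 1L; lmin <- v[i]
    while (j >= 1L && v[j] <= v[i]) { lmin <- min(lmin, v[j]); j <- j - 1L }
    if (j < 1L) lmin <- min(v[1:i])
    j <- i + 1L; rmin <- v[i]
    while (j <= n && v[j] <= v[i]) { rmin <- min(rmin, v[j]); j <- j + 1L }
    if (j > n) rmin <- min(v[i:n])
    prom[k] <- v[i] - max(lmin, rmin)
  }
  data.frame(idx = idx, height = v[idx], prominence = prom)
}

# Top-k peaks by prominence subject to a minimum index separation; ties broken
# by smaller index. Returned sorted by index.
select_peaks <- function(v, k, min_distance = 1L) {
  pk <- find_peaks(v)
  if (!nrow(pk)) return(integer())
  pk <- pk[order(-pk$prominence, pk$idx), , drop = FALSE]
  chosen <- integer()
  for (i in seq_len(nrow(pk))) {
    if (!length(chosen) || all(abs(pk$idx[i] - chosen) >= min_distance)) {
      chosen <- c(chosen, pk$idx[i])
      if (length(chosen) >= k) break
    }
  }
  sort(chosen)
}

# --- polygon utilities -----------------------------------------------------

# Densify a polyline to unit steps and round to pixel coordinates; returns the
# ordered unique pixel chain (8-connected if the input steps are <= 1 px).
polyline_pixels <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2L) return(round(pts))
  out <- vector("list", nrow(pts) - 1L)
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    ns <- max(1L, ceiling(max(abs(b - a))))
    t <- seq(0, 1, length.out = ns + 1L)
    seg <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    out[[i]] <- if (i > 1L) seg[-1L, , drop = FALSE] else seg
  }
  px <- round(do.call(rbind, out))
  keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
  px[keep, , drop = FALSE]
}

#' Rasterize a closed polygon to a binary mask
#'
#' Even-odd scanline fill with boundary pixels included: a pixel is foreground
#' if its center lies inside the polygon under the even-odd rule or if it lies
#' on the (unit-step densified, rounded) polygon boundary.
#'
#' @param poly numeric matrix of (row, col) vertices; closed automatically.
#' @param dim output dimensions `c(m, n)`.
#' @return logical matrix.
#' @export
fill_polygon <- function(poly, dim) {
  poly <- as.matrix(poly)
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  m <- dim[1]; n <- dim[2]
  out <- matrix(FALSE, m, n)
  r1 <- poly[-nrow(poly), 1]; c1 <- poly[-nrow(poly), 2]
  r2 <- poly[-1, 1]; c2 <- poly[-1, 2]
  nonh <- r1 != r2
  r1 <- r1[nonh]; c1 <- c1[nonh]; r2 <- r2[nonh]; c2 <- c2[nonh]
  rlo <- pmin(r1, r2); rhi <- pmax(r1, r2)
  ymin <- max(1L, floor(min(poly[, 1])))
  ymax <- min(m, ceiling(max(poly[, 1])))
  for (y in ymin:ymax) {
    hit <- rlo <= y & y < rhi
    if (!any(hit)) next
    xs <- sort(c1[hit] + (y - r1[hit]) * (c2[hit] - c1[hit]) / (r2[hit] - r1[hit]))
    for (i in seq(1L, length(xs) - 1L, by = 2L)) {
      a <- ceiling(xs[i] - 1e-7); b <- floor(xs[i + 1L] + 1e-7)
      a <- max(1L, a); b <- min(n, b)
      if (a <= b) out[y, a:b] <- TRUE
    }
  }
  bp <- polyline_pixels(poly)
  bp <- bp[bp[, 1] >= 1 & bp[, 1] <= m & bp[, 2] >= 1 & bp[, 2] <= n, , drop = FALSE]
  out[cbind(bp[, 1], bp[, 2])] <- TRUE
  out
}

# Minimum Euclidean distance from every row of P to the point set Q, computed
# brute force in memory-bounded chunks.
min_dists <- function(P, Q, chunk = 512L) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  np <- nrow(P)
  out <- numeric(np)
  qr <- Q[, 1]; qc <- Q[, 2]
  for (s in seq(1L, np, by = chunk)) {
    e <- min(s + chunk - 1L, np)
    dr <- outer(P[s:e, 1], qr, "-")
    dc <- outer(P[s:e, 2], qc, "-")
    out[s:e] <- sqrt(apply(dr * dr + dc * dc, 1, min))
  }
  out
}
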