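# Synthetic forearm-radiograph phantom with exact ground truth.
#
# The phantom emulates the image properties the pipeline must cope with: two
# bright tapered bone bands inside a soft-tissue band, a soft-tissue neck at
# the wrist followed by a widening hand, a smooth multiplicative background
# nonuniformity, dark collimation borders, additive Gaussian noise, variable
# orientation and exposure. Geometry is generated analytically, so bone
# masks, contours, edge rows and the wrist-neck column are known exactly.

#' Phantom parameters
#'
#' All geometric defaults are sized for a 704 x 704 canvas (about a quarter of
#' the clinical ~2816 px resolution) and scale linearly with `size`. The
#' canonical frame is left-to-right with the wrist at the right; `orientation`
#' rotates the final image (and all stored truth) by a multiple of 90 degrees.
#'
#' @param size square canvas side in pixels.
#' @param seed RNG seed; the phantom is bit-reproducible given its parameters.
#' @param orientation `"lr"`, `"rl"`, `"up"` or `"down"` (direction the wrist
#'   points).
#' @param centerline_row forearm axis row (canonical frame).
#' @param soft_halfheight soft-tissue band half-height away from the wrist.
#' @param neck_depth,neck_width Gaussian dip of the soft-tissue half-height at
#'   the wrist neck.
#' @param hand_amp,hand_offset,hand_width logistic widening of the hand beyond
#'   the wrist.
#' @param wrist_col nominal wrist-neck column (canonical frame).
#' @param bone_offset distance of each bone centerline from the forearm axis.
#' @param bone_halfwidth length-2 vector of diaphysis half-widths.
#' @param taper fractional widening of the half-width from proximal to distal.
#' @param flare_amp,flare_back,flare_width Gaussian widening (metaphyseal
#'   flare) centered `flare_back` columns before the bone end.
#' @param cap length of the elliptical distal end cap.
#' @param intensity_bg,intensity_soft,intensity_bone nominal intensity levels,
#'   ordered background < soft tissue < bone.
#' @param bg_grad_amp amplitude of the smooth multiplicative background field.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param exposure_scale,exposure_offset affine exposure model applied to the
#'   exposed region (`0.6 / 0.25` emulates a low-dose, low-contrast image).
#' @param collim_width width of the dark collimation border.
#' @param marker if `TRUE`, a small bright disk is placed in the background
#'   far from the forearm (a disturbing object).
#' @return list of class `ur_phantom_params`.
#' @export
phantom_params <- function(size = 704L,
                           seed = 1L,
                           orientation = c("lr", "rl", "up", "down"),
                           centerline_row = 0.5 * size,
                           soft_halfheight = 90 / 704 * size,
                           neck_depth = 22 / 704 * size,
                           neck_width = 40 / 704 * size,
                           hand_amp = 55 / 704 * size,
                           hand_offset = 60 / 704 * size,
                           hand_width = 25 / 704 * size,
                           wrist_col = 0.74 * size,
                           bone_offset = 34 / 704 * size,
                           bone_halfwidth = c(18, 17) / 704 * size,
                           taper = 0.10,
                           flare_amp = 4 / 704 * size,
                           flare_back = 20 / 704 * size,
                           flare_width = 25 / 704 * size,
                           cap = 12 / 704 * size,
                           intensity_bg = 0.08,
                           intensity_soft = 0.42,
                           intensity_bone = 0.78,
                           bg_grad_amp = 0.12,
                           noise_sigma = 0.03,
                           exposure_scale = 1,
                           exposure_offset = 0,
                           collim_width = 24 / 704 * size,
                           marker = FALSE) {
  orientation <- match.arg(orientation)
  if (!(intensity_bg < intensity_soft && intensity_soft < intensity_bone))
    stop("phantom_params: intensities must be ordered background < soft tissue < bone")
  p <- list(size = as.integer(size), seed = as.integer(seed),
            orientation = orientation,
            centerline_row = centerline_row, soft_halfheight = soft_halfheight,
            neck_depth = neck_depth, neck_width = neck_width,
            hand_amp = hand_amp, hand_offset = hand_offset,
            hand_width = hand_width, wrist_col = wrist_col,
            bone_offset = bone_offset, bone_halfwidth = bone_halfwidth,
            taper = taper, flare_amp = flare_amp, flare_back = flare_back,
            flare_width = flare_width, cap = cap,
            intensity_bg = intensity_bg, intensity_soft = intensity_soft,
            intensity_bone = intensity_bone, bg_grad_amp = bg_grad_amp,
            noise_sigma = noise_sigma, exposure_scale = exposure_scale,
            exposure_offset = exposure_offset,
            collim_width = collim_width, marker = isTRUE(marker))
  class(p) <- "ur_phantom_params"
  p
}

# Soft-tissue half-height profile over canonical columns.
soft_halfheight_profile <- function(p, xs) {
  p$soft_halfheight -
    p$neck_depth * exp(-((xs - p$wrist_col) / p$neck_width)^2) +
    p$hand_amp / (1 + exp(-(xs - p$wrist_col - p$hand_offset) / p$hand_width))
}

# Bone half-width profile (0 beyond the distal end) for bone i.
bone_halfwidth_profile <- function(p, xs, i) {
  xe <- p$wrist_col
  hw <- p$bone_halfwidth[i] * (1 + p$taper * pmin(xs, xe) / xe) +
    p$flare_amp * exp(-((xs - (xe - p$flare_back)) / p$flare_width)^2)
  capz <- xs > (xe - p$cap)
  hw[capz] <- hw[capz] * sqrt(pmax(0, 1 - ((xs[capz] - (xe - p$cap)) / p$cap)^2))
  hw[xs > xe] <- 0
  hw
}

#' Generate a synthetic forearm phantom
#'
#' Deterministic for a fixed parameter set (including `seed`). Bone contours
#' are built from the analytic geometry, rasterized with [fill_polygon()] to
#' give masks that are exactly consistent with the contours, and the image is
#' rendered from the masks, so thresholding a noiseless phantom midway between
#' the soft-tissue and bone levels recovers the bone masks exactly.
#'
#' @param params [phantom_params()] object.
#' @return object of class `ur_phantom`: `image`, `bone_masks` (list, bone1 =
#'   upper bone in the canonical frame), `bone_contours` (closed polygons),
#'   `soft_mask` (all in the final orientation's coordinates), plus canonical
#'   truth `edge_rows`, `bone_cols`, `wrist_column`, `p_max_column`,
#'   `rotation_deg`, `regime` (set by [generate_suite()]) and `params`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  p <- params
  set.seed(p$seed)
  size <- p$size
  cw <- as.integer(round(p$collim_width))
  x_lo <- cw + 1L; x_hi <- size - cw
  xs <- seq_len(size)
  H <- soft_halfheight_profile(p, xs)
  H[xs < x_lo | xs > x_hi] <- 0
  # collimation follows the anatomy: rows far from the forearm are collimated,
  # so the valid region is rectangular along the forearm axis
  maxH <- max(H)
  r_lo <- max(cw + 1L, as.integer(floor(p$centerline_row - maxH - 30 / 704 * size)))
  r_hi <- min(size - cw, as.integer(ceiling(p$centerline_row + maxH + 30 / 704 * size)))

  rows <- matrix(seq_len(size), size, size)
  colsm <- matrix(xs, size, size, byrow = TRUE)
  Hm <- matrix(H, size, size, byrow = TRUE)
  soft <- Hm > 0 & abs(rows - p$centerline_row) <= Hm & rows >= r_lo & rows <= r_hi

  cls <- c(p$centerline_row - p$bone_offset, p$centerline_row + p$bone_offset)
  contours <- list(); masks <- list(); edge_rows <- list(); bone_cols <- list()
  for (i in 1:2) {
    hw <- bone_halfwidth_profile(p, xs, i)
    ok <- which(hw >= 0.5 & xs >= x_lo)
    xcols <- ok
    ru <- round(cls[i] - hw[xcols])
    rl <- round(cls[i] + hw[xcols])
    poly <- rbind(cbind(ru, xcols), cbind(rev(rl), rev(xcols)))
    poly <- rbind(poly, poly[1, ])
    colnames(poly) <- c("row", "col")
    mask <- fill_polygon(poly, c(size, size))
    if (any(mask & !soft))
      stop("generate_phantom: geometrically infeasible parameters (bone outside soft tissue)")
    contours[[i]] <- poly
    masks[[i]] <- mask
    er <- rep(NA_real_, size); el <- rep(NA_real_, size)
    er[xcols] <- ru; el[xcols] <- rl
    edge_rows[[i]] <- list(upper = er, lower = el)
    bone_cols[[i]] <- range(xcols)
  }
  if (any(masks[[1]] & masks[[2]]))
    stop("generate_phantom: geometrically infeasible parameters (bones overlap)")

  img <- matrix(p$intensity_bg, size, size)
  img[soft] <- p$intensity_soft
  img[masks[[1]] | masks[[2]]] <- p$intensity_bone
  if (p$marker) {
    mc <- c(p$centerline_row - p$soft_halfheight - 45 / 704 * size,
            x_lo + 40 / 704 * size)
    mrad <- 0.012 * size
    blob <- (rows - mc[1])^2 + (colsm - mc[2])^2 <= mrad^2
    img[blob] <- p$intensity_bone
  }
  a1 <- stats::runif(1, -1, 1); a2 <- stats::runif(1, -1, 1)
  phase <- stats::runif(1, 0, 2 * pi)
  field <- 1 + p$bg_grad_amp * (a1 * (colsm / size - 0.5) +
                                  a2 * (rows / size - 0.5) +
                                  0.5 * sin(2 * pi * 0.7 * colsm / size + phase))
  img <- p$exposure_scale * img * field + p$exposure_offset
  if (p$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(size * size, 0, p$noise_sigma), size, size)
  # collimated border: almost no dose reaches the detector, so both the level
  # and the noise are far below the exposed region
  border <- rows < r_lo | rows > r_hi | colsm <= cw | colsm > size - cw
  img[border] <- 0.005 + stats::rnorm(sum(border), 0, 0.003)
  img <- pmin(pmax(img, 0), 1)

  Hvalid <- H[x_lo:x_hi]
  pm <- which.max(Hvalid)
  wc <- which.min(Hvalid[seq_len(pm)]) + x_lo - 1L
  pm <- pm + x_lo - 1L

  deg <- c(lr = 0L, rl = 180L, down = 90L, up = 270L)[[p$orientation]]
  out <- list(
    image = rot_mat(img, deg),
    bone_masks = lapply(masks, rot_mat, deg = deg),
    bone_contours = lapply(contours, function(cc)
      rotate_points_cw(cc, deg, c(size, size))),
    soft_mask = rot_mat(soft, deg),
    edge_rows = edge_rows,
    bone_cols = bone_cols,
    wrist_column = as.integer(wc),
    p_max_column = as.integer(pm),
    rotation_deg = deg,
    regime = "normal",
    params = p)
  class(out) <- "ur_phantom"
  out
}

#' @export
print.ur_phantom <- function(x, ...) {
  cat(sprintf("Forearm phantom %dx%d, orientation %s, wrist column %d (canonical), noise sigma %g\n",
              nrow(x$image), ncol(x$image), x$params$orientation,
              x$wrist_column, x$params$noise_sigma))
  invisible(x)
}

#' Map points between the phantom frame and the canonical frame
#'
#' The stored image, masks and contours live in the final orientation's
#' coordinates; `edge_rows`, `wrist_column` and `bone_cols` are canonical
#' (left-to-right). These helpers convert point matrices between the frames.
#'
#' @param pts numeric matrix of (row, col) points.
#' @param phantom `ur_phantom` object.
#' @return transformed points matrix.
#' @export
phantom_to_canonical <- function(pts, phantom) {
  unrotate_points_cw(pts, phantom$rotation_deg,
                     rep(phantom$params$size, 2L))
}

#' @rdname phantom_to_canonical
#' @export
canonical_to_phantom <- function(pts, phantom) {
  rotate_points_cw(pts, phantom$rotation_deg, rep(phantom$params$size, 2L))
}

#' Ground-truth bone edge rows at a canonical column
#'
#' @param phantom `ur_phantom`.
#' @param col canonical column index.
#' @return numeric vector (bone1 upper, bone1 lower, bone2 upper, bone2
#'   lower), `NA` where the bone does not reach the column.
#' @export
phantom_edges_at <- function(phantom, col) {
  col <- as.integer(round(col))
  c(phantom$edge_rows[[1]]$upper[col], phantom$edge_rows[[1]]$lower[col],
    phantom$edge_rows[[2]]$upper[col], phantom$edge_rows[[2]]$lower[col])
}

# Michelson contrast between bone and soft tissue, from the stored masks.
phantom_contrast <- function(phantom) {
  bone <- phantom$bone_masks[[1]] | phantom$bone_masks[[2]]
  mb <- mean(phantom$image[bone])
  ms <- mean(phantom$image[phantom$soft_mask & !bone])
  (mb - ms) / (mb + ms)
}

#' Generate a reproducible suite of phantoms
#'
#' Parameters are jittered over documented ranges; orientations cycle through
#' all four values and phantoms alternate between a normal-exposure regime
#' (noise sigma 0.03, full contrast) and a low-exposure regime (noise sigma
#' 0.08, exposure scale 0.6 with offset 0.25, i.e. reduced contrast),
#' emulating a mixed-dose clinical sample. Fully reproducible from
#' `master_seed`.
#'
#' @param n number of phantoms.
#' @param master_seed integer master seed.
#' @param size canvas side passed to [phantom_params()].
#' @return list of `ur_phantom` objects (element `regime` set per phantom).
#' @export
generate_suite <- function(n, master_seed = 1L, size = 704L) {
  stopifnot(n >= 1L)
  orientations <- c("lr", "rl", "up", "down")
  lapply(seq_len(n), function(i) {
    seed_i <- (as.numeric(master_seed) * 10007 + i * 7919) %% 2100000000
    set.seed(seed_i)
    s <- size / 704
    low <- i %% 2L == 0L
    pp <- phantom_params(
      size = size,
      seed = as.integer(seed_i),
      orientation = orientations[(i - 1L) %% 4L + 1L],
      centerline_row = 0.5 * size + stats::runif(1, -12, 12) * s,
      soft_halfheight = (90 + stats::runif(1, -8, 8)) * s,
      wrist_col = 0.74 * size + stats::runif(1, -25, 25) * s,
      bone_offset = (34 + stats::runif(1, -3, 3)) * s,
      bone_halfwidth = (c(18, 17) + stats::runif(2, -2, 2)) * s,
      taper = 0.10 + stats::runif(1, -0.04, 0.04),
      flare_amp = (4 + stats::runif(1, -1.5, 1.5)) * s,
      bg_grad_amp = stats::runif(1, 0.06, 0.16),
      noise_sigma = if (low) 0.08 else 0.03,
      exposure_scale = if (low) 0.6 else 1,
      exposure_offset = if (low) 0.25 else 0)
    ph <- generate_phantom(pp)
    ph$regime <- if (low) "low" else "normal"
    ph
  })
}
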