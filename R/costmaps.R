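# Cost maps for DP contour tracing. Two per-pixel cost images in [0, 1] are
# built so that bone edges have low cost: I1 from the vertical gradient (for
# the near-horizontal diaphysis edges) and I2 from the horizontal gradient
# (for the near-vertical wrist-joint edges), each blended with an inverted
# Canny edge mask:
#
#   I1 = lambda1 * f_Gy + (1 - lambda1) * f_c
#   I2 = lambda2 * f_Gx + (1 - lambda2) * f_c
#
# where f_G = 1 - |G| / max|G| is the scaled, inverted Sobel gradient and
# f_c is 0 on Canny edge pixels and 1 elsewhere.

# Set the outermost 1-px frame to the given value (discourages paths hugging
# the crop border, where padded gradients are unreliable).
set_frame <- function(x, value = 1) {
  x[1, ] <- value; x[nrow(x), ] <- value
  x[, 1] <- value; x[, ncol(x)] <- value
  x
}

#' Scaled inverted gradient cost
#'
#' `1 - |G| / max(|G|)` where `G` is the Sobel gradient along the requested
#' axis (absolute value, so both edge polarities cost equally). The strongest
#' edge pixels map to cost 0. For a constant image (`max |G| = 0`) the cost is
#' defined as all ones and a warning is emitted. The outermost 1-px frame is
#' set to 1.
#'
#' @param image standardized radiograph matrix.
#' @param axis `"y"` for the vertical gradient (horizontal edges), `"x"` for
#'   the horizontal gradient (vertical edges).
#' @return cost matrix in \[0, 1\].
#' @export
scaled_inverted_gradient <- function(image, axis = c("y", "x")) {
  axis <- match.arg(axis)
  g <- abs(if (axis == "y") sobel_y(image) else sobel_x(image))
  mx <- max(g)
  if (mx == 0) {
    warning("scaled_inverted_gradient: constant image, cost defined as 1 everywhere")
    return(set_frame(matrix(1, nrow(image), ncol(image))))
  }
  set_frame(1 - g / mx)
}

#' Canny edge cost
#'
#' 0 on Canny edge pixels, 1 elsewhere; outermost frame forced to 1.
#'
#' @param image standardized radiograph matrix.
#' @param ... passed to [canny_edges()].
#' @return cost matrix of 0/1 values (list with `cost` and the binary `edges`).
#' @export
canny_cost <- function(image, ...) {
  edges <- canny_edges(image, ...)
  list(cost = set_frame(1 - edges), edges = edges)
}

#' Build the cost-map pair
#'
#' @param image standardized radiograph matrix (e.g. `pre$pixels`).
#' @param lambda1 weight of the vertical-gradient term in I1 (default 0.3).
#' @param lambda2 weight of the horizontal-gradient term in I2 (default 0.7).
#' @param canny_sigma,canny_high_quantile,canny_low_fraction Canny parameters,
#'   see [canny_edges()].
#' @return object of class `ur_costmaps` with `I1`, `I2`, `lambda1`,
#'   `lambda2`, `canny_mask`, `Gy`, `Gx`.
#' @export
build_cost_maps <- function(image, lambda1 = 0.3, lambda2 = 0.7,
                            canny_sigma = 1.4, canny_high_quantile = 0.9,
                            canny_low_fraction = 0.4) {
  if (lambda1 < 0 || lambda1 > 1 || lambda2 < 0 || lambda2 > 1)
    stop("build_cost_maps: lambda weights must lie in [0, 1]")
  f_gy <- scaled_inverted_gradient(image, "y")
  f_gx <- scaled_inverted_gradient(image, "x")
  cc <- canny_cost(image, sigma = canny_sigma,
                   high_quantile = canny_high_quantile,
                   low_fraction = canny_low_fraction)
  structure(list(I1 = lambda1 * f_gy + (1 - lambda1) * cc$cost,
                 I2 = lambda2 * f_gx + (1 - lambda2) * cc$cost,
                 lambda1 = lambda1, lambda2 = lambda2,
                 canny_mask = cc$edges,
                 Gy = sobel_y(image), Gx = sobel_x(image)),
            class = "ur_costmaps")
}

#' @export
print.ur_costmaps <- function(x, ...) {
  cat(sprintf("Cost-map pair %dx%d (lambda1 = %g, lambda2 = %g, %d Canny edge px)\n",
              nrow(x$I1), ncol(x$I1), x$lambda1, x$lambda2, sum(x$canny_mask)))
  invisible(x)
}
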