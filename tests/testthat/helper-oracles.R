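# Independent oracles used to freeze expected values. These deliberately use
# naive loops / exhaustive enumeration, not the package's own code paths.

# Minimum total cost over ALL 3-connected paths that start at (seed_row, j0)
# and advance one column per step (direction dir) until stop column. Pure
# recursion over every branch.
enumerate_min_cost <- function(costmap, seed_row, j0, dir, stop) {
  m <- nrow(costmap)
  best <- Inf
  best_path <- NULL
  recurse <- function(r, j, acc, path) {
    acc <- acc + costmap[r, j]
    path <- c(path, r)
    if (j == stop) {
      if (acc < best) {
        best <<- acc
        best_path <<- path
      }
      return(invisible())
    }
    for (nr in (r - 1L):(r + 1L)) {
      if (nr >= 1L && nr <= m) recurse(nr, j + dir, acc, path)
    }
  }
  recurse(seed_row, j0, 0, integer())
  list(cost = best, rows = best_path)
}

# Brute-force mean absolute distance between two pixel sets (double loop).
brute_mad <- function(A, B) {
  one_way <- function(P, Q) {
    s <- 0
    for (i in seq_len(nrow(P))) {
      d <- Inf
      for (j in seq_len(nrow(Q))) {
        d <- min(d, sqrt(sum((P[i, ] - Q[j, ])^2)))
      }
      s <- s + d
    }
    s
  }
  (one_way(A, B) + one_way(B, A)) / (nrow(A) + nrow(B))
}

# Reference crop rule: maximal interval of profile > frac * max, expanded by
# floor(margin * length) per side (direct scan, no vectorized shortcuts).
oracle_valid_range <- function(prof, frac = 0.05, margin = 0.02) {
  th <- frac * max(prof)
  lo <- NA; hi <- NA
  for (i in seq_along(prof)) if (prof[i] > th) { lo <- i; break }
  for (i in rev(seq_along(prof))) if (prof[i] > th) { hi <- i; break }
  pad <- floor(margin * (hi - lo + 1))
  c(max(1, lo - pad), min(length(prof), hi + pad))
}

# Hand-applied 3x3 Sobel stencil with symmetric (reflected) padding.
oracle_sobel <- function(img, axis) {
  m <- nrow(img); n <- ncol(img)
  refl <- function(i, k) { if (i < 1) 1 - i else if (i > k) 2 * k + 1 - i else i }
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # column derivative
  ky <- t(kx)                                                 # row derivative
  k <- if (axis == "x") kx else ky
  out <- matrix(0, m, n)
  for (r in seq_len(m)) for (cc in seq_len(n)) {
    acc <- 0
    for (dr in -1:1) for (dc in -1:1) {
      acc <- acc + k[dr + 2, dc + 2] * img[refl(r + dr, m), refl(cc + dc, n)]
    }
    out[r, cc] <- acc
  }
  out
}

# Direct scan implementing the documented distal-end rule (smooth, restrict
# to [1, p_max], deepest interior dip, valley-run midpoint).
oracle_distal_end <- function(colsums, width = 7, tol = 1) {
  n <- length(colsums)
  prof <- numeric(n)
  half <- width %/% 2
  for (i in seq_len(n)) {
    w <- colsums[max(1, i - half):min(n, i + half)]
    prof[i] <- mean(w)
  }
  p_max <- which.max(prof)
  dips <- c()
  for (i in 2:(p_max - 1)) {
    lgt <- any(prof[1:(i - 1)] > prof[i])
    rgt <- any(prof[(i + 1):p_max] > prof[i])
    lle <- prof[i - 1] >= prof[i]
    rle <- prof[i + 1] >= prof[i]
    if (lgt && rgt && lle && rle && prof[i] > 0) dips <- c(dips, i)
  }
  if (!length(dips)) return(NULL)
  i <- dips[which.min(prof[dips])]
  l <- i; while (l > 1 && prof[l - 1] <= prof[i] + tol) l <- l - 1
  r <- i; while (r < p_max && prof[r + 1] <= prof[i] + tol) r <- r + 1
  list(x0 = (l + r) %/% 2, p_max = p_max)
}

# Identity preprocessing transform for assembling contours directly in a
# known frame.
identity_transform <- function(dim) {
  list(crop = c(1, 1, dim[1], dim[2]), rot = 0L, ratio = 1,
       dims = list(orig = dim, cropped = dim, rotated = dim, std = dim))
}

# A minimal ur_preprocessed stand-in for seed-detection tests.
fake_preprocessed <- function(pixels, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  structure(list(pixels = pixels, mask = mask,
                 transform = identity_transform(dim(pixels)),
                 provenance = list()),
            class = "ur_preprocessed")
}
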