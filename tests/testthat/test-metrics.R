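# Evaluation metrics.

square_poly <- function(r0, c0, side) {
  rbind(c(r0, c0), c(r0, c0 + side), c(r0 + side, c0 + side), c(r0 + side, c0),
        c(r0, c0))
}

# star-shaped simple polygon around a center
random_polygon <- function(center, rmin, rmax, k = 12) {
  ang <- sort(runif(k, 0, 2 * pi))
  rad <- runif(k, rmin, rmax)
  pts <- cbind(center[1] + rad * sin(ang), center[2] + rad * cos(ang))
  rbind(pts, pts[1, ])
}

test_that("confusion counts: identical, disjoint, shifted-block cases", {
  a <- matrix(FALSE, 10, 10); a[3:6, 3:6] <- TRUE
  cc <- confusion_counts(a, a)
  expect_equal(cc, list(TP = 16L, FP = 0L, FN = 0L))
  b <- matrix(FALSE, 10, 10); b[8:9, 8:9] <- TRUE
  cc2 <- confusion_counts(a, b)
  expect_equal(cc2, list(TP = 0L, FP = 4L, FN = 16L))
  shifted <- matrix(FALSE, 10, 10); shifted[3:6, 4:7] <- TRUE
  cc3 <- confusion_counts(a, shifted)
  expect_equal(cc3, list(TP = 12L, FP = 4L, FN = 4L))
  expect_error(confusion_counts(a, matrix(FALSE, 9, 10)))
})

test_that("DSC, Sens, FPR formulas", {
  perfect <- list(TP = 50L, FP = 0L, FN = 0L)
  expect_equal(dsc(perfect), 1)
  expect_equal(sens(perfect), 1)
  expect_equal(fpr(perfect), 0)
  expect_equal(dsc(list(TP = 6, FP = 2, FN = 2)), 12 / 16)
  expect_equal(sens(list(TP = 8, FP = 1, FN = 2)), 0.8)
  expect_equal(fpr(list(TP = 8, FP = 1, FN = 2)), 0.1)
  expect_error(dsc(list(TP = 0, FP = 3, FN = 0)), "undefined")
})

test_that("DSC is consistent with the harmonic mean of Sens and precision", {
  set.seed(44)
  for (i in 1:10) {
    gt <- matrix(runif(400) > 0.5, 20, 20)
    pred <- matrix(runif(400) > 0.4, 20, 20)
    cc <- confusion_counts(gt, pred)
    if (cc$TP == 0) next
    p <- cc$TP / (cc$TP + cc$FP)
    expect_equal(dsc(cc), 2 * sens(cc) * p / (sens(cc) + p), tolerance = 1e-12)
  }
})

test_that("MAD: zero on identity, exact for parallel segments, symmetric", {
  A <- cbind(rep(10, 20), 1:20)
  expect_equal(contour_mad(A, A, closed = FALSE, densify = FALSE), 0)
  B <- cbind(rep(15, 20), 1:20)
  expect_equal(contour_mad(A, B, closed = FALSE, densify = FALSE), 5)
  set.seed(9)
  P <- cbind(sample(1:40, 25), sample(1:40, 25))
  Q <- cbind(sample(1:40, 30, TRUE), sample(1:40, 30, TRUE))
  expect_equal(contour_mad(P, Q, closed = FALSE, densify = FALSE),
               contour_mad(Q, P, closed = FALSE, densify = FALSE), tolerance = 1e-12)
})

test_that("MAD agrees with the brute-force double loop within 1e-9", {
  set.seed(77)
  A <- unique(cbind(sample(1:200, 250, TRUE), sample(1:200, 250, TRUE)))
  B <- unique(cbind(sample(1:200, 250, TRUE), sample(1:200, 250, TRUE)))
  expect_equal(contour_mad(A, B, closed = FALSE, densify = FALSE), brute_mad(A, B),
               tolerance = 1e-9)
})

test_that("MSD: zero on identity, positive when ground truth is larger", {
  sq <- square_poly(10, 10, 10)
  expect_equal(contour_msd(sq, sq), 0)
  inner <- square_poly(12, 12, 6)
  m <- contour_msd(sq, inner)
  expect_gt(m, 0)                                   # ground truth larger
  expect_lte(abs(m), contour_mad(sq, inner))        # |MSD| <= MAD
  expect_equal(contour_msd(inner, sq), -m, tolerance = 1e-12)
})

test_that("MSD is antisymmetric on random polygon pairs", {
  set.seed(15)
  for (i in 1:5) {
    A <- random_polygon(c(40, 40), 10, 20)
    B <- random_polygon(c(42, 38), 8, 18)
    dimv <- c(80L, 80L)
    expect_equal(contour_msd(A, B, dimv), -contour_msd(B, A, dimv),
                 tolerance = 1e-9)
    expect_lte(abs(contour_msd(A, B, dimv)), contour_mad(A, B) + 1e-9)
  }
})

test_that("regional report: perfect prediction", {
  gt <- matrix(FALSE, 50, 120); gt[20:30, 11:100] <- TRUE
  ctr <- list(rbind(c(20, 11), c(20, 100), c(30, 100), c(30, 11), c(20, 11)))
  rep <- regional_report(gt, gt, ctr, ctr)
  expect_equal(rep$dsc, rep(1, 4))
  expect_equal(rep$mad, rep(0, 4))
  expect_equal(rep$msd, rep(0, 4))
  # the three bands tile the ground-truth extent exactly
  expect_equal(sum(rep$n_gt[2:4]), rep$n_gt[1])
})

test_that("regional report localizes a distal-only dilation", {
  gt_poly <- rbind(c(40, 11), c(40, 100), c(60, 100), c(60, 11), c(40, 11))
  # prediction dilated by 3 px in rows, only over the distal third (cols > 70)
  pred_poly <- rbind(c(40, 11), c(40, 70), c(37, 71), c(37, 100),
                     c(63, 100), c(63, 71), c(60, 70), c(60, 11), c(40, 11))
  dims <- c(90L, 120L)
  gt <- fill_polygon(gt_poly, dims)
  pred <- fill_polygon(pred_poly, dims)
  rep <- regional_report(gt, pred, list(gt_poly), list(pred_poly))
  expect_equal(rep$dsc[rep$region == "proximal"], 1)
  expect_lt(rep$dsc[rep$region == "distal"], 1)
  expect_lt(rep$msd[rep$region == "distal"], 0)     # prediction larger
  expect_equal(rep$sens[rep$region == "distal"], 1) # dilation never misses gt
})

test_that("regional report flags empty-ground-truth bands and errors sensibly", {
  gt <- matrix(FALSE, 40, 60); gt[10:20, 5:50] <- TRUE
  pred <- gt
  ctr <- list(rbind(c(10, 5), c(10, 50), c(20, 50), c(20, 5), c(10, 5)))
  expect_error(regional_report(gt, matrix(FALSE, 41, 60), ctr, ctr))
  expect_error(regional_report(matrix(FALSE, 40, 60), pred, ctr, ctr), "empty")
  expect_error(contour_mad(matrix(numeric(), 0, 2), ctr[[1]]))
})
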