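# Dynamic-programming path tracing and contour assembly.

test_that("cumulative cost: trivial maps", {
  z <- matrix(0, 5, 6)
  cum <- cumulative_cost(z, c(3, 1), "col", 1L, 6L)
  # zero cost everywhere reachable; unreachable cells hold Inf
  reach <- abs(outer(1:5, 1:6, function(r, j) r - 3)) <= outer(1:5, 1:6, function(r, j) j - 1)
  expect_true(all(cum$cum[reach] == 0))
  expect_true(all(is.infinite(cum$cum[!reach])))
  # single-slice: cumulative equals the cost map at the seed
  one <- matrix(runif(4), 4, 1)
  c1 <- cumulative_cost(one, c(2, 1), "col", 1L, 1L)
  expect_equal(c1$cum[2, 1], one[2, 1])
})

test_that("the 3x4 worked example matches exhaustive enumeration", {
  cmap <- rbind(c(0.1, 0.9, 0.9, 0.9),
                c(0.9, 0.1, 0.9, 0.1),
                c(0.9, 0.9, 0.1, 0.9))
  cum <- cumulative_cost(cmap, c(1, 1), "col", 1L, 4L)
  path <- backtrack_path(cum)
  orc <- enumerate_min_cost(cmap, 1L, 1L, 1L, 4L)
  expect_equal(path$total_cost, orc$cost, tolerance = 1e-12)
  expect_equal(orc$cost, 0.4, tolerance = 1e-12)
  expect_equal(path$points[, 1], orc$rows)
  expect_equal(path$points[, 1], c(1, 2, 3, 2))
})

test_that("backtracking ties resolve to the smallest row", {
  z <- matrix(0, 5, 5)
  path <- backtrack_path(cumulative_cost(z, c(3, 1), "col", 1L, 5L))
  # all reachable endpoints cost 0, so the endpoint is the topmost reachable
  # row and the walk back hugs the smallest reachable rows
  expect_equal(path$points[, 1], c(3, 2, 1, 1, 1))
  expect_equal(path$total_cost, 0)
})

test_that("path cost equals the endpoint cumulative value on random maps", {
  set.seed(99)
  for (k in 1:20) {
    m <- sample(3:7, 1); n <- sample(3:8, 1)
    cmap <- matrix(runif(m * n), m, n)
    sr <- sample(m, 1)
    cum <- cumulative_cost(cmap, c(sr, 1), "col", 1L, n)
    path <- backtrack_path(cum)
    expect_equal(path$total_cost, sum(cmap[path$points]), tolerance = 1e-9)
    expect_true(is_three_connected(path))
  }
})

test_that("leftward tracing works symmetrically", {
  set.seed(4)
  cmap <- matrix(runif(5 * 7), 5, 7)
  cum <- cumulative_cost(cmap, c(2, 7), "col", -1L, 1L)
  path <- backtrack_path(cum)
  expect_equal(path$points[1, ], c(row = 2, col = 7))
  expect_equal(unname(path$points[nrow(path$points), 2]), 1)
  flipped <- enumerate_min_cost(cmap[, 7:1], 2L, 1L, 1L, 7L)
  expect_equal(path$total_cost, flipped$cost, tolerance = 1e-12)
})

test_that("windowed diaphysis tracing reduces to a single trace for wide windows", {
  set.seed(12)
  cmap <- matrix(runif(20 * 90), 20, 90)
  seed <- c(10L, 30L)
  single <- trace_diaphysis_edge(cmap, seed, 1L, window_w = 1000L, stop_col = 90L)
  ref <- backtrack_path(cumulative_cost(cmap, seed, "col", 1L, 90L))
  expect_equal(single$points, ref$points)
  expect_equal(single$total_cost, ref$total_cost, tolerance = 1e-9)
})

test_that("tracing follows an embedded zero-cost line exactly", {
  cmap <- matrix(1, 40, 60)
  line_rows <- 10 + floor((0:59) / 3)     # slope 1/3, 3-connected
  cmap[cbind(line_rows, 1:60)] <- 0
  path <- trace_diaphysis_edge(cmap, c(line_rows[20], 20L), 1L, 16L, 60L)
  expect_equal(path$points[, 1], line_rows[20:60])
  left <- trace_diaphysis_edge(cmap, c(line_rows[20], 20L), -1L, 16L, 1L)
  expect_equal(left$points[, 1], line_rows[20:1])
  expect_equal(path$total_cost + left$total_cost, 0)
})

test_that("adding a constant to the cost map shifts costs but not paths", {
  set.seed(31)
  cmap <- matrix(runif(12 * 25), 12, 25)
  p0 <- trace_diaphysis_edge(cmap, c(6L, 10L), 1L, 8L, 25L)
  p1 <- trace_diaphysis_edge(cmap + 2.5, c(6L, 10L), 1L, 8L, 25L)
  expect_equal(p0$points, p1$points)
  expect_equal(p1$total_cost - p0$total_cost, 2.5 * nrow(p0$points),
               tolerance = 1e-9)
})

test_that("joint tracing: straight vertical when a zero-cost line joins the endpoints", {
  cmap <- matrix(1, 50, 60)
  cmap[10:40, 30] <- 0
  path <- trace_joint_segment(cmap, c(10L, 30L), c(40L, 30L), x0 = 30L, n = 60L)
  expect_equal(path$points[, 2], rep(30L, 31))
  expect_equal(path$points[, 1], 10:40)
  expect_true(is_three_connected(path))
})

test_that("joint tracing honors the x0 +/- n/10 band and widens with a warning", {
  set.seed(17)
  cmap <- matrix(runif(60 * 100), 60, 100)
  x0 <- 50L; n <- 100L          # band columns 40..60
  path <- trace_joint_segment(cmap, c(5L, 48L), c(55L, 52L), x0, n)
  expect_true(all(path$points[, 2] >= 40 & path$points[, 2] <= 60))
  expect_warning(
    wide <- trace_joint_segment(cmap, c(5L, 30L), c(55L, 52L), x0, n),
    "widening")
  expect_equal(wide$points[1, ], c(row = 5, col = 30))
})

test_that("contour assembly: rectangle from three straight paths", {
  mk_path <- function(pts, axis) structure(
    list(points = pts, axis = axis, direction = 1L, total_cost = 0),
    class = "ur_traced_path")
  upper <- mk_path(cbind(row = rep(10L, 20), col = 1:20), "col")
  lower <- mk_path(cbind(row = rep(30L, 20), col = 1:20), "col")
  joint <- mk_path(cbind(row = 10:30, col = rep(20L, 21)), "row")
  paths <- list(bone1 = list(upper = upper, lower = lower, joint = joint),
                bone2 = list(upper = mk_path(cbind(row = rep(40L, 20), col = 1:20), "col"),
                             lower = mk_path(cbind(row = rep(50L, 20), col = 1:20), "col"),
                             joint = mk_path(cbind(row = 40:50, col = rep(20L, 11)), "row")))
  ctr <- assemble_contours(paths, identity_transform(c(60L, 30L)))
  expect_equal(sum(ctr$masks$bone1), 21 * 20)
  expect_true(all(ctr$masks$bone1[10:30, 1:20]))
  # closed polygon; vertex bookkeeping: upper + joint-1 + lower-1 + closing
  expect_equal(ctr$bone1[1, ], ctr$bone1[nrow(ctr$bone1), ])
  expect_equal(nrow(ctr$bone1), 20 + 20 + 19 + 19 + 1)
  # interiors disjoint
  expect_false(any(ctr$masks$bone1 & ctr$masks$bone2))
})

test_that("crossing diaphysis paths raise an assembly error", {
  mk_path <- function(pts, axis) structure(
    list(points = pts, axis = axis, direction = 1L, total_cost = 0),
    class = "ur_traced_path")
  upper <- mk_path(cbind(row = c(rep(10L, 10), rep(35L, 10)), col = 1:20), "col")
  lower <- mk_path(cbind(row = rep(30L, 20), col = 1:20), "col")
  joint <- mk_path(cbind(row = 35:30, col = rep(20L, 6)), "row")
  paths <- list(bone1 = list(upper = upper, lower = lower, joint = joint),
                bone2 = list(upper = upper, lower = lower, joint = joint))
  expect_error(assemble_contours(paths, identity_transform(c(60L, 30L))),
               class = "urseg_trace_error")
})

test_that("full segmentation is deterministic and all paths are 3-connected", {
  seg <- default_segmentation()
  seg2 <- segment_image(default_phantom()$image)
  expect_identical(seg$bone1, seg2$bone1)
  expect_identical(seg$masks$bone2, seg2$masks$bone2)
  for (bone in seg$components) {
    for (nm in c("upper", "lower", "joint")) {
      expect_true(is_three_connected(bone[[nm]]))
    }
  }
})

test_that("windowed and single-window tracing agree on the noiseless phantom", {
  pre <- noiseless_pre()
  cm <- build_cost_maps(pre$pixels)
  de <- locate_distal_end(pre$mask)
  ss <- detect_seed_points(pre, de$x0, de$p_max)
  for (i in c(1L, 4L)) {
    w64 <- trace_diaphysis_edge(cm$I1, ss$seeds[i, ], 1L, 64L, de$x0)
    wall <- trace_diaphysis_edge(cm$I1, ss$seeds[i, ], 1L, 100000L, de$x0)
    expect_equal(w64$points, wall$points)
  }
})

test_that("phantom diaphysis tracing stays within 2 px of the true edge", {
  ph <- noiseless_phantom()
  pre <- noiseless_pre()
  cm <- build_cost_maps(pre$pixels)
  de <- locate_distal_end(pre$mask)
  ss <- detect_seed_points(pre, de$x0, de$p_max)
  path <- trace_diaphysis_edge(cm$I1, ss$seeds[1, ], -1L, 64L, 1L)
  pts_orig <- std_to_orig(path$points, pre$transform)
  er <- ph$edge_rows[[1]]$upper
  cols <- round(pts_orig[, 2])
  keep <- cols >= 1 & cols <= length(er) & !is.na(er[pmax(1, cols)])
  err <- abs(pts_orig[keep, 1] - er[cols[keep]])
  expect_lt(mean(err), 2)
})
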