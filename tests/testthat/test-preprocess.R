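# Preprocessing: crop, direction, cleaning, enhancement, downsampling,
# transform bookkeeping.

test_that("crop detects uniform low-content borders (profile-scan oracle)", {
  img <- matrix(0.001, 100, 100)
  img[11:90, 11:90] <- 0.9
  cr <- crop_valid_region(img)
  rr <- oracle_valid_range(rowMeans(img))
  cc <- oracle_valid_range(colMeans(img))
  expect_equal(cr$crop_box, c(rr[1], cc[1], rr[2], cc[2]))
  # the detected content interval is rows/cols 11..90, expanded by a 2% margin
  expect_equal(cr$crop_box, c(10, 10, 91, 91))
  expect_equal(dim(cr$image), c(82L, 82L))
})

test_that("crop is the identity for an image without margins", {
  img <- matrix(0.5, 60, 80) + matrix(runif(60 * 80, 0, 0.1), 60, 80)
  cr <- crop_valid_region(img)
  expect_equal(cr$crop_box, c(1, 1, 60, 80))
  expect_identical(cr$image, img)
})

test_that("crop keeps the whole phantom forearm and errors on degenerate input", {
  ph <- noiseless_phantom()
  cr <- crop_valid_region(ph$image)
  fg <- which(ph$soft_mask, arr.ind = TRUE)
  expect_true(min(fg[, 1]) >= cr$crop_box[1] && max(fg[, 1]) <= cr$crop_box[3])
  expect_true(min(fg[, 2]) >= cr$crop_box[2] && max(fg[, 2]) <= cr$crop_box[4])
  tiny <- matrix(0, 100, 100); tiny[40:49, 40:49] <- 1
  expect_error(crop_valid_region(tiny), class = "urseg_preprocess_error")
})

test_that("direction correction rotates portrait images 90 degrees clockwise", {
  img <- matrix(0.1, 120, 60)
  img[20:100, 20:40] <- 0.5   # soft-tissue block between the two thresholds
  img[40:60, 25:35] <- 1.0
  cd <- correct_direction(img)
  expect_true(cd$rotation %in% c(90L, 270L))
  expect_equal(dim(cd$image), c(60L, 120L))
})

test_that("direction correction: landscape phantom unchanged, reversed flipped", {
  lr <- generate_phantom(phantom_params(seed = 5, noise_sigma = 0))
  crop <- crop_valid_region(lr$image)$image
  cd <- correct_direction(crop)
  expect_equal(cd$rotation, 0L)
  expect_identical(cd$image, crop)

  rl <- generate_phantom(phantom_params(seed = 5, noise_sigma = 0, orientation = "rl"))
  crop_rl <- crop_valid_region(rl$image)$image
  cd_rl <- correct_direction(crop_rl)
  expect_equal(cd_rl$rotation, 180L)
  # after the flip the image matches the left-to-right phantom's crop
  expect_equal(dim(cd_rl$image), dim(crop))
  expect_lt(max(abs(cd_rl$image - crop)), 1e-12)
})

test_that("direction correction is idempotent and errors on a degenerate image", {
  ph <- default_phantom()
  cd1 <- correct_direction(crop_valid_region(ph$image)$image)
  cd2 <- correct_direction(cd1$image)
  expect_equal(cd2$rotation, 0L)
  expect_identical(cd2$image, cd1$image)
  expect_error(correct_direction(matrix(0.9, 64, 80)),
               class = "urseg_preprocess_error")
})

test_that("extract_and_clean zeroes exactly the complement of the dilated mask", {
  ph <- noiseless_phantom()
  cr <- crop_valid_region(ph$image)
  cd <- correct_direction(cr$image)
  cl <- extract_and_clean(cd$image)
  cb <- cr$crop_box
  truth <- dilate_disk(ph$soft_mask[cb[1]:cb[3], cb[2]:cb[4]],
                       preprocess_config()$dilation_radius)
  expect_identical(cl$mask, truth)
  expect_true(all(cl$image[!cl$mask] == 0))
  expect_true(all(cl$image[cl$mask] == cd$image[cl$mask]))
})

test_that("extract_and_clean keeps an all-foreground image unchanged and drops a far marker", {
  img <- matrix(0.9, 64, 64)
  cl <- extract_and_clean(img)
  expect_true(all(cl$mask))
  expect_identical(cl$image, img)

  phm <- generate_phantom(phantom_params(seed = 9, noise_sigma = 0, marker = TRUE))
  cr <- crop_valid_region(phm$image)
  cl2 <- extract_and_clean(correct_direction(cr$image)$image)
  # the marker is bright enough to survive thresholding but is not connected
  # to the forearm, so the largest-component step removes it
  p <- phm$params
  mrow <- p$centerline_row - p$soft_halfheight - 45 / 704 * p$size - cr$crop_box[1] + 1
  mcol <- round(p$collim_width) + 1 + 40 / 704 * p$size - cr$crop_box[2] + 1
  expect_true(all(cl2$image[round(mrow) + (-2:2), round(mcol) + (-2:2)] == 0))
})

test_that("denoise_enhance: constant interior stays constant, noise variance drops", {
  img <- matrix(0, 48, 48)
  mask <- matrix(FALSE, 48, 48); mask[10:40, 10:40] <- TRUE
  img[mask] <- 0.6
  out <- denoise_enhance(img, preprocess_config(), mask)
  # constant interior stays constant (to bilateral summation precision)
  expect_equal(out[mask], rep(0.6, sum(mask)), tolerance = 1e-6)
  expect_lt(max(out[mask]) - min(out[mask]), 1e-6)
  expect_true(all(out[!mask] == 0))

  set.seed(21)
  noisy <- img
  noisy[mask] <- pmin(pmax(0.6 + rnorm(sum(mask), 0, 0.05), 0), 1)
  sm <- bilateral_cpp(noisy, 3, 0.1)
  expect_lt(stats::var(sm[mask]), stats::var(noisy[mask]))
})

test_that("masked equalization spreads a two-level interior to the extremes", {
  img <- matrix(0, 40, 40)
  mask <- matrix(FALSE, 40, 40); mask[5:36, 5:36] <- TRUE
  half <- which(mask)
  img[half[seq_along(half) %% 2 == 0]] <- 0.3
  img[half[seq_along(half) %% 2 == 1]] <- 0.6
  out <- urseg:::hist_equalize_masked(img, mask)
  lv <- sort(unique(out[mask]))
  # two equal-mass bins map to the range extremes under the CDF rule
  expect_equal(lv, c(0, 1))
})

test_that("downsample: identity, dimension rule, argument checks", {
  img <- matrix(runif(200 * 300), 200, 300)
  expect_identical(downsample_image(img, 1), img)
  expect_equal(dim(downsample_image(img, 0.5)), c(100L, 150L))
  expect_equal(dim(downsample_image(img, 0.7)), c(140L, 210L))
  expect_error(downsample_image(img, 0))
  expect_error(downsample_image(img, 1.2))
})

test_that("preprocess standardizes the phantom with exact zero background", {
  pre <- noiseless_pre()
  expect_true(all(pre$pixels[!pre$mask] == 0))
  expect_true(all(pre$pixels >= 0 & pre$pixels <= 1))
  expect_equal(pre$transform$rot, 0L)
  expect_equal(pre$transform$ratio, 0.7)
  # deterministic: a second run is bit-identical
  pre2 <- preprocess(noiseless_phantom()$image)
  expect_identical(pre$pixels, pre2$pixels)
  expect_identical(pre$mask, pre2$mask)
})

test_that("preprocess recovers the standard orientation for every phantom orientation", {
  expected_rot <- c(lr = 0L, rl = 180L, down = 270L, up = 90L)
  for (o in names(expected_rot)) {
    ph <- generate_phantom(phantom_params(seed = 31, noise_sigma = 0, orientation = o))
    pre <- preprocess(ph$image)
    expect_equal(pre$transform$rot, expected_rot[[o]], info = o)
    # wrist (soft-tissue neck + hand) ends up on the right half
    de <- locate_distal_end(pre$mask)
    expect_gt(de$x0, ncol(pre$pixels) / 2)
  }
})

test_that("transform round-trips within 0.5 px and maps truth consistently", {
  ph <- noiseless_phantom()
  pre <- noiseless_pre()
  tf <- pre$transform
  set.seed(8)
  pts <- cbind(runif(50, 1, tf$dims$std[1]), runif(50, 1, tf$dims$std[2]))
  back <- orig_to_std(std_to_orig(pts, tf), tf)
  expect_lt(max(abs(back - pts)), 1e-9)
  # ground-truth contour mapped std -> orig -> std reproduces coordinates
  ctr <- ph$bone_contours[[1]]
  ctr_std <- orig_to_std(ctr, tf)
  ctr_back <- orig_to_std(std_to_orig(ctr_std, tf), tf)
  expect_lt(max(abs(ctr_back - ctr_std)), 0.5)
})

test_that("inverted-polarity radiographs are detected and handled", {
  ph <- noiseless_phantom()
  pre_inv <- preprocess(1 - ph$image)
  expect_true(pre_inv$provenance$inverted)
  pre <- noiseless_pre()
  expect_identical(pre_inv$pixels, pre$pixels)
})
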