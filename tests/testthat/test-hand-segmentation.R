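test_that("Otsu threshold separates a two-level chroma image exactly", {
  set.seed(1)
  v <- matrix(40, 32, 32)
  hi_region <- matrix(FALSE, 32, 32); hi_region[10:25, 5:20] <- TRUE
  v[hi_region] <- 200
  thr <- otsu_threshold(v)
  expect_gt(thr, 40); expect_lt(thr, 200)
  expect_identical(v > thr, hi_region)
  # brute-force between-class-variance maximizer agrees on the split
  t_oracle <- oracle_otsu(v)
  expect_identical(v > t_oracle, hi_region)
})

test_that("Otsu threshold matches the brute-force split on noisy images", {
  set.seed(7)
  for (k in 1:5) {
    v <- matrix(c(rnorm(300, 60, 12), rnorm(212, 190, 10)), 32, 16)
    v <- pmin(pmax(round(v), 0), 255)
    thr <- otsu_threshold(v)
    t_oracle <- oracle_otsu(v)
    # the two implementations may sit on different sides of an empty
    # histogram gap; the induced classification must agree
    expect_identical(v > thr, v > t_oracle)
  }
})

test_that("constant chroma channel raises a no-threshold error", {
  img <- flat_image(16, 16, c(0, 0, 0))
  expect_error(segment_hand(img), "no-threshold")
})

test_that("skin silhouette is segmented with high IoU", {
  m <- hand_model("right", "palmar", width = 240, height = 300)
  r <- render_hand(m, seed = 11)
  mask <- segment_hand(r$image)
  gt <- r$ground_truth$mask
  iou <- sum(mask & gt) / sum(mask | gt)
  expect_gte(iou, 0.95)
})

test_that("segmentation is idempotent under background zeroing", {
  m <- hand_model("right", "palmar", width = 200, height = 250)
  r <- render_hand(m, seed = 3)
  mask1 <- segment_hand(r$image)
  img2 <- unclass(r$image)
  for (k in 1:3) img2[, , k][!mask1] <- 0
  mask2 <- segment_hand(rgb_image(img2))
  expect_true(all(mask2[mask1]))               # mask2 contains mask1
})

test_that("largest_contour keeps the biggest component only", {
  m <- matrix(FALSE, 40, 40)
  m[2:11, 2:11] <- TRUE                   # 100 px blob
  m[30:32, 30:32] <- TRUE                 # 9 px blob
  ct <- largest_contour(binary_mask(m))
  comp <- attr(ct, "component_mask")
  expect_true(all(which(comp, arr.ind = TRUE)[, 1] <= 11))
  expect_equal(sum(comp), 100)
})

test_that("largest_contour area matches the filled rectangle", {
  m <- matrix(FALSE, 60, 100)
  m[11:51, 11:81] <- TRUE                 # pixel centres 10..50 x 10..80
  ct <- largest_contour(binary_mask(m))
  area <- abs(sum(ct[, 1] * c(ct[-1, 2], ct[1, 2]) -
                  c(ct[-1, 1], ct[1, 1]) * ct[, 2]) / 2)
  expect_lt(abs(area - 2800) / 2800, 0.02)
})

test_that("empty mask raises a no-hand error", {
  expect_error(largest_contour(binary_mask(matrix(FALSE, 10, 10))),
               "no-hand")
})

test_that("largest component dominates every other component", {
  set.seed(5)
  for (k in 1:10) {
    m <- matrix(runif(40 * 40) < 0.35, 40, 40)
    if (!any(m)) next
    ct <- largest_contour(binary_mask(m))
    comp <- attr(ct, "component_mask")
    lab <- EBImage::bwlabel(m * 1L)
    sizes <- tabulate(lab[lab > 0])
    expect_equal(sum(comp), max(sizes))
  }
})

test_that("wrist points cross a rectangular arm at the wrist landmark", {
  m <- matrix(FALSE, 60, 100)
  m[20:40, 10:90] <- TRUE                 # vertical arm, x 19..39
  ct <- largest_contour(binary_mask(m))
  lms <- landmarks_stub(list("0" = c(30, 60), "9" = c(30, 20)),
                        default = c(30, 15))
  w <- wrist_points(ct, lms)
  pts <- rbind(w$left_point, w$right_point)
  expect_equal(sort(pts[, 1]), c(19, 39), tolerance = 1)
  expect_equal(pts[, 2], c(60, 60), tolerance = 1)
})

test_that("coincident landmarks 0 and 9 raise a degenerate-axis error", {
  m <- matrix(FALSE, 30, 30); m[5:25, 5:25] <- TRUE
  ct <- largest_contour(binary_mask(m))
  lms <- landmarks_stub(list("0" = c(15, 15), "9" = c(15, 15)))
  expect_error(wrist_points(ct, lms), "degenerate-axis")
})

test_that("wrist line outside the contour raises wrist-not-found", {
  m <- matrix(FALSE, 30, 40); m[5:25, 5:35] <- TRUE
  ct <- largest_contour(binary_mask(m))
  lms <- landmarks_stub(list("0" = c(15, 60), "9" = c(15, 50)))
  expect_error(wrist_points(ct, lms), "wrist-not-found")
})

test_that("ROI is the half-plane clip on the finger side", {
  m <- matrix(TRUE, 40, 60)
  mask <- binary_mask(m)
  ct <- largest_contour(mask)
  lms <- landmarks_stub(list("0" = c(20, 30), "9" = c(20, 5)))
  wrist <- structure(list(left_point = c(0, 30), right_point = c(39, 30)),
                     class = "wrist_points")
  roi <- extract_roi(mask, ct, wrist, lms)
  # upper half (rows y <= 30), area within 2% of half the rectangle
  expect_lt(abs(sum(roi$mask) - 40 * 31) / (40 * 30), 0.05)
  expect_true(all(which(roi$mask, arr.ind = TRUE)[, 2] <= 31))
  # subset property
  expect_true(all(roi$mask <= m))
})

test_that("wrist line beyond the far side keeps the entire mask", {
  m <- matrix(FALSE, 30, 40); m[5:25, 5:35] <- TRUE
  mask <- binary_mask(m)
  ct <- largest_contour(mask)
  lms <- landmarks_stub(list("0" = c(15, 40), "9" = c(15, 5)))
  wrist <- structure(list(left_point = c(0, 39), right_point = c(29, 39)),
                     class = "wrist_points")
  roi <- extract_roi(mask, ct, wrist, lms)
  expect_identical(as.logical(roi$mask), as.logical(m))
})

test_that("wrist line beyond the fingertip side empties the ROI", {
  m <- matrix(FALSE, 30, 40); m[5:25, 10:35] <- TRUE
  mask <- binary_mask(m)
  ct <- largest_contour(mask)
  lms <- landmarks_stub(list("0" = c(15, 35), "9" = c(15, 12)))
  wrist <- structure(list(left_point = c(0, 2), right_point = c(29, 2)),
                     class = "wrist_points")
  expect_error(extract_roi(mask, ct, wrist, lms), "empty-roi")
})
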