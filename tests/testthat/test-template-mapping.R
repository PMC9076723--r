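test_that("unit square maps to itself through the identity homography", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  H <- fit_segment_homography(sq, sq)
  expect_equal(H$matrix / H$matrix[3, 3], diag(3), tolerance = 1e-9)
})

test_that("similarity case gives the expected diagonal and exact corners", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  H <- fit_segment_homography(sq, 2 * sq)
  M <- H$matrix / H$matrix[3, 3]
  expect_equal(M, diag(c(2, 2, 1)), tolerance = 1e-9)
  expect_equal(apply_homography(H, sq), 2 * sq, tolerance = 1e-9)
})

test_that("random quads are mapped with sub-microscopic corner residual", {
  set.seed(8)
  for (k in 1:20) {
    src <- random_quad(); dst <- random_quad()
    H <- fit_segment_homography(src, dst)
    got <- apply_homography(H, src)
    expect_lt(max(sqrt(rowSums((got - dst)^2))), 1e-6)
    # round trip through the inverse
    back <- apply_homography(invert_homography(H), got)
    expect_lt(max(sqrt(rowSums((back - src)^2))), 0.5)
  }
})

test_that("collinear corners raise a degenerate-homography error", {
  bad <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 5))
  good <- random_quad()
  expect_error(fit_segment_homography(bad, good), "degenerate-homography")
  expect_error(fit_segment_homography(good, bad), "degenerate-homography")
})

test_that("all 18 segment homographies of a synthetic hand round-trip", {
  tpl <- templates_fixture()[["palmar_right"]]
  m <- hand_model("right", "palmar", width = 240, height = 300,
                  pose = list(scale = 175, theta = 0.12, tx = 50, ty = 15))
  dec <- model_decomposition(m)$decomposition
  for (lab in names(dec$segments)) {
    H <- fit_segment_homography(dec$segments[[lab]]$corners,
                                tpl$segments$segments[[lab]]$corners,
                                label = lab)
    fwd <- apply_homography(H, dec$segments[[lab]]$corners)
    expect_lt(max(sqrt(rowSums(
      (fwd - tpl$segments$segments[[lab]]$corners)^2))), 1e-6)
    back <- apply_homography(invert_homography(H), fwd)
    expect_lt(max(sqrt(rowSums(
      (back - dec$segments[[lab]]$corners)^2))), 0.5)
  }
})

test_that("full-ROI coverage maps to covered == valid", {
  tpl <- templates_fixture()[["palmar_right"]]
  m <- hand_model("right", "palmar", width = 220, height = 275)
  parts <- model_decomposition(m)
  full <- binary_mask(as_plain_mask(parts$roi$mask))
  mc <- map_to_template(full, parts$roi, parts$decomposition, tpl)
  expect_identical(as.logical(mc$covered), as.logical(mc$valid))
  empty <- binary_mask(matrix(FALSE, 220, 275))
  mc0 <- map_to_template(empty, parts$roi, parts$decomposition, tpl)
  expect_false(any(mc0$covered))
  expect_gt(sum(mc0$valid), 0)
})

test_that("single-segment coverage stays inside its template segment", {
  tpl <- templates_fixture()[["palmar_right"]]
  m <- hand_model("right", "palmar", width = 220, height = 275,
                  pose = list(scale = 165, theta = -0.08, tx = 45, ty = 12))
  parts <- model_decomposition(m)
  seg <- polygon_raster_mask(
    parts$decomposition$segments[["ring_middle"]]$corners, 220, 275)
  cov <- binary_mask(seg & as_plain_mask(parts$roi$mask))
  mc <- map_to_template(cov, parts$roi, parts$decomposition, tpl)
  mc <- correct_errors(mc, tpl)
  tseg <- polygon_raster_mask(
    tpl$segments$segments[["ring_middle"]]$corners,
    tpl$width, tpl$height, expand = 2)
  expect_gte(sum(mc$covered & tseg) / sum(mc$covered), 0.95)
})

test_that("mapping a template onto itself is the identity up to rasterization", {
  tpl <- templates_fixture()[["dorsal_left"]]
  roi <- structure(list(mask = tpl$outline_mask,
                        contour = largest_contour(tpl$outline_mask),
                        wrist = tpl$wrist, landmarks = tpl$landmarks),
                   class = "hand_roi")
  set.seed(4)
  cov <- matrix(runif(tpl$width * tpl$height) < 0.5,
                tpl$width, tpl$height) & as_plain_mask(tpl$outline_mask)
  mc <- map_to_template(binary_mask(cov), roi, tpl$segments, tpl)
  mc <- correct_errors(mc, tpl)
  agree <- mean(mc$covered[mc$valid] == cov[mc$valid])
  expect_gte(agree, 0.99)
})

test_that("missing segment pair is reported by label", {
  tpl <- templates_fixture()[["palmar_right"]]
  m <- hand_model("right", "palmar", width = 200, height = 250)
  parts <- model_decomposition(m)
  dec <- parts$decomposition
  dec$segments[["palm_q2"]] <- NULL
  expect_error(map_to_template(binary_mask(matrix(FALSE, 200, 250)),
                               parts$roi, dec, tpl),
               "palm_q2")
})

test_that("error correction enforces covered within valid within outline", {
  tpl <- templates_fixture()[["palmar_right"]]
  set.seed(12)
  for (k in 1:5) {
    covered <- matrix(runif(tpl$width * tpl$height) < 0.3,
                      tpl$width, tpl$height)
    valid <- covered | (matrix(runif(tpl$width * tpl$height) < 0.4,
                               tpl$width, tpl$height))
    mc <- mapped_stub(covered, valid)
    out <- correct_errors(mc, tpl)
    outline <- as_plain_mask(tpl$outline_mask)
    expect_true(all(!out$covered | out$valid))
    expect_true(all(!out$valid | outline))
    # per-pixel oracle of the two removal rules
    expect_identical(as.logical(out$valid), as.logical(valid & outline))
    expect_identical(as.logical(out$covered),
                     as.logical(covered & valid & outline))
    # idempotence
    out2 <- correct_errors(out, tpl)
    expect_identical(as.logical(out2$covered), as.logical(out$covered))
    expect_identical(as.logical(out2$valid), as.logical(out$valid))
  }
})

test_that("quality flag passes full validity and fails sparse or lost segments", {
  tpl <- templates_fixture()[["palmar_right"]]
  outline <- as_plain_mask(tpl$outline_mask)
  full <- mapped_stub(matrix(FALSE, tpl$width, tpl$height), outline)
  expect_true(quality_flag(full, tpl)$pass)
  # half the outline valid -> valid-area floor failure
  half <- outline
  half[, seq_len(floor(ncol(half) / 2))] <- FALSE
  q <- quality_flag(mapped_stub(matrix(FALSE, tpl$width, tpl$height), half),
                    tpl)
  expect_false(q$pass)
  expect_true(any(grepl("valid-area floor", q$reasons)))
  # one segment with zero valid pixels is named
  sv <- setNames(rep(10L, 18), segment_labels_18_fixture())
  sv["thumb_distal"] <- 0L
  q2 <- quality_flag(mapped_stub(matrix(FALSE, tpl$width, tpl$height),
                                 outline, segment_valid = sv), tpl)
  expect_false(q2$pass)
  expect_true(any(grepl("thumb_distal", q2$reasons)))
})

test_that("template-space coverage ratio tracks the image-space fraction", {
  tpl <- templates_fixture()[["palmar_right"]]
  set.seed(31)
  for (k in 1:20) {
    pose <- list(scale = 160 * runif(1, 0.95, 1.05),
                 theta = runif(1, -0.12, 0.12),
                 tx = 45 + runif(1, -5, 5), ty = 12 + runif(1, -5, 5))
    m <- hand_model("right", "palmar", width = 220, height = 275,
                    pose = pose)
    parts <- model_decomposition(m)
    labs <- sample(names(parts$decomposition$segments),
                   sample(3:12, 1))
    cov <- matrix(FALSE, 220, 275)
    for (lab in labs)
      cov <- cov | polygon_raster_mask(
        parts$decomposition$segments[[lab]]$corners, 220, 275,
        expand = 0.75)
    cov <- cov & as_plain_mask(parts$roi$mask)
    f <- sum(cov) / sum(parts$roi$mask)
    mc <- correct_errors(map_to_template(binary_mask(cov), parts$roi,
                                         parts$decomposition, tpl), tpl)
    ratio <- sum(mc$covered) / sum(mc$valid)
    expect_lt(abs(ratio - f), 0.05)
  }
})

test_that("template sets round-trip through disk", {
  tset <- templates_fixture()
  dir <- file.path(tempdir(), "tplset")
  unlink(dir, recursive = TRUE)
  write_template_set(tset, dir)
  back <- read_template_set(dir)
  expect_setequal(names(back), names(tset))
  tp <- back[["palmar_left"]]
  expect_equal(as.logical(tp$outline_mask),
               as.logical(tset[["palmar_left"]]$outline_mask))
  expect_equal(landmark_points(tp$landmarks),
               landmark_points(tset[["palmar_left"]]$landmarks))
  for (lab in names(tp$segments$segments))
    expect_equal(tp$segments$segments[[lab]]$corners,
                 tset[["palmar_left"]]$segments$segments[[lab]]$corners)
})
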