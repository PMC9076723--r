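prob_stub <- function(p) agg_stub(p)

test_that("combining one step is the identity; two steps take the max", {
  p1 <- matrix(runif(36), 6, 6)
  one <- combine_steps(list("1" = prob_stub(p1)), "1")
  expect_equal(one$probability, p1)
  p2 <- matrix(0.2, 6, 6); p3 <- matrix(0.9, 6, 6)
  two <- combine_steps(list("1" = prob_stub(p2), "4" = prob_stub(p3)),
                       c("1", "4"))
  expect_true(all(two$probability == 0.9))
})

test_that("max-combination matches the per-pixel oracle with missing data", {
  set.seed(19)
  labels <- c("1", "2R", "3", "5L", "6R")
  for (k in 1:5) {
    probs <- lapply(labels, function(s) {
      p <- matrix(runif(64), 8, 8)
      p[matrix(runif(64) < 0.2, 8, 8)] <- NA
      p
    })
    names(probs) <- labels
    maps <- lapply(probs, prob_stub)
    got <- combine_steps(maps, labels)$probability
    expect_identical(got, oracle_max_combine(probs))
  }
})

test_that("adding a step never decreases the combined probability", {
  set.seed(20)
  labels <- c("1", "2R", "2L", "3", "4")
  maps <- setNames(lapply(labels, function(s)
    prob_stub(matrix(runif(49), 7, 7))), labels)
  for (k in 2:5) {
    small <- combine_steps(maps, labels[1:(k - 1)])$probability
    big <- combine_steps(maps, labels[1:k])$probability
    expect_true(all(big >= small, na.rm = TRUE))
  }
})

test_that("combined probability respects the superadditivity bound", {
  set.seed(21)
  labels <- c("1", "5R", "5L")
  probs <- lapply(labels, function(s) matrix(runif(36), 6, 6))
  names(probs) <- labels
  comb <- combine_steps(lapply(probs, prob_stub), labels)$probability
  bound <- pmin(1, Reduce(`+`, probs))
  expect_true(all(comb <= bound + 1e-12))
})

test_that("empty or unknown step sets are rejected", {
  maps <- list("1" = prob_stub(matrix(0.5, 3, 3)))
  expect_error(combine_steps(maps, character(0)), "empty")
  expect_error(combine_steps(maps, c("1", "9Z")), "unknown")
  expect_error(combine_steps(list("2R" = prob_stub(matrix(0.5, 3, 3))),
                             "2R"), "prerequisite")
})

test_that("a redundant step has zero exclusive coverage and unit loss map", {
  base <- matrix(0.8, 5, 5)
  maps <- list("1" = prob_stub(base), "3" = prob_stub(base * 0.5))
  res <- exclusive_coverage(maps, c("1", "3"), "3")
  expect_true(all(res$exclusive_map == 0))
  expect_true(all(res$loss_map == 1))
})

test_that("a uniquely covering step owns its exclusive region", {
  p1 <- matrix(0, 6, 6)
  p4 <- matrix(0, 6, 6); p4[2:4, 2:4] <- 1
  maps <- list("1" = prob_stub(p1), "4" = prob_stub(p4))
  res <- exclusive_coverage(maps, c("1", "4"), "4")
  expect_equal(res$exclusive_map, p4)
  expect_equal(res$loss_map, 1 - p4)
})

test_that("exclusive coverage matches the brute-force max-subtract", {
  set.seed(22)
  labels <- c("1", "2R", "2L", "4", "5R")
  for (k in 1:5) {
    probs <- setNames(lapply(labels, function(s) {
      p <- matrix(runif(64), 8, 8)
      p[matrix(runif(64) < 0.15, 8, 8)] <- NA
      p
    }), labels)
    maps <- lapply(probs, prob_stub)
    res <- exclusive_coverage(maps, labels, "4")
    all_max <- oracle_max_combine(probs)
    wo_max <- oracle_max_combine(probs[setdiff(labels, "4")])
    want <- all_max
    def <- !is.na(all_max)
    wo0 <- ifelse(is.na(wo_max), 0, wo_max)
    want[def] <- pmax(all_max[def] - wo0[def], 0)
    expect_equal(res$exclusive_map, want)
    expect_true(all(res$exclusive_map >= 0, na.rm = TRUE))
  }
})

test_that("excluding the prerequisite step is refused", {
  maps <- list("1" = prob_stub(matrix(0.5, 3, 3)),
               "3" = prob_stub(matrix(0.5, 3, 3)))
  expect_error(exclusive_coverage(maps, c("1", "3"), "1"),
               "necessary prerequisite")
})

test_that("exclusive coverage ignores the order of the other steps", {
  set.seed(23)
  labels <- c("1", "2R", "4", "6L")
  maps <- setNames(lapply(labels, function(s)
    prob_stub(matrix(runif(25), 5, 5))), labels)
  a <- exclusive_coverage(maps, labels, "4")
  b <- exclusive_coverage(maps[c("6L", "1", "4", "2R")],
                          c("6L", "1", "4", "2R"), "4")
  expect_identical(a$exclusive_map, b$exclusive_map)
})

test_that("loss fractions follow their closed-form definitions", {
  tpl <- templates_fixture()[["palmar_right"]]
  outline <- as_plain_mask(tpl$outline_mask)
  zero <- matrix(0, tpl$width, tpl$height)
  res0 <- structure(list(exclusive_map = zero, loss_map = 1 - zero,
                         excluded = "3", steps = c("1", "3")),
                    class = "coverage_loss_result")
  lf0 <- loss_fraction(res0, tpl)
  expect_equal(lf0$weighted, 0)
  expect_equal(lf0$thresholded, 0)
  # exclusive = 1 on exactly 10% of outline pixels
  n <- sum(outline)
  k <- round(0.1 * n)
  e <- zero
  e[which(outline)[seq_len(k)]] <- 1
  res1 <- structure(list(exclusive_map = e, loss_map = 1 - e,
                         excluded = "4", steps = c("1", "4")),
                    class = "coverage_loss_result")
  lf1 <- loss_fraction(res1, tpl)
  expect_equal(lf1$weighted, k / n)
  expect_equal(lf1$thresholded, k / n)
  # probability-weighted loss equals the outline mean of the map
  set.seed(24)
  e2 <- zero; e2[outline] <- runif(n)
  res2 <- structure(list(exclusive_map = e2, loss_map = 1 - e2,
                         excluded = "4", steps = c("1", "4")),
                    class = "coverage_loss_result")
  expect_equal(loss_fraction(res2, tpl)$weighted, mean(e2[outline]))
})

test_that("accumulation validation reports exact differences", {
  p <- matrix(runif(49), 7, 7)
  maps <- list("1" = prob_stub(p))
  same <- validate_accumulation(maps, prob_stub(p), "1")
  expect_equal(same$mean_abs_diff, 0)
  expect_equal(same$category_agreement, 1)
  shifted <- pmin(p + 0.1, 1)
  expect_equal(validate_accumulation(
    list("1" = prob_stub(shifted)), prob_stub(p), "1")$mean_abs_diff,
    mean(abs(shifted - p)))
})
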