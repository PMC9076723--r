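test_that("aggregation computes valid-count-normalized probabilities", {
  d <- c(6, 5)
  m1 <- mapped_stub(matrix(TRUE, d[1], d[2]), matrix(TRUE, d[1], d[2]))
  m2 <- m1
  m3 <- m1
  agg <- aggregate_maps(list(m1, m2, m3))
  expect_true(all(agg$probability == 1))
  # pixel covered in 1 of 4 valid observations
  cov <- matrix(FALSE, d[1], d[2]); cov[2, 2] <- TRUE
  m4 <- mapped_stub(cov, matrix(TRUE, d[1], d[2]))
  agg2 <- aggregate_maps(list(m4, mapped_stub(matrix(FALSE, d[1], d[2]),
                                              matrix(TRUE, d[1], d[2])),
                              mapped_stub(matrix(FALSE, d[1], d[2]),
                                          matrix(TRUE, d[1], d[2])),
                              mapped_stub(matrix(FALSE, d[1], d[2]),
                                          matrix(TRUE, d[1], d[2]))))
  expect_equal(agg2$probability[2, 2], 0.25)
  # a pixel valid nowhere carries no probability
  v <- matrix(TRUE, d[1], d[2]); v[4, 4] <- FALSE
  agg3 <- aggregate_maps(list(mapped_stub(matrix(FALSE, d[1], d[2]), v)))
  expect_true(is.na(agg3$probability[4, 4]))
})

test_that("aggregation rejects empty input and mixed identities", {
  expect_error(aggregate_maps(list()), "empty")
  a <- mapped_stub(matrix(FALSE, 3, 3), matrix(TRUE, 3, 3),
                   identity = list(task = 1, hand = "left", side = "dorsal"))
  b <- mapped_stub(matrix(FALSE, 3, 3), matrix(TRUE, 3, 3),
                   identity = list(task = 2, hand = "left", side = "dorsal"))
  expect_error(aggregate_maps(list(a, b)), "mixed identities")
})

test_that("aggregation matches the per-pixel counting oracle", {
  set.seed(14)
  for (k in 1:5) {
    stack <- lapply(1:6, function(i) {
      v <- matrix(runif(64) < 0.8, 8, 8)
      c_ <- v & matrix(runif(64) < 0.5, 8, 8)
      mapped_stub(c_, v)
    })
    agg <- aggregate_maps(stack)
    expect_identical(agg$probability, oracle_aggregate(stack))
  }
})

test_that("probability-count products conserve the covered totals", {
  set.seed(15)
  stack <- lapply(1:7, function(i) {
    v <- matrix(runif(100) < 0.7, 10, 10)
    mapped_stub(v & matrix(runif(100) < 0.4, 10, 10), v)
  })
  agg <- aggregate_maps(stack)
  total_covered <- sum(vapply(stack, function(m) sum(m$covered), numeric(1)))
  prob <- agg$probability; prob[is.na(prob)] <- 0
  expect_equal(sum(prob * agg$count), total_covered)
})

test_that("aggregation is order invariant and binary for one observation", {
  set.seed(16)
  stack <- lapply(1:5, function(i) {
    v <- matrix(runif(64) < 0.6, 8, 8)
    mapped_stub(v & matrix(runif(64) < 0.5, 8, 8), v)
  })
  a <- aggregate_maps(stack)
  b <- aggregate_maps(rev(stack))
  expect_identical(a$probability, b$probability)
  one <- aggregate_maps(stack[2])
  vals <- one$probability[!is.na(one$probability)]
  expect_true(all(vals %in% c(0, 1)))
})

test_that("quantization respects the interval boundaries", {
  p <- matrix(c(0, 0.25, 0.26, 0.5, 0.51, 0.75, 0.76, 1, NA), 3, 3)
  q <- quantize_map(p)
  expect_equal(as.vector(q), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, NA))
})

test_that("quantization equals the brute-force interval lookup", {
  set.seed(17)
  p <- matrix(runif(400), 20, 20)
  p[sample(400, 30)] <- NA
  expect_identical(quantize_map(p), oracle_quantize(p))
})

test_that("quantize of three-observation aggregates hits all categories", {
  d <- c(4, 1)
  mk <- function(cov_counts) {
    lapply(1:3, function(i)
      mapped_stub(matrix(cov_counts >= i, d[1], d[2]),
                  matrix(TRUE, d[1], d[2])))
  }
  # per-pixel covered counts 0,1,2,3 over 3 valid observations
  stack <- lapply(1:3, function(i)
    mapped_stub(matrix(c(FALSE, i <= 1, i <= 2, TRUE), d[1], d[2]),
                matrix(TRUE, d[1], d[2])))
  agg <- aggregate_maps(stack)
  expect_equal(agg$probability[, 1], c(0, 1 / 3, 2 / 3, 1))
  expect_equal(quantize_map(agg)[, 1], c(1L, 2L, 3L, 4L))
})

test_that("side correlations recover identity, negation and simulated r", {
  parts <- sprintf("p%02d", 1:200)
  set.seed(18)
  x <- rnorm(200)
  df <- rbind(
    data.frame(participant = parts, hand = "left", side = "dorsal",
               coverage = x),
    data.frame(participant = parts, hand = "right", side = "dorsal",
               coverage = x),
    data.frame(participant = parts, hand = "left", side = "palmar",
               coverage = -x + mean(x) * 2),
    data.frame(participant = parts, hand = "right", side = "palmar",
               coverage = 0.8 * x + sqrt(1 - 0.8^2) * rnorm(200)))
  sc <- side_correlations(df)
  expect_equal(sc$r["dorsal_left", "dorsal_right"], 1)
  expect_equal(sc$r["dorsal_left", "palmar_left"], -1)
  expect_lt(abs(sc$r["dorsal_left", "palmar_right"] - 0.8), 0.1)
  expect_lt(sc$p["dorsal_left", "palmar_right"], 0.001)
})

test_that("a constant column yields NA correlations", {
  parts <- sprintf("p%02d", 1:10)
  df <- rbind(
    data.frame(participant = parts, hand = "left", side = "dorsal",
               coverage = 1),
    data.frame(participant = parts, hand = "right", side = "dorsal",
               coverage = runif(10)))
  sc <- side_correlations(df)
  expect_true(is.na(sc$r["dorsal_left", "dorsal_right"]))
})
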