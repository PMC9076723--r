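# Shared fixtures and independent oracles. Everything is generated in
# code at test time; expensive objects (template sets, the small demo
# study) are built once per test run and cached here.

.fixture_env <- new.env(parent = emptyenv())

# low-resolution template set for mapping tests
templates_fixture <- function(resolution = 300) {
  key <- paste0("tpl_", resolution)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- build_template_set(resolution)
  .fixture_env[[key]]
}

# a small synthetic study (2 participants) on disk, plus its report
small_study_fixture <- function() {
  if (is.null(.fixture_env$study)) {
    dir <- file.path(tempdir(), "handcover-small-study")
    unlink(dir, recursive = TRUE)
    design <- study_design(n_participants = 2, seed = 42,
                           image_width = 200, image_height = 250)
    sim <- simulate_study(design, dir)
    .fixture_env$study <- list(dir = dir, design = design, sim = sim)
  }
  .fixture_env$study
}

small_report_fixture <- function() {
  if (is.null(.fixture_env$report)) {
    st <- small_study_fixture()
    cfg <- run_config(templates = templates_fixture(), seed = 1)
    .fixture_env$report <- run_study(st$sim$manifest_path, cfg)
  }
  .fixture_env$report
}

# ---- tiny constructors -----------------------------------------------------

# RGB image from per-channel matrices
rgb_from_channels <- function(r, g, b) {
  rgb_image(array(c(r, g, b), dim = c(nrow(r), ncol(r), 3)))
}

# uniform-colour image
flat_image <- function(width, height, rgb) {
  rgb_from_channels(matrix(rgb[1], width, height),
                    matrix(rgb[2], width, height),
                    matrix(rgb[3], width, height))
}

# landmark set with all 21 points at given defaults, selected rows
# overridden; geometry-light tests only need landmarks 0 and 9
landmarks_stub <- function(overrides = list(), default = c(5, 5),
                           handedness = "right") {
  pts <- matrix(rep(default, each = 21), 21, 2)
  for (idx in names(overrides)) pts[as.integer(idx) + 1, ] <-
    overrides[[idx]]
  landmark_set(pts, handedness = handedness, source = "manual")
}

# random RGB image with values covering the 8-bit range
random_image <- function(width, height) {
  rgb_from_channels(matrix(sample(0:255, width * height, TRUE), width),
                    matrix(sample(0:255, width * height, TRUE), width),
                    matrix(sample(0:255, width * height, TRUE), width))
}

# mapped_coverage stub from bare matrices
mapped_stub <- function(covered, valid, identity = NULL,
                        segment_valid = NULL) {
  if (is.null(segment_valid))
    segment_valid <- setNames(rep(1L, 18), segment_labels_18_fixture())
  structure(list(covered = binary_mask(covered),
                 valid = binary_mask(valid),
                 identity = identity, segment_valid = segment_valid),
            class = "mapped_coverage")
}

segment_labels_18_fixture <- function() {
  c(paste0(rep(c("index", "middle", "ring", "little"), each = 3),
           c("_proximal", "_middle", "_distal")),
    "thumb_proximal", "thumb_distal", paste0("palm_q", 1:4))
}

# aggregated_map stub from a probability matrix (count 1 where defined)
agg_stub <- function(prob, identity = NULL) {
  count <- matrix(0L, nrow(prob), ncol(prob))
  count[!is.na(prob)] <- 1L
  structure(list(probability = prob, count = count,
                 n_observations = 1L, identity = identity),
            class = "aggregated_map")
}

# ---- independent oracles ---------------------------------------------------

# per-pixel HSB from first principles (case-split hue formula); hue on
# the half-degree 0-179+ scale, brightness 0-255
oracle_hsb_pixel <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b)
  if (mx == mn) h <- 0
  else if (mx == r) h <- (60 * ((g - b) / (mx - mn)) + 360) %% 360
  else if (mx == g) h <- 60 * ((b - r) / (mx - mn)) + 120
  else h <- 60 * ((r - g) / (mx - mn)) + 240
  c(h = h / 2, b = mx)
}

# per-pixel brute-force fluorescence rule
oracle_fluorescence <- function(img, thr) {
  a <- unclass(img)
  out <- matrix(FALSE, dim(a)[1], dim(a)[2])
  for (x in seq_len(dim(a)[1])) for (y in seq_len(dim(a)[2])) {
    hb <- oracle_hsb_pixel(a[x, y, 1], a[x, y, 2], a[x, y, 3])
    in_hue <- hb["h"] >= thr$hue_min && hb["h"] <= thr$hue_max
    rej <- hb["b"] >= thr$brightness_reject_min &&
      hb["b"] <= thr$brightness_reject_max
    out[x, y] <- in_hue && !rej
  }
  out
}

# brute-force Otsu: maximize between-class variance over all 256 cuts
oracle_otsu <- function(channel) {
  vals <- as.vector(round(channel))
  best_t <- NA; best_v <- -Inf
  for (t in 0:254) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (length(lo) == 0 || length(hi) == 0) next
    v <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# brute-force per-pixel aggregation of a list of mapped observations
oracle_aggregate <- function(mapped) {
  d <- dim(mapped[[1]]$valid)
  prob <- matrix(NA_real_, d[1], d[2])
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    nv <- 0; nc <- 0
    for (m in mapped) {
      if (m$valid[x, y]) { nv <- nv + 1; if (m$covered[x, y]) nc <- nc + 1 }
    }
    if (nv > 0) prob[x, y] <- nc / nv
  }
  prob
}

# brute-force per-pixel category lookup
oracle_quantize <- function(prob) {
  out <- matrix(NA_integer_, nrow(prob), ncol(prob))
  for (x in seq_len(nrow(prob))) for (y in seq_len(ncol(prob))) {
    p <- prob[x, y]
    if (is.na(p)) next
    out[x, y] <- if (p <= 0.25) 1L else if (p <= 0.5) 2L
                 else if (p <= 0.75) 3L else 4L
  }
  out
}

# brute-force per-pixel max over a list of probability matrices
oracle_max_combine <- function(probs) {
  d <- dim(probs[[1]])
  out <- matrix(NA_real_, d[1], d[2])
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    vals <- vapply(probs, function(p) p[x, y], numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) > 0) out[x, y] <- max(vals)
  }
  out
}

# random non-degenerate convex-ish quadrilateral
random_quad <- function(scale = 100) {
  repeat {
    base <- matrix(runif(8, 0, scale), 4, 2)
    ctr <- colMeans(base)
    ang <- atan2(base[, 2] - ctr[2], base[, 1] - ctr[1])
    q <- base[order(ang), ]
    ok <- TRUE
    for (k in 1:4) {
      tri <- q[setdiff(1:4, k), ]
      a <- abs((tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
               (tri[3, 1] - tri[1, 1]) * (tri[2, 2] - tri[1, 2])) / 2
      if (a < 0.02 * scale^2) ok <- FALSE
    }
    if (ok) return(q)
  }
}
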