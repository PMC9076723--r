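#' Build a standard hand template
#'
#' The standard template is the canonical synthetic hand rendered
#' noise-free at a chosen resolution, with its manually-defined
#' landmark schema, web valleys, wrist points and 18-segment
#' decomposition attached. One template exists per (hand, side); all
#' observations of that hand side are warped onto it.
#'
#' @param hand `"left"` or `"right"`.
#' @param side `"dorsal"` or `"palmar"`.
#' @param resolution hand length (wrist landmark to middle fingertip)
#'   in template pixels.
#' @return a `standard_template`: list with `identity`, `resolution`,
#'   `width`, `height`, `outline_mask` (the hand region above the
#'   wrist), `landmarks`, `webs`, `wrist`, `segments` (a
#'   `segment_decomposition`) and the underlying `model`.
#' @export
build_standard_template <- function(hand, side, resolution = 1000) {
  hand <- match.arg(hand, c("left", "right"))
  side <- match.arg(side, c("dorsal", "palmar"))
  geom <- canonical_hand_geometry()
  scale <- resolution / geom$hand_length
  width <- ceiling(0.96 * scale)
  height <- ceiling(0.97 * scale)
  pose <- list(scale = scale, theta = 0,
               tx = width / 2 - 0.5 * scale, ty = 2 - 0.03 * scale)
  model <- hand_model(hand, side, pose = pose, width = width,
                      height = height, geometry = geom)
  parts <- model_decomposition(model)
  structure(list(identity = list(hand = hand, side = side),
                 resolution = resolution, width = width, height = height,
                 outline_mask = parts$roi$mask,
                 landmarks = parts$roi$landmarks,
                 webs = parts$webs, wrist = parts$roi$wrist,
                 segments = parts$decomposition, model = model),
            class = "standard_template")
}

#' @export
print.standard_template <- function(x, ...) {
  cat(sprintf("<standard_template %s %s, %d x %d px>\n",
              x$identity$hand, x$identity$side, x$width, x$height))
  invisible(x)
}

#' Build the full template set (four hand sides)
#'
#' @param resolution hand length in template pixels.
#' @return named list with elements `dorsal_left`, `dorsal_right`,
#'   `palmar_left`, `palmar_right`.
#' @export
build_template_set <- function(resolution = 1000) {
  out <- list()
  for (side in c("dorsal", "palmar"))
    for (hand in c("left", "right"))
      out[[paste(side, hand, sep = "_")]] <-
        build_standard_template(hand, side, resolution)
  out
}

#' Write / read a template set on disk
#'
#' Each template occupies one directory `<side>_<hand>/` holding
#' `outline.png` (the outline mask), `landmarks.json` and
#' `segments.json`, plus `meta.json` with the remaining geometry.
#'
#' @param templates a template set from [build_template_set()].
#' @param dir directory.
#' @return `read_template_set` returns the template set (without the
#'   generating `model`, which disk templates do not carry).
#' @export
write_template_set <- function(templates, dir) {
  for (nm in names(templates)) {
    tp <- templates[[nm]]
    d <- file.path(dir, nm)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_mask_png(tp$outline_mask, file.path(d, "outline.png"))
    write_landmarks(tp$landmarks, file.path(d, "landmarks.json"))
    write_segments_json(tp$segments, file.path(d, "segments.json"))
    meta <- list(hand = tp$identity$hand, side = tp$identity$side,
                 resolution = tp$resolution,
                 width = tp$width, height = tp$height,
                 webs = unname(unclass(tp$webs)),
                 wrist = list(left_point = tp$wrist$left_point,
                              right_point = tp$wrist$right_point))
    jsonlite::write_json(meta, file.path(d, "meta.json"),
                         auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  invisible(dir)
}

#' @rdname write_template_set
#' @export
read_template_set <- function(dir) {
  out <- list()
  for (nm in list.dirs(dir, recursive = FALSE, full.names = FALSE)) {
    d <- file.path(dir, nm)
    meta <- jsonlite::read_json(file.path(d, "meta.json"),
                                simplifyVector = TRUE)
    webs <- as.matrix(meta$webs)
    rownames(webs) <- c("thumb_index", "index_middle", "middle_ring",
                        "ring_little")
    colnames(webs) <- c("x", "y")
    out[[nm]] <- structure(
      list(identity = list(hand = meta$hand, side = meta$side),
           resolution = meta$resolution,
           width = meta$width, height = meta$height,
           outline_mask = read_mask_png(file.path(d, "outline.png")),
           landmarks = read_landmarks(file.path(d, "landmarks.json"),
                                      source = "manual"),
           webs = structure(webs, class = c("web_points", class(webs))),
           wrist = structure(list(
             left_point = as.numeric(meta$wrist$left_point),
             right_point = as.numeric(meta$wrist$right_point)),
             class = "wrist_points"),
           segments = read_segments_json(file.path(d, "segments.json")),
           model = NULL),
      class = "standard_template")
  }
  out
}

#' Warp observed coverage into template space
#'
#' For every segment pair (observation segment, template segment of the
#' same label) the exact 4-corner homography is fitted and the coverage
#' and ROI masks restricted to that segment are warped into template
#' space by inverse mapping with nearest-neighbour sampling. Segments
#' are composited with covered-wins logic: a template pixel observed
#' covered through any segment is covered; observed through any segment
#' at all, it is valid.
#'
#' @param coverage a [binary_mask()] of fluorescent coverage (image
#'   space).
#' @param roi a `hand_roi`.
#' @param decomposition the observation's `segment_decomposition`.
#' @param template a `standard_template`.
#' @param identity optional list tagging (participant, task, hand,
#'   side).
#' @return a `mapped_coverage`: list with template-space `covered` and
#'   `valid` masks, `identity`, and per-segment valid-pixel counts in
#'   `segment_valid`.
#' @export
map_to_template <- function(coverage, roi, decomposition, template,
                            identity = NULL) {
  stopifnot(inherits(template, "standard_template"),
            inherits(decomposition, "segment_decomposition"))
  cov <- as_plain_mask(coverage)
  rmask <- as_plain_mask(roi$mask)
  W <- template$width; H <- template$height
  covered <- matrix(FALSE, W, H)
  valid <- matrix(FALSE, W, H)
  seg_valid <- setNames(integer(length(template$segments$segments)),
                        names(template$segments$segments))
  for (label in names(template$segments$segments)) {
    tseg <- template$segments$segments[[label]]
    oseg <- decomposition$segments[[label]]
    if (is.null(oseg))
      stop("missing segment pair for label: ", label)
    Hmat <- fit_segment_homography(oseg$corners, tseg$corners,
                                   label = label)
    Hinv <- invert_homography(Hmat)
    # pixels of the template-space quad (slightly expanded to avoid
    # one-pixel seams between adjacent segments); bbox-local to keep
    # the per-segment work proportional to the segment size
    poly <- tseg$corners
    ctr <- colMeans(poly)
    dirs <- sweep(poly, 2, ctr)
    lens <- sqrt(rowSums(dirs^2)); lens[lens < 1e-9] <- 1
    poly <- poly + dirs / lens * 0.75
    x0 <- max(1L, floor(min(poly[, 1])) + 1L)
    x1 <- min(W, ceiling(max(poly[, 1])) + 1L)
    y0 <- max(1L, floor(min(poly[, 2])) + 1L)
    y1 <- min(H, ceiling(max(poly[, 2])) + 1L)
    if (x0 > x1 || y0 > y1) next
    g <- expand.grid(x = (x0:x1) - 1L, y = (y0:y1) - 1L)
    inside <- points_in_polygon(g$x, g$y, poly)
    if (!any(inside)) next
    idx <- cbind(g$x[inside] + 1L, g$y[inside] + 1L)
    tp <- cbind(idx[, 1] - 1, idx[, 2] - 1)
    sp <- apply_homography(Hinv, tp)
    sx <- round(sp[, 1]) + 1L; sy <- round(sp[, 2]) + 1L
    ok <- sx >= 1L & sx <= nrow(rmask) & sy >= 1L & sy <= ncol(rmask)
    if (!any(ok)) next
    si <- cbind(sx[ok], sy[ok])
    ti <- idx[ok, , drop = FALSE]
    v <- rmask[si]
    c_ <- cov[si] & v
    seg_valid[label] <- sum(v)
    valid[ti[v, , drop = FALSE]] <- TRUE
    covered[ti[c_, , drop = FALSE]] <- TRUE
  }
  structure(list(covered = binary_mask(covered),
                 valid = binary_mask(valid),
                 identity = identity, segment_valid = seg_valid),
            class = "mapped_coverage")
}

#' @export
print.mapped_coverage <- function(x, ...) {
  cat(sprintf("<mapped_coverage %d x %d: %d covered / %d valid px>\n",
              nrow(x$valid), ncol(x$valid), sum(x$covered), sum(x$valid)))
  invisible(x)
}

#' Error-correct a mapped observation against the template outline
#'
#' Removes the two classes of erroneous template points: points falling
#' outside the boundary of the standard drawing become invalid (and
#' uncovered), and outline points that received no mapped information
#' simply remain invalid. Idempotent.
#'
#' @param mapped a `mapped_coverage`.
#' @param template the `standard_template` it was mapped onto.
#' @return a corrected `mapped_coverage` with
#'   `covered` \eqn{\subseteq} `valid` \eqn{\subseteq} outline.
#' @export
correct_errors <- function(mapped, template) {
  outline <- as_plain_mask(template$outline_mask)
  valid <- as_plain_mask(mapped$valid) & outline
  covered <- as_plain_mask(mapped$covered) & valid
  structure(list(covered = binary_mask(covered),
                 valid = binary_mask(valid),
                 identity = mapped$identity,
                 segment_valid = mapped$segment_valid),
            class = "mapped_coverage")
}

#' Automated quality check of a mapped observation
#'
#' Surrogate for the study's visual inspection step: an observation
#' fails when the valid area covers less than `floor` of the template
#' outline (hand movement, gross misalignment) or when any segment
#' contributed no valid pixels at all (lost segment).
#'
#' @param mapped an error-corrected `mapped_coverage`.
#' @param template the `standard_template`.
#' @param floor minimum valid-area / outline-area ratio.
#' @return list with `pass` (logical), `reasons` (character vector,
#'   empty when passing) and `valid_ratio`.
#' @export
quality_flag <- function(mapped, template, floor = 0.80) {
  outline <- as_plain_mask(template$outline_mask)
  ratio <- sum(mapped$valid) / sum(outline)
  reasons <- character(0)
  if (ratio < floor)
    reasons <- c(reasons, sprintf(
      "valid-area floor: valid/outline = %.3f < %.2f", ratio, floor))
  dead <- names(mapped$segment_valid)[mapped$segment_valid == 0]
  if (length(dead) > 0)
    reasons <- c(reasons, paste0("segment contributed no valid pixels: ",
                                 paste(dead, collapse = ", ")))
  list(pass = length(reasons) == 0, reasons = reasons, valid_ratio = ratio)
}
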