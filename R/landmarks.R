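#' The 21-point hand landmark set
#'
#' Landmarks follow the standard 21-point hand schema: index 0 is the
#' wrist; 1-4 the thumb (CMC, MCP, IP, tip); 5-8 the index, 9-12 the
#' middle, 13-16 the ring and 17-20 the little finger (MCP, PIP, DIP,
#' tip each). Index 9 is the middle-finger base used to define the
#' wrist line.
#'
#' @param points `21 x 2` numeric matrix of 0-based `(x, y)` pixel
#'   coordinates, rows in landmark-index order.
#' @param handedness `"left"` or `"right"`.
#' @param source one of `"detector"`, `"manual"`, `"synthetic"`.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(points, handedness = c("left", "right"),
                         source = c("detector", "manual", "synthetic")) {
  points <- as.matrix(points)
  if (!identical(dim(points), c(21L, 2L)))
    stop("landmarks-not-found: expected exactly 21 (x, y) points")
  if (!all(is.finite(points)))
    stop("landmarks-not-found: landmark coordinates must be finite")
  handedness <- match.arg(handedness)
  source <- match.arg(source)
  structure(list(points = points, handedness = handedness, source = source),
            class = "landmark_set")
}

landmark_points <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  landmarks$points
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set %s hand, source %s>\n", x$handedness, x$source))
  invisible(x)
}

#' Read / write a landmark sidecar JSON
#'
#' The sidecar format is
#' `{"handedness": "left", "points": [[x, y], ...21 rows]}`.
#'
#' @param path JSON file path.
#' @param landmarks a [landmark_set()] (for writing).
#' @param source source tag recorded on the landmarks read back.
#' @return `read_landmarks` returns a [landmark_set()].
#' @export
read_landmarks <- function(path, source = "manual") {
  if (!file.exists(path)) stop("landmarks-not-found: no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$points) || is.null(obj$handedness))
    stop("landmarks-not-found: sidecar missing 'points' or 'handedness'")
  pts <- as.matrix(obj$points)
  if (!identical(dim(pts), c(21L, 2L)))
    stop("landmarks-not-found: sidecar must contain exactly 21 points")
  landmark_set(pts, handedness = obj$handedness, source = source)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  obj <- list(handedness = landmarks$handedness,
              points = unname(landmarks$points))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Detect hand landmarks
#'
#' The landmark detector is a pluggable backend. The built-in `"file"`
#' backend reads a JSON sidecar next to (or given instead of) the image,
#' so the pipeline runs deterministically without any external model;
#' an external detector can be registered as a function
#' `function(image) -> landmark_set`.
#'
#' @param image an [rgb_image()] or an image file path.
#' @param backend `"file"` or a detector function.
#' @param sidecar path to the landmark JSON when `backend = "file"`.
#' @return a [landmark_set()].
#' @export
detect_landmarks <- function(image, backend = "file", sidecar = NULL) {
  if (is.function(backend)) {
    lm <- backend(image)
    if (!inherits(lm, "landmark_set"))
      stop("landmarks-not-found: detector backend did not return a landmark_set")
    return(lm)
  }
  if (identical(backend, "file")) {
    if (is.null(sidecar)) {
      if (!is.character(image))
        stop("landmarks-not-found: file backend needs a `sidecar` path")
      sidecar <- paste0(tools::file_path_sans_ext(image), ".json")
    }
    return(read_landmarks(sidecar, source = "detector"))
  }
  stop("unknown landmark backend")
}

# ---- convexity defects -----------------------------------------------------

# Convexity defects of a closed contour: for every convex-hull edge,
# the contour arc between its two hull vertices, split wherever the
# contour comes back to touch the hull chord (several collinear
# fingertips share one hull edge), with the deepest point of each
# touching-free sub-arc reported as one defect.
convexity_defects <- function(contour, touch_tol = 1.0) {
  pts <- unclass(contour)
  n <- nrow(pts)
  hull <- grDevices::chull(pts[, 1], pts[, 2])   # indices, one orientation
  hull <- sort(hull)                             # contour order
  out <- list()
  for (k in seq_along(hull)) {
    i0 <- hull[k]
    i1 <- if (k == length(hull)) hull[1] else hull[k + 1]
    if (i1 == i0) next
    arc <- if (i1 > i0) seq(i0, i1) else c(seq(i0, n), seq_len(i1))
    if (length(arc) < 3) next
    a <- pts[i0, ]; b <- pts[i1, ]
    e <- b - a
    len <- vec_norm(e)
    if (len < 1e-12) next
    d <- abs((pts[arc, 1] - a[1]) * e[2] - (pts[arc, 2] - a[2]) * e[1]) / len
    # sub-arcs separated by chord contacts
    off <- d > touch_tol
    r <- rle(off)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (g in which(r$values)) {
      seg <- starts[g]:ends[g]
      j <- seg[which.max(d[seg])]
      if (d[j] <= 0) next
      apex <- refine_notch_apex(pts, arc, seg, j)
      out[[length(out) + 1L]] <- list(start = i0, end = i1,
                                      index = arc[j],
                                      point = apex,
                                      depth = d[j])
    }
  }
  out
}

# Sub-pixel apex of a notch: the deepest raster point is ambiguous by
# a few pixels (ties along whichever wall runs nearly parallel to the
# hull chord), so the apex is re-estimated as the intersection of
# straight lines fitted to the two notch walls on either side of the
# deepest point. Falls back to the raw deepest pixel when the walls
# are nearly parallel or the intersection lands implausibly far away.
refine_notch_apex <- function(pts, arc, seg, j, reach = 18L, skip = 2L) {
  p0 <- pts[arc[j], ]
  fit_dir <- function(idx) {
    if (length(idx) < 3) return(NULL)
    pp <- pts[arc[idx], , drop = FALSE]
    ctr <- colMeans(pp)
    sv <- svd(sweep(pp, 2, ctr))
    list(ctr = ctr, dir = sv$v[, 1])
  }
  pos <- which(seg == j)
  before <- seg[pos - seq_len(min(reach, pos - 1))]
  after <- seg[pos + seq_len(min(reach, length(seg) - pos))]
  la <- fit_dir(before[-seq_len(min(skip, length(before)))])
  lb <- fit_dir(after[-seq_len(min(skip, length(after)))])
  if (is.null(la) || is.null(lb)) return(p0)
  cross <- la$dir[1] * lb$dir[2] - la$dir[2] * lb$dir[1]
  if (abs(cross) < 0.3) return(p0)        # walls nearly parallel
  A <- cbind(la$dir, -lb$dir)
  t <- tryCatch(solve(A, lb$ctr - la$ctr), error = function(e) NULL)
  if (is.null(t)) return(p0)
  apex <- la$ctr + t[1] * la$dir
  if (sum((apex - p0)^2) > 64) return(p0) # implausibly far from argmax
  apex
}

contour_perimeter <- function(contour) {
  pts <- unclass(contour)
  d <- diff(rbind(pts, pts[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

nearest_contour_index <- function(contour, p) {
  pts <- unclass(contour)
  which.min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)
}

#' Finger-web points from convexity defects
#'
#' Web points are the valleys between adjacent fingers, found as
#' convexity defects of the hand contour. For each adjacent fingertip
#' landmark pair (4, 8), (8, 12), (12, 16), (16, 20) the deepest
#' qualifying defect whose point lies on the contour arc between the two
#' fingertips (the arc not passing through any other fingertip) is kept.
#' Defects shallower than 2 percent of the contour perimeter are ignored
#' as noise.
#'
#' @param contour a `hand_contour`.
#' @param landmarks a [landmark_set()].
#' @param min_depth_frac noise floor for defect depth, as a fraction of
#'   the contour perimeter.
#' @return a `web_points` object: `4 x 2` matrix with rows
#'   `thumb_index`, `index_middle`, `middle_ring`, `ring_little`.
#' @export
web_points <- function(contour, landmarks, min_depth_frac = 0.02) {
  pts <- unclass(contour)
  n <- nrow(pts)
  lm <- landmark_points(landmarks)
  defects <- convexity_defects(contour)
  perim <- contour_perimeter(contour)
  defects <- Filter(function(d) d$depth >= min_depth_frac * perim, defects)
  if (length(defects) < 4L)
    stop("webs-not-found: fewer than 4 convexity defects of sufficient depth")
  tips <- c(4, 8, 12, 16, 20)                 # landmark indices (0-based)
  tip_idx <- vapply(tips, function(i) nearest_contour_index(contour, lm[i + 1, ]),
                    integer(1))
  pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5))
  labels <- c("thumb_index", "index_middle", "middle_ring", "ring_little")
  webs <- matrix(NA_real_, 4, 2, dimnames = list(labels, c("x", "y")))
  def_idx <- vapply(defects, function(d) d$index, numeric(1))
  def_depth <- vapply(defects, function(d) d$depth, numeric(1))
  for (k in seq_len(4)) {
    i0 <- tip_idx[pairs[k, 1]]; i1 <- tip_idx[pairs[k, 2]]
    # the two candidate arcs between the fingertips
    arc_fwd <- if (i1 >= i0) c(i0, i1) else c(i0, i1 + n)
    in_fwd <- (def_idx >= arc_fwd[1] & def_idx <= arc_fwd[2]) |
      (def_idx + n >= arc_fwd[1] & def_idx + n <= arc_fwd[2])
    other_tips <- tip_idx[-pairs[k, ]]
    fwd_clean <- !any((other_tips >= arc_fwd[1] & other_tips <= arc_fwd[2]) |
                      (other_tips + n >= arc_fwd[1] & other_tips + n <= arc_fwd[2]))
    arc_bwd <- if (i0 >= i1) c(i1, i0) else c(i1, i0 + n)
    in_bwd <- (def_idx >= arc_bwd[1] & def_idx <= arc_bwd[2]) |
      (def_idx + n >= arc_bwd[1] & def_idx + n <= arc_bwd[2])
    bwd_clean <- !any((other_tips >= arc_bwd[1] & other_tips <= arc_bwd[2]) |
                      (other_tips + n >= arc_bwd[1] & other_tips + n <= arc_bwd[2]))
    cand <- if (fwd_clean) in_fwd else if (bwd_clean) in_bwd else in_fwd & FALSE
    if (!any(cand))
      stop("webs-not-found: no qualifying defect between fingertips ",
           tips[pairs[k, 1]], " and ", tips[pairs[k, 2]])
    j <- which(cand)[which.max(def_depth[cand])]
    webs[k, ] <- defects[[j]]$point
  }
  structure(webs, class = c("web_points", class(webs)))
}
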