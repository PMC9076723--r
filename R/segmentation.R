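#' Segment the hand from a white-light photograph
#'
#' Converts the image to the YUV colour system, takes the V
#' (red-difference chroma) channel and applies Otsu's automatic global
#' threshold. Skin is redder than the dark background, so the foreground
#' is the class with the higher mean V, i.e. pixels strictly above the
#' threshold. A single 3x3 morphological closing suppresses speckle
#' before contour extraction.
#'
#' @param image an [rgb_image()] taken under white light with one hand
#'   against a dark background.
#' @param close logical; apply a 3x3 morphological closing before
#'   contour extraction. Off by default: at desk-scale resolutions the
#'   closing can seal the raster-thin tips of the finger-web valleys
#'   and displace the detected web points, while the Otsu split on the
#'   chroma channel is already speckle-free for realistic noise levels.
#' @return a [binary_mask()] of the hand (and any forearm in frame).
#' @seealso [largest_contour()], [extract_roi()]
#' @export
segment_hand <- function(image, close = FALSE) {
  v <- yuv_v_channel(image)
  thr <- otsu_threshold(v)          # errors on a constant channel
  m <- v > thr
  if (close) {
    m <- EBImage::closing(m * 1L, EBImage::makeBrush(3, "box")) > 0
  }
  binary_mask(m, ref = image)
}

#' Boundary contour of the largest foreground component
#'
#' Labels the connected components of a binary mask and returns the
#' ordered boundary polygon of the component with the greatest pixel
#' area; all smaller components are discarded. The filled mask of that
#' component is attached as attribute `component_mask`.
#'
#' @param mask a [binary_mask()] with at least one foreground pixel.
#' @return a `hand_contour`: an `n x 2` matrix of 0-based `(x, y)`
#'   boundary coordinates in tracing order.
#' @export
largest_contour <- function(mask) {
  m <- as_plain_mask(mask)
  if (!any(m)) stop("no-hand: mask has no foreground component")
  lab <- EBImage::bwlabel(m * 1L)
  tab <- tabulate(lab[lab > 0])
  big <- which.max(tab)
  comp <- lab == big
  oc <- EBImage::ocontour(comp * 1L)
  pts <- oc[[1]]
  if (nrow(pts) < 3L) stop("no-hand: largest component has no polygonal boundary")
  structure(pts, class = c("hand_contour", class(pts)),
            component_mask = binary_mask(comp))
}

#' Wrist points of a hand contour
#'
#' The wrist line is the line through landmark 0 (the wrist landmark)
#' perpendicular to the segment from landmark 0 to landmark 9 (the
#' middle-finger base). Its intersections with the hand contour, one on
#' each side of the 0-9 axis and each the closest crossing to landmark 0
#' on its side, are the wrist points.
#'
#' @param contour a `hand_contour` from [largest_contour()].
#' @param landmarks a [landmark_set()].
#' @return a `wrist_points` object: list with `left_point` and
#'   `right_point` (0-based `(x, y)`), where "left" is the side with
#'   negative cross product against the 0-9 axis.
#' @export
wrist_points <- function(contour, landmarks) {
  lm <- landmark_points(landmarks)
  p0 <- lm[1, ]; p9 <- lm[10, ]
  axis <- p9 - p0
  if (vec_norm(axis) < 1e-9)
    stop("degenerate-axis: landmarks 0 and 9 coincide")
  axis <- axis / vec_norm(axis)
  # the wrist line has normal = axis and passes through p0
  hits <- line_polygon_intersections(p0, axis, unclass(contour))
  if (nrow(hits$points) < 2L)
    stop("wrist-not-found: wrist line crosses the contour fewer than twice")
  side <- hits$t                     # signed offset along the line direction
  neg <- which(side < 0); pos <- which(side > 0)
  if (length(neg) == 0L || length(pos) == 0L)
    stop("wrist-not-found: no contour crossing on both sides of the 0-9 axis")
  iL <- neg[which.max(side[neg])]    # closest to p0 from the negative side
  iR <- pos[which.min(side[pos])]
  structure(list(left_point = hits$points[iL, ],
                 right_point = hits$points[iR, ]),
            class = "wrist_points")
}

#' Region of interest above the wrist
#'
#' Clips the hand mask to the closed half-plane of the wrist line that
#' contains landmark 9, i.e. the hand proper without the forearm.
#'
#' @param mask the segmentation [binary_mask()] (or the largest
#'   component's mask).
#' @param contour the `hand_contour`.
#' @param wrist the `wrist_points`.
#' @param landmarks the [landmark_set()].
#' @return a `hand_roi`: list with elements `mask` ([binary_mask()]),
#'   `contour`, `wrist` and `landmarks`.
#' @export
extract_roi <- function(mask, contour, wrist, landmarks) {
  m <- as_plain_mask(mask)
  lm <- landmark_points(landmarks)
  p0 <- lm[1, ]; p9 <- lm[10, ]
  a <- wrist$left_point
  # the kept half-plane opens in the wrist-to-middle-finger direction,
  # so a wrist line beyond the fingertips leaves nothing
  n <- p9 - p0
  if (vec_norm(n) < 1e-9) stop("degenerate-axis: landmarks 0 and 9 coincide")
  n <- n / vec_norm(n)
  hp <- halfplane_mask(nrow(m), ncol(m), a, n)
  roi <- m & hp
  if (!any(roi)) stop("empty-roi: no hand pixels above the wrist line")
  structure(list(mask = binary_mask(roi), contour = contour,
                 wrist = wrist, landmarks = landmarks),
            class = "hand_roi")
}

#' @export
print.hand_roi <- function(x, ...) {
  cat(sprintf("<hand_roi %d x %d, %d px>\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}
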