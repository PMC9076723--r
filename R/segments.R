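# Fixed 18-segment hand layout
#
# The hand (and each standard template) is decomposed into 18 labelled
# quadrilaterals derived from the 21 landmarks, the 4 finger-web points
# and the 2 wrist points:
#   * 3 segments per finger for index/middle/ring/little (proximal,
#     middle, distal phalanx), split at the MCP/PIP/DIP/tip landmarks
#     with lateral corners taken perpendicular to the local finger axis
#     out to the hand contour                                  -> 12
#   * 2 segments for the thumb (MCP-IP, IP-tip)                ->  2
#   * 4 palm (or dorsum) quadrants fanning from the wrist line up to
#     the finger-web points and the outer knuckle corners      ->  4
# Corner names are canonical per segment and shared with the template
# decomposition of the same label, which is what makes the per-segment
# homographies well defined.

finger_landmark_rows <- list(          # 1-based rows into the 21-point set
  thumb  = c(2, 4, 5),                 # CMC, IP, tip: the proximal thumb
                                       # segment starts at the CMC so it
                                       # covers the thenar junction
  index  = c(6, 7, 8, 9),
  middle = c(10, 11, 12, 13),
  ring   = c(14, 15, 16, 17),
  little = c(18, 19, 20, 21)
)

segment_labels_18 <- function() {
  c(paste0(rep(c("index", "middle", "ring", "little"), each = 3),
           c("_proximal", "_middle", "_distal")),
    "thumb_proximal", "thumb_distal",
    paste0("palm_q", 1:4))
}

finger_corner_key <- c("base_left", "tip_left", "tip_right", "base_right")
palm_corner_key   <- c("bottom_left", "bottom_right", "top_right", "top_left")

# Lateral corners of one finger chain: for each joint, cast rays
# perpendicular to the local axis to the contour (capped at
# 1.5 * finger width, falling back to a half-width offset).
finger_lateral_corners <- function(joints, contour, width_cap_factor = 1.5) {
  nj <- nrow(joints)
  poly <- unclass(contour)
  # finger width estimate: twice the median distance from the joints to
  # the nearest contour point
  dists <- vapply(seq_len(nj), function(i) {
    sqrt(min((poly[, 1] - joints[i, 1])^2 + (poly[, 2] - joints[i, 2])^2))
  }, numeric(1))
  w <- 2 * stats::median(dists)
  if (w <= 0) w <- 1
  # push the tip joint towards the cap apex so the distal segment
  # covers most of the rounded fingertip
  tip_dir <- joints[nj, ] - joints[nj - 1, ]
  if (vec_norm(tip_dir) > 1e-9) {
    joints[nj, ] <- joints[nj, ] + 0.9 * (w / 2) * tip_dir / vec_norm(tip_dir)
  }
  left <- matrix(NA_real_, nj, 2)
  right <- matrix(NA_real_, nj, 2)
  for (i in seq_len(nj)) {
    prev <- max(i - 1, 1); nxt <- min(i + 1, nj)
    d <- joints[nxt, ] - joints[prev, ]
    if (vec_norm(d) < 1e-9)
      stop("degenerate-segment: coincident joints in finger chain")
    d <- d / vec_norm(d)
    pl <- perp2(d)
    for (s in c(1, -1)) {
      if (i == nj) {
        # at the (extended) tip station the contour has already curved
        # in around the fingertip cap; a fixed half-width offset keeps
        # the distal segment full width so the capsule sides stay
        # covered (any overshoot into background is clipped by the ROI)
        p <- joints[i, ] + s * pl * (w / 2)
      } else {
        hit <- ray_polygon_first_hit(joints[i, ], s * pl, poly)
        p <- if (!is.null(hit) && hit$t <= width_cap_factor * w)
          hit$point else joints[i, ] + s * pl * (w / 2)
      }
      if (s > 0) left[i, ] <- p else right[i, ] <- p
    }
  }
  list(left = left, right = right, width = w)
}

make_segment <- function(label, corners, key) {
  corners <- as.matrix(corners)
  dimnames(corners) <- list(key, c("x", "y"))
  if (quad_degenerate(corners))
    stop("degenerate-segment: ", label)
  list(label = label, corners = corners, corner_key = key)
}

#' Decompose a hand region into the fixed 18-segment layout
#'
#' Splits the hand into 18 labelled quadrilateral segments based on the
#' 21 landmarks, the wrist points and the 4 finger-web points: three
#' phalanx segments for each of index/middle/ring/little, two for the
#' thumb, and four palm (dorsum) quadrants between the wrist line and
#' the knuckle/web chain. Segment labels and canonical corner orders are
#' identical between observed hands and templates, giving the 1:1
#' corner correspondence the per-segment homographies require.
#'
#' @param roi a `hand_roi` from [extract_roi()].
#' @param landmarks a [landmark_set()] (defaults to the one in `roi`).
#' @param webs a `web_points` object from [web_points()].
#' @return a `segment_decomposition`: list of 18 segments, each with
#'   `label`, a `4 x 2` `corners` matrix (rows named by the canonical
#'   corner key) and `corner_key`.
#' @export
decompose_segments <- function(roi, landmarks = roi$landmarks, webs) {
  stopifnot(inherits(roi, "hand_roi"), inherits(webs, "web_points"))
  lm <- landmark_points(landmarks)
  contour <- roi$contour
  segs <- list()

  # lateral corner chains per finger (ray casting at every joint)
  corners_by_finger <- list()
  for (finger in names(finger_landmark_rows)) {
    rows <- finger_landmark_rows[[finger]]
    joints <- lm[rows, , drop = FALSE]
    corners_by_finger[[finger]] <- finger_lateral_corners(joints, contour)
  }

  # the base corners of the four long fingers are snapped to the
  # flanking web points (or to the ray-cast corner on the outer hand
  # edges), so finger segments and palm quadrants share corners and
  # tile without seams
  web_of <- list(index  = c(NA, "index_middle"),
                 middle = c("index_middle", "middle_ring"),
                 ring   = c("middle_ring", "ring_little"),
                 little = c("ring_little", NA))
  for (finger in names(web_of)) {
    lat <- corners_by_finger[[finger]]
    rows <- finger_landmark_rows[[finger]]
    mcp <- lm[rows[1], ]; pip <- lm[rows[2], ]
    axis <- pip - mcp
    pl <- perp2(axis / vec_norm(axis))
    anchors <- web_of[[finger]]
    for (s in 1:2) {                    # 1 = "left" side, 2 = "right"
      side_sign <- if (s == 1) 1 else -1
      anchor <- NA
      for (a in anchors) {
        if (is.na(a)) next
        w <- webs[a, ]
        if (sign(sum((w - mcp) * pl)) == side_sign) anchor <- w
      }
      if (all(!is.na(anchor))) {
        if (s == 1) lat$left[1, ] <- anchor else lat$right[1, ] <- anchor
      }
    }
    corners_by_finger[[finger]] <- lat
  }

  for (finger in names(finger_landmark_rows)) {
    lat <- corners_by_finger[[finger]]
    nseg <- nrow(lat$left) - 1L
    part_names <- if (finger == "thumb") c("proximal", "distal")
                  else c("proximal", "middle", "distal")
    for (k in seq_len(nseg)) {
      label <- paste0(finger, "_", part_names[k])
      segs[[label]] <- make_segment(label,
        rbind(lat$left[k, ], lat$left[k + 1, ],
              lat$right[k + 1, ], lat$right[k, ]),
        finger_corner_key)
    }
  }

  # palm quadrants: bottom chain along the wrist line, top chain
  # through the same base corners the finger segments use
  wl <- roi$wrist$left_point; wr <- roi$wrist$right_point
  thumb_mcp <- lm[3, ]
  if (sum((wl - thumb_mcp)^2) <= sum((wr - thumb_mcp)^2)) {
    b0 <- wl; b4 <- wr
  } else {
    b0 <- wr; b4 <- wl
  }
  b2 <- lm[1, ]                          # wrist landmark
  b1 <- (b0 + b2) / 2; b3 <- (b2 + b4) / 2
  bottom <- rbind(b0, b1, b2, b3, b4)

  outer_base <- function(finger, neighbour_mcp) {
    lat <- corners_by_finger[[finger]]
    cand <- rbind(lat$left[1, ], lat$right[1, ])
    d <- (cand[, 1] - neighbour_mcp[1])^2 + (cand[, 2] - neighbour_mcp[2])^2
    cand[which.max(d), ]
  }
  t0 <- outer_base("index", lm[10, ])      # radial corner, away from middle
  t4 <- outer_base("little", lm[14, ])     # ulnar corner, away from ring
  top <- rbind(t0, webs["index_middle", ], webs["middle_ring", ],
               webs["ring_little", ], t4)

  for (q in 1:4) {
    label <- paste0("palm_q", q)
    segs[[label]] <- make_segment(label,
      rbind(bottom[q, ], bottom[q + 1, ], top[q + 1, ], top[q, ]),
      palm_corner_key)
  }

  segs <- segs[segment_labels_18()]
  structure(list(segments = segs), class = "segment_decomposition")
}

#' @export
print.segment_decomposition <- function(x, ...) {
  cat(sprintf("<segment_decomposition: %d segments>\n", length(x$segments)))
  invisible(x)
}

#' Rasterize segment membership masks
#'
#' @param decomposition a `segment_decomposition`.
#' @param width,height raster dimensions in pixels.
#' @param expand outward offset of each corner (pixels) before
#'   rasterization; the small default compensates the half-open pixel
#'   test so shared segment edges leave no one-pixel seams.
#' @return named list of `W x H` logical matrices, one per segment.
#' @export
segment_masks <- function(decomposition, width, height, expand = 0.75) {
  lapply(decomposition$segments, function(s)
    polygon_raster_mask(s$corners, width, height, expand = expand))
}

# General polygon rasterization (even-odd), bbox-limited. `expand`
# moves each vertex radially away from the centroid by that many pixels.
polygon_raster_mask <- function(poly, width, height, expand = 0) {
  if (expand > 0) {
    ctr <- colMeans(poly)
    dirs <- sweep(poly, 2, ctr)
    lens <- sqrt(rowSums(dirs^2))
    lens[lens < 1e-9] <- 1
    poly <- poly + dirs / lens * expand
  }
  m <- matrix(FALSE, width, height)
  x0 <- max(1L, floor(min(poly[, 1])) + 1L)
  x1 <- min(width, ceiling(max(poly[, 1])) + 1L)
  y0 <- max(1L, floor(min(poly[, 2])) + 1L)
  y1 <- min(height, ceiling(max(poly[, 2])) + 1L)
  if (x0 > x1 || y0 > y1) return(m)
  xs <- (x0:x1) - 1; ys <- (y0:y1) - 1
  g <- expand.grid(x = xs, y = ys)
  inside <- points_in_polygon(g$x, g$y, poly)
  m[x0:x1, y0:y1] <- matrix(inside, length(xs), length(ys))
  m
}

#' Write a segment decomposition to JSON for inspection
#'
#' @param decomposition a `segment_decomposition`.
#' @param path output JSON path.
#' @export
write_segments_json <- function(decomposition, path) {
  obj <- lapply(decomposition$segments, function(s)
    list(label = s$label, corners = unname(s$corners),
         corner_key = s$corner_key))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_segments_json
#' @export
read_segments_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- lapply(obj, function(s) {
    corners <- as.matrix(s$corners)
    dimnames(corners) <- list(s$corner_key, c("x", "y"))
    list(label = s$label, corners = corners, corner_key = s$corner_key)
  })
  names(segs) <- vapply(segs, `[[`, character(1), "label")
  structure(list(segments = segs), class = "segment_decomposition")
}
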