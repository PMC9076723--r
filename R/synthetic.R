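# Synthetic hand-image generator
#
# A parametric hand is built from a superelliptical palm, five finger
# capsules (segment + radius) and a forearm capsule, in a canonical
# frame where y points down, the middle fingertip is near y = 0.1 and
# the wrist landmark sits at y = 0.93 (units of one canonical hand
# length). Every quantity the pipeline later estimates - the hand mask,
# the ROI above the wrist, the 21 landmarks, the web valleys, the wrist
# crossings, the fluorescent coverage - has a closed-form (or
# root-found) ground-truth counterpart in this frame, which is what
# makes pipeline recovery testable to pixel tolerances.

canonical_hand_geometry <- function() {
  fingers <- list(
    # bottom anchors sit inside the palm; adjacent capsules converge
    # downwards and splay at the tips, so each finger gap closes at a
    # sharp, analytically known crossing of the facing capsule sides,
    # well above the palm boundary
    index  = list(bottom = c(0.368, 0.560), tip = c(0.2645, 0.1737),
                  r = 0.0505),
    middle = list(bottom = c(0.456, 0.560), tip = c(0.4239, 0.1010),
                  r = 0.0520),
    ring   = list(bottom = c(0.544, 0.560), tip = c(0.5952, 0.1430),
                  r = 0.0500),
    little = list(bottom = c(0.632, 0.560), tip = c(0.7340, 0.2460),
                  r = 0.0490)
  )
  list(
    palm = list(cx = 0.50, cy = 0.73, a = 0.215, b = 0.20, n = 10),
    arm  = list(p0 = c(0.50, 0.88), p1 = c(0.50, 1.25), r = 0.105),
    thumb = list(bottom = c(0.300, 0.830), tip = c(0.110, 0.610), r = 0.052),
    fingers = fingers,
    wrist_y = 0.90,
    # landmark positions as fractions along each finger axis
    finger_fracs = c(mcp = 0.18, pip = 0.50, dip = 0.75, tip = 1.0),
    thumb_fracs  = c(cmc = 0.00, mcp = 0.25, ip = 0.62, tip = 1.0),
    hand_length = 0.80                  # wrist landmark to middle fingertip
  )
}

#' Parametric synthetic hand model
#'
#' @param handedness `"left"` or `"right"`.
#' @param side `"dorsal"` or `"palmar"`.
#' @param pose similarity pose mapping canonical coordinates (one hand
#'   length = 1) into pixels: list with `scale` (px per hand unit),
#'   `theta` (radians), `tx`, `ty` (px).
#' @param width,height image dimensions in pixels.
#' @param geometry canonical geometry; override for unusual hands.
#' @return an object of class `hand_model`.
#' @export
hand_model <- function(handedness = "right", side = "palmar",
                       pose = NULL, width = 756, height = 1008,
                       geometry = canonical_hand_geometry()) {
  handedness <- match.arg(handedness, c("left", "right"))
  side <- match.arg(side, c("dorsal", "palmar"))
  if (is.null(pose)) {
    scale <- 0.62 * height
    pose <- list(scale = scale, theta = 0,
                 tx = width / 2 - 0.41 * scale, ty = 0.04 * height)
  }
  # the camera sees the palmar side of a right hand with the thumb on
  # the low-x side; flipping either the hand or the viewed side mirrors
  # the silhouette
  mirror <- xor(handedness == "left", side == "dorsal")
  structure(list(handedness = handedness, side = side, pose = pose,
                 width = width, height = height, mirror = mirror,
                 geometry = geometry),
            class = "hand_model")
}

#' @export
print.hand_model <- function(x, ...) {
  cat(sprintf("<hand_model %s %s, %d x %d px, scale %.1f>\n",
              x$handedness, x$side, x$width, x$height, x$pose$scale))
  invisible(x)
}

# canonical -> pixel coordinates (mirror, then similarity pose)
model_to_image <- function(model, pts) {
  pts <- as.matrix(pts)
  if (model$mirror) pts[, 1] <- 1 - pts[, 1]
  apply_pose(pts, model$pose)
}

# pixel -> canonical
image_to_model <- function(model, pts) {
  pts <- as.matrix(pts)
  ct <- cos(model$pose$theta); st <- sin(model$pose$theta)
  x <- (pts[, 1] - model$pose$tx) / model$pose$scale
  y <- (pts[, 2] - model$pose$ty) / model$pose$scale
  q <- cbind(ct * x + st * y, -st * x + ct * y)
  if (model$mirror) q[, 1] <- 1 - q[, 1]
  q
}

# squared-distance-free capsule membership: distance from point to the
# segment p0-p1 compared to radius r, vectorized over points
capsule_member <- function(px, py, p0, p1, r) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx^2 + vy^2
  t <- ((px - p0[1]) * vx + (py - p0[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  dx <- px - (p0[1] + t * vx); dy <- py - (p0[2] + t * vy)
  dx * dx + dy * dy <= r * r
}

superellipse_member <- function(px, py, palm) {
  (abs((px - palm$cx) / palm$a))^palm$n +
    (abs((py - palm$cy) / palm$b))^palm$n <= 1
}

# half-width of the superellipse at vertical offset dy from the centre
superellipse_halfwidth <- function(palm, y) {
  u <- abs((y - palm$cy) / palm$b)
  if (u >= 1) return(NA_real_)
  palm$a * (1 - u^palm$n)^(1 / palm$n)
}

# V-notch wedges carved out of the silhouette at each finger valley.
# The raw capsule gaps close at a very shallow angle, which a raster
# cannot resolve; carving a wedge whose apex is the analytic valley
# point makes each web a sharp, raster-stable concavity whose deepest
# point is exactly the stored ground truth. Computed once per geometry
# (the thumb valley involves a root search) and cached.
.wedge_cache <- new.env(parent = emptyenv())

model_wedges <- function(geometry) {
  if (!is.null(.wedge_cache$geometry) &&
      identical(.wedge_cache$geometry, geometry))
    return(.wedge_cache$wedges)
  w <- compute_model_wedges(geometry)
  .wedge_cache$geometry <- geometry
  .wedge_cache$wedges <- w
  w
}

compute_model_wedges <- function(geometry) {
  g <- geometry
  f <- g$fingers
  unit <- function(v) v / vec_norm(v)
  gap_wedge <- function(capA, capB, half_angle = 20 * pi / 180,
                        radius = 0.055) {
    apex <- capsule_gap_valley(capA, capB)
    dirA <- unit(capA$tip - capA$bottom)
    dirB <- unit(capB$tip - capB$bottom)
    list(apex = apex, dir = unit(dirA + dirB),
         cos_half = cos(half_angle), radius = radius)
  }
  thumb_wedge <- local({
    apex <- thumb_palm_valley(g)
    dirT <- unit(g$thumb$tip - g$thumb$bottom)
    # palm boundary tangent at the apex, pointing up
    palm <- g$palm
    sx <- (apex[1] - palm$cx) / palm$a
    sy <- (apex[2] - palm$cy) / palm$b
    grad <- c(sign(sx) * abs(sx)^(palm$n - 1) / palm$a,
              sign(sy) * abs(sy)^(palm$n - 1) / palm$b)
    tang <- perp2(unit(grad))
    if (tang[2] > 0) tang <- -tang
    list(apex = apex, dir = unit(dirT + tang),
         cos_half = cos(25 * pi / 180), radius = 0.055)
  })
  list(thumb_index = thumb_wedge,
       index_middle = gap_wedge(f$index, f$middle),
       middle_ring = gap_wedge(f$middle, f$ring),
       ring_little = gap_wedge(f$ring, f$little))
}

wedge_member <- function(px, py, wedge) {
  dx <- px - wedge$apex[1]; dy <- py - wedge$apex[2]
  d2 <- dx * dx + dy * dy
  d <- sqrt(pmax(d2, 1e-300))
  (d2 <= wedge$radius^2) &
    ((dx * wedge$dir[1] + dy * wedge$dir[2]) / d >= wedge$cos_half)
}

model_membership_canonical <- function(g, q) {
  m <- superellipse_member(q[, 1], q[, 2], g$palm)
  m <- m | capsule_member(q[, 1], q[, 2], g$arm$p0, g$arm$p1, g$arm$r)
  m <- m | capsule_member(q[, 1], q[, 2], g$thumb$bottom, g$thumb$tip,
                          g$thumb$r)
  for (f in g$fingers)
    m <- m | capsule_member(q[, 1], q[, 2], f$bottom, f$tip, f$r)
  for (wd in model_wedges(g))
    m <- m & !wedge_member(q[, 1], q[, 2], wd)
  m
}

model_membership <- function(model, px, py) {
  q <- image_to_model(model, cbind(px, py))
  model_membership_canonical(model$geometry, q)
}

#' Ground-truth hand mask of a synthetic model
#'
#' @param model a [hand_model()].
#' @param roi_only clip to the region above the wrist line.
#' @return a [binary_mask()] (`width x height`).
#' @export
model_mask <- function(model, roi_only = FALSE) {
  model_masks(model)[[if (roi_only) "roi" else "hand"]]
}

# hand mask and ROI mask from one membership evaluation
model_masks <- function(model) {
  g <- expand.grid(x = seq_len(model$width) - 1,
                   y = seq_len(model$height) - 1)
  q <- image_to_model(model, cbind(g$x, g$y))
  m <- model_membership_canonical(model$geometry, q)
  hand <- binary_mask(matrix(m, model$width, model$height))
  roi <- binary_mask(matrix(m & (q[, 2] <= model$geometry$wrist_y),
                            model$width, model$height))
  list(hand = hand, roi = roi)
}

#' Ground-truth landmarks of a synthetic model
#'
#' @param model a [hand_model()].
#' @return a [landmark_set()] with `source = "synthetic"`.
#' @export
model_landmarks <- function(model) {
  g <- model$geometry
  lm <- matrix(NA_real_, 21, 2)
  axis_pts <- function(cap, fracs) {
    t(sapply(fracs, function(f) cap$bottom + f * (cap$tip - cap$bottom)))
  }
  # the wrist landmark sits directly below the middle-finger MCP, so
  # the 0-9 axis is vertical and the wrist line horizontal in the
  # canonical frame (which keeps the wrist crossings closed-form)
  mid <- g$fingers$middle
  mcp_x <- mid$bottom[1] + g$finger_fracs["mcp"] * (mid$tip[1] - mid$bottom[1])
  lm[1, ] <- c(mcp_x, g$wrist_y)
  lm[2:5, ] <- axis_pts(g$thumb, g$thumb_fracs)
  rows <- list(index = 6:9, middle = 10:13, ring = 14:17, little = 18:21)
  for (nm in names(rows))
    lm[rows[[nm]], ] <- axis_pts(g$fingers[[nm]], g$finger_fracs)
  landmark_set(model_to_image(model, lm), handedness = model$handedness,
               source = "synthetic")
}

# Analytic valley between two adjacent finger capsules: the crossing of
# the two facing offset boundary lines (each finger's axis shifted
# toward the gap by its radius).
capsule_gap_valley <- function(capA, capB) {
  # offset the axis of each capsule towards the other
  offset_line <- function(cap, towards) {
    d <- cap$tip - cap$bottom; d <- d / vec_norm(d)
    n <- perp2(d)
    mid_other <- (towards$bottom + towards$tip) / 2
    if (sum(n * (mid_other - cap$bottom)) < 0) n <- -n
    list(p = cap$bottom + cap$r * n, d = d)
  }
  la <- offset_line(capA, capB)
  lb <- offset_line(capB, capA)
  A <- cbind(la$d, -lb$d)
  rhs <- lb$p - la$p
  t <- solve(A, rhs)
  la$p + t[1] * la$d
}

# Analytic thumb-index valley: the point where the thumb capsule
# boundary crosses the palm superellipse on the finger side, found by a
# 1-D root search along the ellipse parameter.
thumb_palm_valley <- function(geometry) {
  palm <- geometry$palm; th <- geometry$thumb
  cap_dist <- function(p) {
    v <- th$tip - th$bottom
    t <- sum((p - th$bottom) * v) / sum(v^2)
    t <- min(max(t, 0), 1)
    vec_norm(p - (th$bottom + t * v))
  }
  ell <- function(theta) {
    # superellipse parametrisation with the correct quadrant signs
    c(palm$cx + palm$a * sign(cos(theta)) * abs(cos(theta))^(2 / palm$n),
      palm$cy + palm$b * sign(sin(theta)) * abs(sin(theta))^(2 / palm$n))
  }
  f <- function(theta) cap_dist(ell(theta)) - th$r
  # walk the upper-left quadrant of the palm (from the top towards the
  # thumb) for the first sign change
  thetas <- seq(-pi / 2, -1.45 * pi, length.out = 800)
  vals <- vapply(thetas, f, numeric(1))
  i <- which(vals[-1] * vals[-length(vals)] <= 0)[1]
  if (is.na(i)) stop("thumb capsule does not meet the palm boundary")
  root <- stats::uniroot(f, c(thetas[i], thetas[i + 1]), tol = 1e-10)$root
  ell(root)
}

#' Ground-truth web points of a synthetic model
#'
#' @param model a [hand_model()].
#' @return a `web_points` object.
#' @export
model_webs <- function(model) {
  g <- model$geometry
  f <- g$fingers
  webs <- rbind(
    thumb_index  = thumb_palm_valley(g),
    index_middle = capsule_gap_valley(f$index, f$middle),
    middle_ring  = capsule_gap_valley(f$middle, f$ring),
    ring_little  = capsule_gap_valley(f$ring, f$little)
  )
  webs <- model_to_image(model, webs)
  rownames(webs) <- c("thumb_index", "index_middle", "middle_ring",
                      "ring_little")
  colnames(webs) <- c("x", "y")
  structure(webs, class = c("web_points", class(webs)))
}

#' Ground-truth wrist crossings of a synthetic model
#'
#' The wrist line in the canonical frame is horizontal at the wrist
#' landmark; its crossings with the silhouette boundary are the extent
#' of the union of palm and forearm at that height.
#'
#' @param model a [hand_model()].
#' @return a `wrist_points` object (left = thumb side in the canonical
#'   frame before mirroring).
#' @export
model_wrist <- function(model) {
  g <- model$geometry
  y <- g$wrist_y
  hw_palm <- superellipse_halfwidth(g$palm, y)
  # forearm capsule half-width at height y (vertical axis at x = 0.5)
  hw_arm <- local({
    p0 <- g$arm$p0; p1 <- g$arm$p1; r <- g$arm$r
    if (y >= min(p0[2], p1[2]) && y <= max(p0[2], p1[2])) r
    else {
      dy <- min(abs(y - p0[2]), abs(y - p1[2]))
      if (dy >= r) NA_real_ else sqrt(r^2 - dy^2)
    }
  })
  hw <- max(hw_palm, hw_arm, na.rm = TRUE)
  pts <- model_to_image(model, rbind(c(0.5 - hw, y), c(0.5 + hw, y)))
  # label the two crossings by the side convention of wrist_points():
  # "left" is the negative side of the perpendicular direction of the
  # 0-9 axis in image space
  lm <- landmark_points(model_landmarks(model))
  axis <- lm[10, ] - lm[1, ]
  d <- perp2(axis / vec_norm(axis))
  t <- as.numeric((pts - rbind(lm[1, ], lm[1, ])) %*% d)
  structure(list(left_point = pts[which.min(t), ],
                 right_point = pts[which.max(t), ]),
            class = "wrist_points")
}

#' Ground-truth decomposition and ROI of a synthetic model
#'
#' Builds the `hand_roi` and 18-segment decomposition directly from the
#' analytic mask, landmarks, webs and wrist crossings (no rendered
#' image involved).
#'
#' @param model a [hand_model()].
#' @return list with `roi` (a `hand_roi`), `webs` and `decomposition`.
#' @export
model_decomposition <- function(model) {
  masks <- model_masks(model)
  contour <- largest_contour(masks$hand)
  lms <- model_landmarks(model)
  wrist <- model_wrist(model)
  roi <- structure(list(mask = masks$roi, contour = contour,
                        wrist = wrist, landmarks = lms),
                   class = "hand_roi")
  webs <- model_webs(model)
  list(roi = roi, webs = webs,
       decomposition = decompose_segments(roi, lms, webs))
}

# ---- rendering -------------------------------------------------------------

clip8 <- function(x) pmin(pmax(round(x), 0), 255)

render_channels <- function(member, width, height, fg, bg, noise_sd, seed) {
  if (!is.null(seed)) set.seed(seed)
  a <- array(0, dim = c(width, height, 3))
  for (k in 1:3) {
    ch <- ifelse(member, fg[k], bg[k])
    if (noise_sd > 0) ch <- ch + stats::rnorm(length(ch), 0, noise_sd)
    a[, , k] <- matrix(clip8(ch), width, height)
  }
  a
}

#' Render the white-light image of a synthetic hand
#'
#' Skin-toned silhouette on a near-black background with mild additive
#' Gaussian noise. The returned ground truth stores the analytic hand
#' mask, ROI mask, landmarks, web valleys and wrist crossings.
#'
#' @param model a [hand_model()].
#' @param seed integer seed for the pixel noise (`NULL` = do not touch
#'   the RNG state).
#' @param noise_sd additive noise standard deviation in 8-bit counts.
#' @return list with `image` (an [rgb_image()]) and `ground_truth`.
#' @export
render_hand <- function(model, seed = NULL, noise_sd = 3) {
  masks <- model_masks(model)
  img <- render_channels(as_plain_mask(masks$hand), model$width,
                         model$height,
                         fg = c(214, 128, 94), bg = c(12, 12, 16),
                         noise_sd = noise_sd, seed = seed)
  gt <- list(mask = masks$hand,
             roi_mask = masks$roi,
             landmarks = model_landmarks(model),
             webs = model_webs(model),
             wrist = model_wrist(model))
  list(image = rgb_image(img), ground_truth = gt)
}

#' Render the UV-lamp image of a synthetic hand
#'
#' Covered pixels are rendered fluorescent green (hue inside the 25-97
#' band, brightness above 60); uncovered hand pixels are dark bluish;
#' a `residual_rate` fraction of the remaining pixels is rendered
#' green-hued but dim (brightness below 60), emulating residual
#' fluorescent concentrate from earlier tasks that the brightness
#' filter must reject.
#'
#' @param model a [hand_model()].
#' @param covered_mask a [binary_mask()] of ground-truth coverage
#'   (will be clipped to the hand ROI).
#' @param residual_rate fraction of non-covered pixels rendered as dim
#'   green residue.
#' @param seed integer seed (`NULL` = leave RNG alone).
#' @param noise_sd additive noise standard deviation (8-bit counts).
#' @return list with `image`, `covered_mask` (the clipped ground
#'   truth) and `covered_fraction` (covered / ROI pixels).
#' @export
render_uv <- function(model, covered_mask, residual_rate = 0,
                      seed = NULL, noise_sd = 0) {
  masks <- model_masks(model)
  roi <- masks$roi
  hand <- masks$hand
  cov <- as_plain_mask(covered_mask) & as_plain_mask(roi)
  if (!is.null(seed)) set.seed(seed)
  handm <- as_plain_mask(hand)
  residual <- matrix(FALSE, model$width, model$height)
  if (residual_rate > 0) {
    cand <- which(!cov)
    take <- cand[stats::runif(length(cand)) < residual_rate]
    residual[take] <- TRUE
  }
  a <- array(0, dim = c(model$width, model$height, 3))
  col_cov <- c(45, 215, 70)      # bright green: hue ~63, brightness 215
  col_hand <- c(22, 26, 42)      # dark blue-grey: brightness 42, rejected
  col_res <- c(10, 48, 14)       # dim green: hue in band, brightness 48
  col_bg <- c(6, 6, 10)
  for (k in 1:3) {
    ch <- matrix(col_bg[k], model$width, model$height)
    ch[handm] <- col_hand[k]
    ch[residual] <- col_res[k]
    ch[cov] <- col_cov[k]
    if (noise_sd > 0) ch <- ch + stats::rnorm(length(ch), 0, noise_sd)
    a[, , k] <- clip8(ch)
  }
  nroi <- sum(roi)
  list(image = rgb_image(a), covered_mask = binary_mask(cov),
       covered_fraction = if (nroi > 0) sum(cov) / nroi else NA_real_)
}
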