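# Synthetic study generation
#
# A study mirrors the experimental design of a fluorescent hand-hygiene
# assessment: every participant performs 22 tasks (9 individual-step
# tasks and 2 complete-technique repeats, once photographed dorsally,
# once palmarly), each with both hands. Coverage is drawn per step from
# a region model defined on the 18-segment layout, so the expected
# aggregated probability of every template pixel - and therefore every
# step's analytic coverage-loss fraction - is known in closed form.

#' The 22-task study table
#'
#' Tasks 1-9 are the individual steps photographed dorsally (step 1
#' alone, then step 1 followed by each other step), tasks 10-11 the
#' complete technique dorsally, and tasks 12-22 the same for the palmar
#' side.
#'
#' @return data frame with columns `task_id`, `side`, `task_type`,
#'   `step` (NA for complete-technique tasks).
#' @export
study_tasks <- function() {
  steps <- step_labels()
  data.frame(
    task_id = 1:22,
    side = rep(c("dorsal", "palmar"), each = 11),
    task_type = rep(c(rep("individual", 9), "complete", "complete"), 2),
    step = rep(c(steps, NA, NA), 2),
    stringsAsFactors = FALSE)
}

segment_groups <- function() {
  fingers <- c("index", "middle", "ring", "little")
  list(
    palm_quads = paste0("palm_q", 1:4),
    fingers_proximal = paste0(fingers, "_proximal"),
    fingers_middle = paste0(fingers, "_middle"),
    fingers_distal = paste0(fingers, "_distal"),
    fingers_all = c(paste0(fingers, "_proximal"),
                    paste0(fingers, "_middle"),
                    paste0(fingers, "_distal")),
    thumb = c("thumb_proximal", "thumb_distal"))
}

rule <- function(sides, hands, segments, prob) {
  list(sides = sides, hands = hands, segments = segments, prob = prob)
}

#' Default per-step coverage model
#'
#' Each step is a list of rules; a rule gives the hand sides and hands
#' it applies to, the segment labels it covers and the probability that
#' a participant actually covers that region when performing the step.
#' The defaults encode the mechanics of the six-step technique: step 1
#' reliably covers the palmar surfaces except the thumb (often missed);
#' steps 2R/2L cover the opposite dorsum; step 3 recovers palmar areas
#' step 1 already covers (making it redundant by construction, as are
#' 6R/6L whose palmar fingertip regions step 1 also reaches); step 4
#' covers the backs of the fingers; 5R/5L the thumbs.
#'
#' @return named list of steps, each a list of rules.
#' @export
default_step_model <- function() {
  g <- segment_groups()
  both <- c("left", "right")
  list(
    "1" = list(rule("palmar", both, c(g$palm_quads, g$fingers_all), 1.0),
               rule("palmar", both, g$thumb, 0.5)),
    "2R" = list(rule("dorsal", "left", g$palm_quads, 1.0),
                rule("dorsal", "left", g$fingers_proximal, 0.9)),
    "2L" = list(rule("dorsal", "right", g$palm_quads, 1.0),
                rule("dorsal", "right", g$fingers_proximal, 0.9)),
    "3" = list(rule("palmar", both,
                    c(g$palm_quads, g$fingers_proximal, g$fingers_middle),
                    1.0)),
    "4" = list(rule("dorsal", both, c(g$fingers_middle, g$fingers_distal),
                    1.0)),
    "5R" = list(rule(c("dorsal", "palmar"), "left", g$thumb, 0.9)),
    "5L" = list(rule(c("dorsal", "palmar"), "right", g$thumb, 0.9)),
    "6R" = list(rule("palmar", "right", g$fingers_distal, 0.9)),
    "6L" = list(rule("palmar", "left", g$fingers_distal, 0.9)))
}

#' Synthetic study design
#'
#' @param n_participants number of participants.
#' @param seed RNG seed controlling every random draw of the study.
#' @param image_width,image_height rendered image size in pixels.
#' @param step_model per-step coverage model
#'   (see [default_step_model()]).
#' @param residual_rate fraction of non-covered pixels rendered as dim
#'   green residual fluorescence in the UV images.
#' @param landmark_jitter_sd Gaussian jitter (pixels) added to the
#'   landmark sidecars, emulating detector noise. The default is 2 px
#'   at the generator's 756 px reference image width, scaled with
#'   `image_width` so the relative detector noise is resolution
#'   independent.
#' @param participant_sd scale of the per-participant diligence effect:
#'   a participant factor `d ~ U(-1, 1)` shifts every fractional rule
#'   probability `p` by `d * participant_sd * min(p, 1 - p)`, leaving
#'   the population mean unchanged.
#' @param noise_sd white-light image noise (8-bit counts).
#' @param pose_jitter list with `theta` (radians), `scale` (relative)
#'   and `shift` (relative to image width) jitter half-ranges.
#' @return a `study_design` object.
#' @export
study_design <- function(n_participants = 30, seed = 1,
                         image_width = 240, image_height = 300,
                         step_model = default_step_model(),
                         residual_rate = 0.05,
                         landmark_jitter_sd = 2 * image_width / 756,
                         participant_sd = 0.5,
                         noise_sd = 3,
                         pose_jitter = list(theta = 0.10, scale = 0.05,
                                            shift = 0.02)) {
  stopifnot(n_participants >= 1)
  for (s in names(step_model))
    for (r in step_model[[s]])
      stopifnot(r$prob >= 0, r$prob <= 1)
  structure(list(n_participants = n_participants, seed = seed,
                 image_width = image_width, image_height = image_height,
                 step_model = step_model, residual_rate = residual_rate,
                 landmark_jitter_sd = landmark_jitter_sd,
                 participant_sd = participant_sd, noise_sd = noise_sd,
                 pose_jitter = pose_jitter),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design: %d participants, %d x %d px, seed %d>\n",
              x$n_participants, x$image_width, x$image_height, x$seed))
  invisible(x)
}

# effective probability of a rule for participant diligence d
effective_prob <- function(prob, d, participant_sd) {
  prob + d * participant_sd * pmin(prob, 1 - prob)
}

# rules of one step applicable to (side, hand)
applicable_rules <- function(step_model, step, side, hand) {
  Filter(function(r) side %in% r$sides && hand %in% r$hands,
         step_model[[step]])
}

# steps performed during a task
task_steps <- function(task_row) {
  if (task_row$task_type == "complete") step_labels()
  else unique(c("1", task_row$step))
}

#' Analytic per-segment coverage probability of a task
#'
#' Marginal probability (over participants and draws) that each of the
#' 18 segments is covered after performing the task on the given hand
#' and photographed side. The per-participant diligence effect is
#' integrated out numerically.
#'
#' @param design a [study_design()].
#' @param task_row one row of [study_tasks()].
#' @param hand `"left"` or `"right"`.
#' @return named numeric vector over the 18 segment labels.
#' @export
analytic_task_probability <- function(design, task_row, hand) {
  labels <- segment_labels_18()
  steps <- task_steps(task_row)
  rules <- list()
  for (s in steps)
    rules <- c(rules, applicable_rules(design$step_model, s,
                                       task_row$side, hand))
  if (length(rules) == 0)
    return(setNames(rep(0, length(labels)), labels))
  dgrid <- seq(-1, 1, length.out = 201)        # trapezoid over U(-1, 1)
  wts <- rep(1, length(dgrid)); wts[c(1, length(dgrid))] <- 0.5
  wts <- wts / sum(wts)
  out <- setNames(numeric(length(labels)), labels)
  for (lab in labels) {
    touching <- Filter(function(r) lab %in% r$segments, rules)
    if (length(touching) == 0) next
    not_cov <- rep(1, length(dgrid))
    for (r in touching)
      not_cov <- not_cov *
        (1 - effective_prob(r$prob, dgrid, design$participant_sd))
    out[lab] <- sum(wts * (1 - not_cov))
  }
  out
}

#' Analytic coverage-loss table of a design
#'
#' Computes, for every step except the prerequisite and every
#' (side, hand), the expected probability-weighted coverage-loss
#' fraction on the template: per-pixel max-combination of the analytic
#' task probabilities with and without the step, subtracted and
#' averaged over the template outline.
#'
#' @param design a [study_design()].
#' @param templates template set from [build_template_set()].
#' @return data frame with columns `step`, `side_key`,
#'   `loss_weighted`.
#' @export
analytic_loss_table <- function(design, templates) {
  tasks <- study_tasks()
  rows <- list()
  for (key in names(templates)) {
    tpl <- templates[[key]]
    side <- tpl$identity$side; hand <- tpl$identity$hand
    segs <- segment_masks(tpl$segments, tpl$width, tpl$height)
    outline <- as_plain_mask(tpl$outline_mask)
    n_out <- sum(outline)
    # per-step per-pixel analytic probability (max over the segments
    # that contain the pixel)
    ind <- tasks[tasks$task_type == "individual" & tasks$side == side, ]
    pix <- list()
    for (i in seq_len(nrow(ind))) {
      pseg <- analytic_task_probability(design, ind[i, ], hand)
      pm <- matrix(0, tpl$width, tpl$height)
      for (lab in names(pseg))
        if (pseg[lab] > 0) pm[segs[[lab]]] <- pmax(pm[segs[[lab]]], pseg[lab])
      pix[[ind$step[i]]] <- pm
    }
    all_max <- Reduce(pmax, pix)
    for (s in setdiff(names(pix), "1")) {
      wo_max <- Reduce(pmax, pix[setdiff(names(pix), s)])
      excl <- pmax(all_max - wo_max, 0)
      rows[[length(rows) + 1]] <- data.frame(
        step = s, side_key = key,
        loss_weighted = sum(excl[outline]) / n_out,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a complete synthetic study on disk
#'
#' Draws per-participant, per-task coverage from the design's step
#' model, renders the paired white-light / UV images, writes landmark
#' sidecars (with detector-like jitter), a manifest CSV and a
#' ground-truth JSON (per-observation covered fractions and the
#' analytic per-task segment probabilities). Fully deterministic given
#' the design seed.
#'
#' @param design a [study_design()].
#' @param out_dir output directory (created).
#' @return list with `manifest` (data frame), `manifest_path`,
#'   `ground_truth` (list) invisibly; everything is also on disk.
#' @export
simulate_study <- function(design, out_dir) {
  stopifnot(inherits(design, "study_design"))
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  set.seed(design$seed)
  tasks <- study_tasks()
  W <- design$image_width; H <- design$image_height
  pj <- design$pose_jitter
  rows <- list()
  obs_gt <- list()
  for (p in seq_len(design$n_participants)) {
    d_p <- stats::runif(1, -1, 1)
    for (t in seq_len(nrow(tasks))) {
      task <- tasks[t, ]
      for (hand in c("left", "right")) {
        # coverage draws
        covered_labels <- character(0)
        for (s in task_steps(task)) {
          for (r in applicable_rules(design$step_model, s, task$side, hand)) {
            pe <- effective_prob(r$prob, d_p, design$participant_sd)
            if (stats::runif(1) < pe)
              covered_labels <- union(covered_labels, r$segments)
          }
        }
        # pose
        scale <- 0.62 * H * (1 + stats::runif(1, -pj$scale, pj$scale))
        theta <- stats::runif(1, -pj$theta, pj$theta)
        tx <- W / 2 - 0.41 * scale + stats::runif(1, -pj$shift, pj$shift) * W
        ty <- 0.04 * H + stats::runif(1, -pj$shift, pj$shift) * H
        model <- hand_model(hand, task$side,
                            pose = list(scale = scale, theta = theta,
                                        tx = tx, ty = ty),
                            width = W, height = H)
        parts <- model_decomposition(model)
        cov <- matrix(FALSE, W, H)
        for (lab in covered_labels)
          cov <- cov | polygon_raster_mask(
            parts$decomposition$segments[[lab]]$corners, W, H,
            expand = 0.75)
        cov <- cov & as_plain_mask(parts$roi$mask)
        wl <- render_hand(model, seed = NULL, noise_sd = design$noise_sd)
        uv <- render_uv(model, binary_mask(cov),
                        residual_rate = design$residual_rate,
                        seed = NULL, noise_sd = 0)
        # jittered landmark sidecar (detector emulation)
        lmj <- landmark_points(parts$roi$landmarks) +
          matrix(stats::rnorm(42, 0, design$landmark_jitter_sd), 21, 2)
        stem <- sprintf("P%02d_T%02d_%s", p, task$task_id, hand)
        wl_path <- file.path("images", paste0(stem, "_wl.png"))
        uv_path <- file.path("images", paste0(stem, "_uv.png"))
        lm_path <- file.path("images", paste0(stem, "_landmarks.json"))
        write_image_rgb(wl$image, file.path(out_dir, wl_path))
        write_image_rgb(uv$image, file.path(out_dir, uv_path))
        write_landmarks(landmark_set(lmj, handedness = hand,
                                     source = "synthetic"),
                        file.path(out_dir, lm_path))
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, task_id = task$task_id,
          task_type = task$task_type,
          step = ifelse(is.na(task$step), "", task$step),
          hand = hand, side = task$side,
          white_light = wl_path, uv = uv_path, landmarks = lm_path,
          stringsAsFactors = FALSE)
        obs_gt[[stem]] <- list(covered_fraction = uv$covered_fraction,
                               covered_segments = sort(covered_labels))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  # analytic per-task segment probabilities
  analytic <- list()
  for (t in seq_len(nrow(tasks))) {
    for (hand in c("left", "right")) {
      key <- sprintf("T%02d_%s", tasks$task_id[t], hand)
      analytic[[key]] <- as.list(
        analytic_task_probability(design, tasks[t, ], hand))
    }
  }
  ground_truth <- list(
    n_participants = design$n_participants, seed = design$seed,
    image_width = W, image_height = H,
    residual_rate = design$residual_rate,
    observations = obs_gt,
    analytic_task_probability = analytic)
  jsonlite::write_json(ground_truth,
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, manifest_path = manifest_path,
                 ground_truth = ground_truth))
}
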