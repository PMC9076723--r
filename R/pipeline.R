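#' Run configuration for a study analysis
#'
#' @param template_resolution template hand length in pixels. The
#'   default (360) keeps full-study runs fast while leaving per-segment
#'   warps comfortably oversampled relative to desk-scale input images.
#' @param thresholds [fluorescence_thresholds()] for UV extraction.
#' @param quality_floor minimum valid/outline ratio for
#'   [quality_flag()].
#' @param loss_threshold threshold of the thresholded loss variant.
#' @param templates optional prebuilt template set (else built at run
#'   time at `template_resolution`).
#' @param seed seed for any randomized processing (the pipeline itself
#'   is deterministic; the seed is recorded in the report).
#' @return a `run_config` object.
#' @export
run_config <- function(template_resolution = 360,
                       thresholds = fluorescence_thresholds(),
                       quality_floor = 0.80,
                       loss_threshold = 0.5,
                       templates = NULL,
                       seed = 1) {
  structure(list(template_resolution = template_resolution,
                 thresholds = thresholds,
                 quality_floor = quality_floor,
                 loss_threshold = loss_threshold,
                 templates = templates, seed = seed),
            class = "run_config")
}

#' Read a study manifest CSV
#'
#' @param path manifest CSV with columns `participant`, `task_id`,
#'   `task_type`, `step`, `hand`, `side`, `white_light`, `uv`,
#'   `landmarks` (paths relative to the manifest's directory).
#' @return data frame with an attribute `base_dir`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = list(step = "character"))
  need <- c("participant", "task_id", "task_type", "step", "hand", "side",
            "white_light", "uv", "landmarks")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0)
    stop("manifest lacks columns: ", paste(missing, collapse = ", "))
  attr(m, "base_dir") <- dirname(normalizePath(path))
  m
}

#' Process one observation through segmentation, extraction and mapping
#'
#' Runs the per-image pipeline: hand segmentation of the white-light
#' image, wrist line and ROI, web points, 18-segment decomposition,
#' fluorescence extraction from the UV image, warp onto the template,
#' error correction and quality check.
#'
#' @param white_light,uv [rgb_image()]s (or file paths).
#' @param landmarks a [landmark_set()] (or sidecar path).
#' @param template the `standard_template` for this (hand, side).
#' @param thresholds [fluorescence_thresholds()].
#' @param quality_floor see [quality_flag()].
#' @param identity optional identity tag.
#' @return list with `mapped` (error-corrected `mapped_coverage`),
#'   `quality`, `coverage_fraction` (image-space covered/ROI) and
#'   `roi`.
#' @export
process_observation <- function(white_light, uv, landmarks, template,
                                thresholds = fluorescence_thresholds(),
                                quality_floor = 0.80, identity = NULL) {
  if (is.character(white_light)) white_light <- read_image_rgb(white_light)
  if (is.character(uv)) uv <- read_image_rgb(uv)
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  mask <- segment_hand(white_light)
  contour <- largest_contour(mask)
  wrist <- wrist_points(contour, landmarks)
  roi <- extract_roi(attr(contour, "component_mask"), contour, wrist,
                     landmarks)
  webs <- web_points(contour, landmarks)
  decomposition <- decompose_segments(roi, landmarks, webs)
  fluor <- extract_fluorescence(uv, thresholds)
  cov <- coverage_in_roi(fluor, roi)
  mapped <- map_to_template(cov, roi, decomposition, template,
                            identity = identity)
  mapped <- correct_errors(mapped, template)
  quality <- quality_flag(mapped, template, floor = quality_floor)
  list(mapped = mapped, quality = quality,
       coverage_fraction = coverage_percentage(cov, roi), roi = roi)
}

side_key_of <- function(side, hand) paste(side, hand, sep = "_")

#' Run a full study analysis over a manifest
#'
#' Executes the five-stage pipeline for every observation in the
#' manifest, aggregates mapped observations per (task, hand, side),
#' computes per-participant coverage of the complete technique with
#' the side correlations, the per-step coverage-loss table and the
#' accumulation-consistency check. Observation-level failures are
#' quarantined (counted with reasons), never fatal.
#'
#' @param manifest a manifest data frame from [read_manifest()] (or a
#'   path to one).
#' @param config a [run_config()].
#' @param progress print progress every 100 observations.
#' @return a `study_report` (list); see the elements in the examples.
#' @export
run_study <- function(manifest, config = run_config(), progress = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  base_dir <- attr(manifest, "base_dir")
  if (is.null(base_dir)) base_dir <- "."
  templates <- config$templates
  if (is.null(templates))
    templates <- build_template_set(config$template_resolution)
  set.seed(config$seed)

  # streaming per-group aggregation: group = (task_id, hand)
  groups <- list()
  discarded <- list()
  cov_rows <- list()
  n_total <- nrow(manifest)
  for (i in seq_len(n_total)) {
    row <- manifest[i, ]
    key <- sprintf("T%02d_%s", row$task_id, row$hand)
    skey <- side_key_of(row$side, row$hand)
    tpl <- templates[[skey]]
    if (is.null(tpl)) stop("missing template set entry: ", skey)
    res <- tryCatch({
      obs <- process_observation(
        file.path(base_dir, row$white_light),
        file.path(base_dir, row$uv),
        file.path(base_dir, row$landmarks),
        tpl, thresholds = config$thresholds,
        quality_floor = config$quality_floor,
        identity = list(participant = row$participant,
                        task = row$task_id, hand = row$hand,
                        side = row$side))
      if (!obs$quality$pass)
        list(ok = FALSE, reason = paste("quality:",
             paste(obs$quality$reasons, collapse = "; ")))
      else list(ok = TRUE, obs = obs)
    }, error = function(e) {
      msg <- conditionMessage(e)
      reason <- if (grepl("file not found|cannot open", msg)) "io" else msg
      list(ok = FALSE, reason = reason)
    })
    if (!res$ok) {
      discarded[[length(discarded) + 1]] <- data.frame(
        participant = row$participant, task_id = row$task_id,
        hand = row$hand, reason = res$reason, stringsAsFactors = FALSE)
      next
    }
    obs <- res$obs
    if (is.null(groups[[key]])) {
      d <- dim(obs$mapped$valid)
      groups[[key]] <- list(cov = matrix(0L, d[1], d[2]),
                            val = matrix(0L, d[1], d[2]), n = 0L,
                            task_id = row$task_id, hand = row$hand,
                            side = row$side,
                            task_type = row$task_type, step = row$step)
    }
    g <- groups[[key]]
    g$cov <- g$cov + as_plain_mask(obs$mapped$covered)
    g$val <- g$val + as_plain_mask(obs$mapped$valid)
    g$n <- g$n + 1L
    groups[[key]] <- g
    if (row$task_type == "complete")
      cov_rows[[length(cov_rows) + 1]] <- data.frame(
        participant = row$participant, hand = row$hand, side = row$side,
        coverage = obs$coverage_fraction, stringsAsFactors = FALSE)
    if (progress && i %% 100 == 0)
      message(sprintf("processed %d / %d observations", i, n_total))
  }

  aggregated <- lapply(groups, function(g) {
    prob <- matrix(NA_real_, nrow(g$cov), ncol(g$cov))
    nz <- g$val > 0
    prob[nz] <- g$cov[nz] / g$val[nz]
    structure(list(probability = prob, count = g$val,
                   n_observations = g$n,
                   identity = list(task = g$task_id, hand = g$hand,
                                   side = g$side, task_type = g$task_type,
                                   step = g$step)),
              class = "aggregated_map")
  })

  # per-step maps per side key; complete map per side key
  maps_by_side <- list(); complete_by_side <- list()
  for (key in names(aggregated)) {
    agg <- aggregated[[key]]
    skey <- side_key_of(agg$identity$side, agg$identity$hand)
    if (agg$identity$task_type == "individual") {
      maps_by_side[[skey]][[agg$identity$step]] <- agg
    } else {
      complete_by_side[[skey]] <- c(complete_by_side[[skey]], list(agg))
    }
  }
  # pool the two complete-technique repeats per side
  complete_by_side <- lapply(complete_by_side, function(lst) {
    if (length(lst) == 1) return(lst[[1]])
    cov <- Reduce(`+`, lapply(lst, function(a) {
      x <- a$probability; x[is.na(x)] <- 0; x * a$count }))
    val <- Reduce(`+`, lapply(lst, `[[`, "count"))
    prob <- matrix(NA_real_, nrow(val), ncol(val))
    nz <- val > 0
    prob[nz] <- cov[nz] / val[nz]
    structure(list(probability = prob, count = val,
                   n_observations = sum(vapply(lst, `[[`, integer(1),
                                               "n_observations")),
                   identity = lst[[1]]$identity),
              class = "aggregated_map")
  })

  losses <- if (length(maps_by_side) > 0)
    loss_table(maps_by_side, templates, threshold = config$loss_threshold)
  else NULL

  accumulation <- list()
  for (skey in names(maps_by_side)) {
    if (!is.null(complete_by_side[[skey]]))
      accumulation[[skey]] <- validate_accumulation(
        maps_by_side[[skey]], complete_by_side[[skey]])
  }

  per_participant <- if (length(cov_rows) > 0) {
    pp <- do.call(rbind, cov_rows)
    stats::aggregate(coverage ~ participant + hand + side, data = pp,
                     FUN = mean)
  } else NULL

  correlations <- NULL
  coverage_summary <- NULL
  if (!is.null(per_participant) &&
      length(unique(per_participant$participant)) >= 3) {
    correlations <- side_correlations(per_participant)
    coverage_summary <- stats::aggregate(
      coverage ~ side, data = per_participant,
      FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
    coverage_summary <- data.frame(
      side = coverage_summary$side,
      mean = coverage_summary$coverage[, "mean"],
      sd = coverage_summary$coverage[, "sd"])
  }

  discarded_df <- if (length(discarded) > 0) do.call(rbind, discarded)
                  else NULL
  structure(list(
    config = list(template_resolution = config$template_resolution,
                  thresholds = unclass(config$thresholds),
                  quality_floor = config$quality_floor,
                  loss_threshold = config$loss_threshold,
                  seed = config$seed),
    counts = list(total = n_total,
                  processed = n_total - length(discarded),
                  discarded = length(discarded)),
    discarded = discarded_df,
    aggregated = aggregated,
    maps_by_side = maps_by_side,
    complete_by_side = complete_by_side,
    per_participant = per_participant,
    correlations = correlations,
    coverage_summary = coverage_summary,
    loss = losses,
    accumulation = accumulation,
    templates = templates),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %d observations (%d processed, %d discarded)>\n",
              x$counts$total, x$counts$processed, x$counts$discarded))
  if (!is.null(x$coverage_summary)) {
    cat("complete-technique coverage:\n")
    print(x$coverage_summary)
  }
  invisible(x)
}

report_to_json_list <- function(report) {
  agg_summ <- lapply(report$aggregated, function(a) list(
    task = a$identity$task, hand = a$identity$hand,
    side = a$identity$side, step = a$identity$step,
    n_observations = a$n_observations,
    mean_probability = mean(a$probability, na.rm = TRUE),
    defined_px = sum(a$count > 0)))
  list(
    config = report$config,
    counts = report$counts,
    discarded = if (is.null(report$discarded)) list()
                else report$discarded,
    aggregated = agg_summ,
    coverage_summary = if (is.null(report$coverage_summary)) NULL
                       else report$coverage_summary,
    correlations = if (is.null(report$correlations)) NULL else list(
      r = report$correlations$r, p = report$correlations$p,
      n = report$correlations$n),
    loss = if (is.null(report$loss)) NULL else report$loss,
    accumulation = report$accumulation)
}

#' Write a study report to disk
#'
#' Writes `report.json` (configuration, counts, aggregate summaries,
#' correlations, loss table, accumulation check), `loss_table.csv`,
#' `per_participant.csv` and one four-category PNG per aggregated
#' (task, hand) map (darker = less likely to be covered; black =
#' no data).
#'
#' @param report a `study_report` from [run_study()].
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_json_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  if (!is.null(report$loss))
    utils::write.csv(report$loss, file.path(out_dir, "loss_table.csv"),
                     row.names = FALSE)
  if (!is.null(report$per_participant))
    utils::write.csv(report$per_participant,
                     file.path(out_dir, "per_participant.csv"),
                     row.names = FALSE)
  if (length(report$aggregated) == 0) {
    warning("report has no aggregated maps; no category PNGs written")
    return(invisible(out_dir))
  }
  shades <- c(0.25, 0.5, 0.75, 1)
  for (key in names(report$aggregated)) {
    cat_ <- quantize_map(report$aggregated[[key]])
    img <- matrix(0, nrow(cat_), ncol(cat_))
    ok <- !is.na(cat_)
    img[ok] <- shades[cat_[ok]]
    write_mask_png_gray(img, file.path(out_dir,
                                       paste0("category_", key, ".png")))
  }
  invisible(out_dir)
}

write_mask_png_gray <- function(values, path) {
  EBImage::writeImage(EBImage::Image(values), path)
  invisible(path)
}
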