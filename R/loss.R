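# Step-exclusion coverage-loss analysis
#
# The six-step technique is labelled 1, 2R, 2L, 3, 4, 5R, 5L, 6R, 6L.
# Step 1 (palm to palm) is the prerequisite that spreads the handrub,
# so every individual-step task includes it and it can never be the
# excluded step.

step_labels <- function() c("1", "2R", "2L", "3", "4", "5R", "5L", "6R", "6L")

check_step_set <- function(steps) {
  steps <- as.character(steps)
  if (length(steps) == 0) stop("empty step set")
  bad <- setdiff(steps, step_labels())
  if (length(bad) > 0)
    stop("unknown step labels: ", paste(bad, collapse = ", "))
  if (!"1" %in% steps)
    stop("step 1 is a necessary prerequisite and must be included")
  steps
}

#' Combine per-step probability maps by per-pixel maximum
#'
#' The probability that a template point is covered after performing a
#' combination of steps is estimated as the maximum probability across
#' the included steps at that point. Pixels missing from some steps use
#' the maximum over the steps where they are defined; pixels defined
#' nowhere stay NA.
#'
#' @param step_maps named list of `aggregated_map` (names are step
#'   labels).
#' @param steps character vector of step labels to combine (must
#'   include `"1"`).
#' @return a `combined_map`: list with `probability`, `steps`,
#'   `identity`.
#' @export
combine_steps <- function(step_maps, steps = names(step_maps)) {
  steps <- check_step_set(steps)
  missing <- setdiff(steps, names(step_maps))
  if (length(missing) > 0)
    stop("no aggregated map for step(s): ", paste(missing, collapse = ", "))
  first <- step_maps[[steps[1]]]
  d <- dim(first$probability)
  prob <- matrix(NA_real_, d[1], d[2])
  for (s in steps) {
    p <- step_maps[[s]]$probability
    if (!identical(dim(p), d)) stop("step maps have differing dimensions")
    take <- !is.na(p) & (is.na(prob) | p > prob)
    prob[take] <- p[take]
  }
  structure(list(probability = prob, steps = steps,
                 identity = first$identity),
            class = "combined_map")
}

#' Exclusive coverage and coverage loss of one step
#'
#' Subtracts the combined map of all steps without the excluded step
#' from the combined map with it, highlighting the areas exclusively
#' covered by that step. The display-convention loss map is the
#' inversion `1 - exclusive`. Step 1 cannot be excluded.
#'
#' @param step_maps named list of `aggregated_map`.
#' @param all_steps step labels forming the full technique.
#' @param excluded the step label to exclude (not `"1"`).
#' @return a `coverage_loss_result`: list with `exclusive_map`,
#'   `loss_map` (both template rasters with NA where the full
#'   combination is undefined), `excluded` and `steps`.
#' @export
exclusive_coverage <- function(step_maps, all_steps = names(step_maps),
                               excluded) {
  all_steps <- check_step_set(all_steps)
  excluded <- as.character(excluded)
  if (identical(excluded, "1"))
    stop("Step 1 is skipped since it is a necessary prerequisite for other steps")
  if (!excluded %in% all_steps)
    stop("excluded step ", excluded, " is not in the step set")
  with_all <- combine_steps(step_maps, all_steps)
  without <- combine_steps(step_maps, setdiff(all_steps, excluded))
  pa <- with_all$probability
  pw <- without$probability
  excl <- pa
  def <- !is.na(pa)
  pw_val <- ifelse(is.na(pw), 0, pw)        # max over an empty set is 0
  excl[def] <- pmax(pa[def] - pw_val[def], 0)
  loss <- excl
  loss[def] <- 1 - excl[def]
  structure(list(exclusive_map = excl, loss_map = loss,
                 excluded = excluded, steps = all_steps,
                 identity = with_all$identity),
            class = "coverage_loss_result")
}

#' Scalar coverage-loss fraction of an excluded step
#'
#' The size of the untreated area caused by excluding the step,
#' relative to the hand area. Two variants are computed: the primary
#' probability-weighted fraction (mean of the exclusive map over the
#' template outline, no-data counting as zero) and a thresholded
#' fraction (share of outline pixels whose exclusive probability
#' exceeds `threshold`).
#'
#' @param result a `coverage_loss_result`.
#' @param template the `standard_template` (provides the outline).
#' @param threshold threshold for the thresholded variant.
#' @return list with `weighted`, `thresholded`, `threshold` and
#'   `outline_px`.
#' @export
loss_fraction <- function(result, template, threshold = 0.5) {
  outline <- as_plain_mask(template$outline_mask)
  n <- sum(outline)
  if (n == 0) stop("template outline is empty")
  e <- result$exclusive_map[outline]
  e[is.na(e)] <- 0
  list(weighted = sum(e) / n,
       thresholded = sum(e > threshold) / n,
       threshold = threshold, outline_px = n)
}

#' Compare accumulated individual steps against the complete technique
#'
#' Reports the mean absolute per-pixel probability difference and the
#' four-category agreement between the max-combination of all
#' individual steps and the aggregate of the complete-technique
#' observations, over pixels defined in both.
#'
#' @param step_maps named list of `aggregated_map` of the individual
#'   steps.
#' @param complete_map `aggregated_map` of the complete technique.
#' @param steps step labels to combine (default: all present).
#' @return list with `mean_abs_diff`, `category_agreement` and
#'   `n_pixels`.
#' @export
validate_accumulation <- function(step_maps, complete_map,
                                  steps = names(step_maps)) {
  comb <- combine_steps(step_maps, steps)
  pa <- comb$probability
  pc <- complete_map$probability
  if (!identical(dim(pa), dim(pc)))
    stop("combined and complete maps have differing dimensions")
  both <- !is.na(pa) & !is.na(pc)
  if (!any(both)) stop("maps share no defined pixels")
  d <- abs(pa[both] - pc[both])
  ca <- quantize_map(pa)
  cc <- quantize_map(pc)
  list(mean_abs_diff = mean(d),
       category_agreement = mean(ca[both] == cc[both]),
       n_pixels = sum(both))
}

#' Coverage-loss table over steps and hand sides
#'
#' Convenience wrapper producing the loss-per-step-per-side table: for
#' every step except the prerequisite and every (hand, side) present,
#' the probability-weighted and thresholded loss fractions.
#'
#' @param maps_by_side named list (`"dorsal_left"`, ...) of named lists
#'   of per-step `aggregated_map`s.
#' @param templates template set from [build_template_set()].
#' @param threshold threshold for the thresholded variant.
#' @return data frame with columns `step`, `side_key`, `loss_weighted`,
#'   `loss_thresholded`.
#' @export
loss_table <- function(maps_by_side, templates, threshold = 0.5) {
  rows <- list()
  for (key in names(maps_by_side)) {
    step_maps <- maps_by_side[[key]]
    tpl <- templates[[key]]
    if (is.null(tpl)) stop("no template for side key ", key)
    steps <- intersect(step_labels(), names(step_maps))
    for (s in setdiff(steps, "1")) {
      res <- exclusive_coverage(step_maps, steps, s)
      lf <- loss_fraction(res, tpl, threshold = threshold)
      rows[[length(rows) + 1]] <- data.frame(
        step = s, side_key = key,
        loss_weighted = lf$weighted,
        loss_thresholded = lf$thresholded,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
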