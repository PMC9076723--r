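#' Aggregate mapped observations into a coverage-probability map
#'
#' Pools error-corrected, quality-passed observations of the same
#' (task, hand, side): the probability at a template pixel is the
#' number of observations that saw it covered divided by the number of
#' observations that saw it at all (its valid count). Pixels never
#' observed carry no probability (NA).
#'
#' @param mapped list of `mapped_coverage` objects.
#' @param identity optional (task, hand, side) tag; when the mapped
#'   observations carry identities, their (task, hand, side) must
#'   agree.
#' @return an `aggregated_map`: list with `probability` (matrix in
#'   `[0, 1]` with NA where count is 0), `count` (valid counts),
#'   `n_observations` and `identity`.
#' @export
aggregate_maps <- function(mapped, identity = NULL) {
  if (length(mapped) == 0) stop("cannot aggregate an empty list")
  keys <- lapply(mapped, function(m) {
    id <- m$identity
    if (is.null(id)) NULL else id[intersect(names(id),
                                            c("task", "hand", "side"))]
  })
  keys <- Filter(Negate(is.null), keys)
  if (length(keys) > 1) {
    for (k in keys[-1])
      if (!identical(k, keys[[1]]))
        stop("mixed identities: all observations must share (task, hand, side)")
  }
  d <- dim(mapped[[1]]$valid)
  cov_count <- matrix(0L, d[1], d[2])
  val_count <- matrix(0L, d[1], d[2])
  for (m in mapped) {
    if (!identical(dim(m$valid), d))
      stop("mapped observations have differing template dimensions")
    cov_count <- cov_count + as_plain_mask(m$covered)
    val_count <- val_count + as_plain_mask(m$valid)
  }
  prob <- matrix(NA_real_, d[1], d[2])
  nz <- val_count > 0
  prob[nz] <- cov_count[nz] / val_count[nz]
  if (is.null(identity) && length(keys) > 0) identity <- keys[[1]]
  structure(list(probability = prob, count = val_count,
                 n_observations = length(mapped), identity = identity),
            class = "aggregated_map")
}

#' @export
print.aggregated_map <- function(x, ...) {
  cat(sprintf("<aggregated_map %d x %d, n = %d, mean p = %.3f>\n",
              nrow(x$count), ncol(x$count), x$n_observations,
              mean(x$probability, na.rm = TRUE)))
  invisible(x)
}

#' Quantize a probability map into four display categories
#'
#' Probabilities are grouped into the four reporting intervals
#' `[0, 0.25]`, `(0.25, 0.5]`, `(0.5, 0.75]`, `(0.75, 1]` (categories
#' 1-4); the first interval is closed on both ends so every probability
#' has exactly one category. No-data pixels stay NA.
#'
#' @param agg an `aggregated_map`, or a bare probability matrix.
#' @return integer matrix of categories 1-4 with NA as the no-data
#'   marker.
#' @export
quantize_map <- function(agg) {
  p <- if (inherits(agg, "aggregated_map")) agg$probability else agg
  cat_ <- matrix(NA_integer_, nrow(p), ncol(p))
  ok <- !is.na(p)
  cat_[ok] <- 1L + (p[ok] > 0.25) + (p[ok] > 0.5) + (p[ok] > 0.75)
  cat_
}

#' Pairwise Pearson correlation of coverage between hand sides
#'
#' Computes pairwise Pearson correlation coefficients (and two-sided
#' p-values) over participants for the per-participant coverage
#' fractions of the four hand sides.
#'
#' @param per_participant data frame with columns `participant`,
#'   `hand`, `side` and `coverage`.
#' @return list with matrices `r`, `p` and `n` (4 x 4, dimensions
#'   `dorsal_left`, `dorsal_right`, `palmar_left`, `palmar_right`).
#'   Correlations with a constant column are NA.
#' @export
side_correlations <- function(per_participant) {
  need <- c("participant", "hand", "side", "coverage")
  if (!all(need %in% names(per_participant)))
    stop("expected columns: ", paste(need, collapse = ", "))
  per_participant$key <- paste(per_participant$side,
                               per_participant$hand, sep = "_")
  keys <- c("dorsal_left", "dorsal_right", "palmar_left", "palmar_right")
  parts <- sort(unique(per_participant$participant))
  if (length(parts) < 3)
    stop("need at least 3 participants for correlations")
  wide <- matrix(NA_real_, length(parts), length(keys),
                 dimnames = list(as.character(parts), keys))
  for (i in seq_len(nrow(per_participant))) {
    row <- per_participant[i, ]
    wide[as.character(row$participant), row$key] <- row$coverage
  }
  r <- matrix(NA_real_, 4, 4, dimnames = list(keys, keys))
  p <- r; n <- r
  for (i in 1:4) for (j in 1:4) {
    ok <- !is.na(wide[, i]) & !is.na(wide[, j])
    n[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (sum(ok) < 3) next
    if (stats::sd(wide[ok, i]) == 0 || stats::sd(wide[ok, j]) == 0) next
    ct <- stats::cor.test(wide[ok, i], wide[ok, j])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p, n = n)
}
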