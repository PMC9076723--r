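#' Exact 4-point homography between segment corner sets
#'
#' Solves the direct linear system for the 3x3 projective transform (8
#' degrees of freedom, normalized so `H[3,3] = 1`) that maps each of
#' four source corners exactly onto its target corner. Four point
#' correspondences determine the homography uniquely when no three
#' points on either side are collinear.
#'
#' @param source_corners,target_corners `4 x 2` matrices of `(x, y)`
#'   corners in corresponding order.
#' @param label optional segment label carried on the result.
#' @return a `segment_homography`: list with `label` and the 3x3
#'   `matrix`.
#' @export
fit_segment_homography <- function(source_corners, target_corners,
                                   label = NULL) {
  s <- as.matrix(source_corners); t <- as.matrix(target_corners)
  stopifnot(identical(dim(s), c(4L, 2L)), identical(dim(t), c(4L, 2L)))
  if (quad_degenerate(s) || quad_degenerate(t))
    stop("degenerate-homography: three corners are collinear",
         if (!is.null(label)) paste0(" in segment ", label) else "")
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- s[i, 1]; y <- s[i, 2]; u <- t[i, 1]; v <- t[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i]     <- v
  }
  h <- tryCatch(solve(A, b), error = function(e)
    stop("degenerate-homography: corner system is singular"))
  H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  structure(list(label = label, matrix = H), class = "segment_homography")
}

#' Apply a homography to points
#'
#' @param H a `segment_homography` or bare 3x3 matrix.
#' @param pts `n x 2` matrix of `(x, y)` points.
#' @return `n x 2` matrix of transformed points.
#' @export
apply_homography <- function(H, pts) {
  M <- if (inherits(H, "segment_homography")) H$matrix else H
  pts <- as.matrix(pts)
  p <- M %*% rbind(t(pts), 1)
  t(p[1:2, , drop = FALSE] / rep(p[3, ], each = 2))
}

#' Invert a homography
#' @param H a `segment_homography` or 3x3 matrix.
#' @return same type, inverted.
#' @export
invert_homography <- function(H) {
  if (inherits(H, "segment_homography")) {
    structure(list(label = H$label, matrix = solve(H$matrix)),
              class = "segment_homography")
  } else {
    solve(H)
  }
}
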