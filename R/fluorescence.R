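#' Fluorescence extraction thresholds
#'
#' Thresholds for detecting green fluorescent handrub in a UV-lamp
#' photograph: an inclusive hue band on the 0-179 half-degree scale
#' (default 25-97, the green range) and an inclusive brightness band on
#' the 0-255 scale whose pixels are *rejected* (default 0-60), which
#' removes residual fluorescent concentrate from earlier tasks that
#' glows green but only dimly.
#'
#' @param hue_min,hue_max inclusive hue band, 0-179.
#' @param brightness_reject_min,brightness_reject_max inclusive
#'   brightness band to reject, 0-255.
#' @return a `fluorescence_thresholds` object.
#' @export
fluorescence_thresholds <- function(hue_min = 25, hue_max = 97,
                                    brightness_reject_min = 0,
                                    brightness_reject_max = 60) {
  if (!(0 <= hue_min && hue_min <= hue_max && hue_max <= 179))
    stop("need 0 <= hue_min <= hue_max <= 179")
  if (!(0 <= brightness_reject_min &&
        brightness_reject_min <= brightness_reject_max &&
        brightness_reject_max <= 255))
    stop("need 0 <= brightness_reject_min <= brightness_reject_max <= 255")
  structure(list(hue_min = hue_min, hue_max = hue_max,
                 brightness_reject_min = brightness_reject_min,
                 brightness_reject_max = brightness_reject_max),
            class = "fluorescence_thresholds")
}

#' Extract fluorescent handrub coverage from a UV photograph
#'
#' Converts the UV image to the hue-saturation-brightness system and
#' marks as covered every pixel whose hue lies inside the green band
#' and whose brightness lies outside the low-brightness rejection band:
#' `hue_min <= H <= hue_max` and not
#' `brightness_reject_min <= B <= brightness_reject_max`.
#'
#' @param uv_image an [rgb_image()] taken under the UV lamp, registered
#'   with its white-light partner.
#' @param thresholds a [fluorescence_thresholds()] object.
#' @return a [binary_mask()] of covered pixels.
#' @export
extract_fluorescence <- function(uv_image,
                                 thresholds = fluorescence_thresholds()) {
  stopifnot(inherits(thresholds, "fluorescence_thresholds"))
  ch <- hsb_channels(uv_image)
  in_hue <- ch$h >= thresholds$hue_min & ch$h <= thresholds$hue_max
  rejected <- ch$b >= thresholds$brightness_reject_min &
    ch$b <= thresholds$brightness_reject_max
  binary_mask(in_hue & !rejected, ref = uv_image)
}

#' Restrict a coverage mask to a hand ROI
#'
#' Pointwise AND of the coverage mask and the ROI mask.
#'
#' @param coverage a [binary_mask()] from [extract_fluorescence()].
#' @param roi a `hand_roi` (or a bare [binary_mask()]).
#' @return a [binary_mask()].
#' @export
coverage_in_roi <- function(coverage, roi) {
  rmask <- if (inherits(roi, "hand_roi")) roi$mask else roi
  if (!identical(dim(coverage)[1:2], dim(rmask)[1:2]))
    stop("coverage and ROI masks have different dimensions")
  binary_mask(as_plain_mask(coverage) & as_plain_mask(rmask))
}

#' Fraction of the ROI covered by fluorescent handrub
#'
#' @param coverage a [binary_mask()].
#' @param roi a `hand_roi` (or mask).
#' @return fraction in `[0, 1]`: covered-and-in-ROI pixels over ROI
#'   pixels.
#' @export
coverage_percentage <- function(coverage, roi) {
  rmask <- if (inherits(roi, "hand_roi")) roi$mask else roi
  nroi <- sum(rmask)
  if (nroi == 0) stop("empty ROI: coverage percentage undefined")
  sum(as_plain_mask(coverage) & as_plain_mask(rmask)) / nroi
}
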