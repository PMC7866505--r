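#' Circular hue distance
#'
#' Shortest distance between two hues on the circular hue scale normalized to
#' `[0, 1)` (1 identified with 0), going clockwise or counterclockwise:
#' `min(|h - t|, 1 - |h - t|)`. The result lies in `[0, 0.5]`.
#'
#' @param h,target hues in `[0, 1)`; vectorized.
#' @return circular distances in `[0, 0.5]`.
#' @examples
#' circular_hue_difference(0.0, 0.9)   # 0.1 (wraps)
#' circular_hue_difference(0.25, 0.75) # 0.5 (antipodal)
#' @export
circular_hue_difference <- function(h, target) {
  d <- abs(h - target)
  pmin(d, 1 - d)
}

# HSV components of an RGB frame array (rows x cols x 3, values in [0, 1]).
# Returns list of matrices h, s, v with hue in [0, 1).
frame_hsv <- function(frame) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] >= 3)
  d <- dim(frame)[1:2]
  m <- rbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
             as.vector(frame[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = matrix(hsv["h", ], d[1], d[2]),
       s = matrix(hsv["s", ], d[1], d[2]),
       v = matrix(hsv["v", ], d[1], d[2]))
}

#' Hue-similarity image (DifHue)
#'
#' Converts an RGB frame to HSV and computes
#' `DifHue(x, y) = 1 - circular_hue_difference(target, h(x, y))`, then zeroes
#' every pixel whose saturation is below `sat_min` (default 50%) so that
#' near-gray pixels, whose hue is meaningless, cannot respond. Non-zero
#' values therefore lie in `[0.5, 1]`.
#'
#' @param frame RGB array (rows x cols x 3), values in `[0, 1]`.
#' @param target target hue in `[0, 1)` (pure red = 0, yellow = 1/6).
#' @param sat_min saturation gate in `[0, 1]`.
#' @return matrix of the same size as the frame.
#' @export
hue_similarity_image <- function(frame, target, sat_min = 0.5) {
  if (length(frame) == 0) stop("hue_similarity_image: empty frame")
  hsv <- frame_hsv(frame)
  dif <- 1 - circular_hue_difference(hsv$h, target)
  dif[hsv$s < sat_min] <- 0
  dif
}

#' Binarization threshold for a target hue
#'
#' Half the circular hue distance from the target to the nearest of the six
#' primary/secondary hues (0, 1/6, ..., 5/6) other than the target's own bin.
#' For pure red (target 0) this is 1/12: colors within 50% of the range
#' between red and its closest neighbouring primary/secondary hue are kept.
#'
#' @param target hue in `[0, 1)`.
#' @return threshold on circular hue distance.
#' @export
hue_bin_threshold <- function(target) {
  prim <- (0:5) / 6
  d <- circular_hue_difference(prim, target)
  own <- which.min(d)
  0.5 * min(d[-own])
}

#' Binarize a hue-similarity image (DifHueBin)
#'
#' True where the pixel survived the saturation gate (nonzero `DifHue`) and
#' its circular hue distance to the target does not exceed
#' [hue_bin_threshold()].
#'
#' @param dif_hue output of [hue_similarity_image()].
#' @param target the same target hue.
#' @return logical matrix.
#' @export
binarize_hue <- function(dif_hue, target) {
  thr <- hue_bin_threshold(target)
  dif_hue > 0 & dif_hue >= 1 - thr
}

# Fused fast path: binary hue mask straight from an RGB array, computed in a
# single compiled pass; equals the composition
# binarize_hue(hue_similarity_image(frame, target, sat_min), target).
binary_hue_mask <- function(frame, target, sat_min = 0.5) {
  .hue_mask_cpp(frame, target, sat_min, hue_bin_threshold(target))
}
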