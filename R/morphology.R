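# Morphological primitives for marker detection. Masks are plain logical or
# 0/1 numeric matrices indexed [row = y, col = x]; structuring elements are
# linear (a line of pixels) as the stripes and marks being detected are
# compact, oriented features.

#' Linear structuring element
#'
#' @param length element length in pixels (>= 1); rounded up to an odd value
#'   so the element has a well-defined centre and is symmetric under point
#'   reflection (erode-then-dilate is then the exact morphological opening).
#' @param orientation `"vertical"` (along image y), `"horizontal"` (along x),
#'   or `"diag135"` (a discrete line along the up-right/down-left diagonal,
#'   matching the oblique stripes of warning tape).
#' @return binary matrix usable as an EBImage kernel.
#' @export
se_line <- function(length, orientation = c("vertical", "horizontal", "diag135")) {
  orientation <- match.arg(orientation)
  length <- max(1L, as.integer(round(length)))
  if (length %% 2L == 0L) length <- length + 1L
  switch(orientation,
         vertical = matrix(1, length, 1),
         horizontal = matrix(1, 1, length),
         diag135 = {
           k <- matrix(0, length, length)
           k[cbind(seq_len(length), length:1)] <- 1
           k
         })
}

mask_as_numeric <- function(mask) {
  m <- mask
  storage.mode(m) <- "double"
  m
}

# Opening restricted to the bounding box of the nonzero support. The crop is
# zero-padded by the kernel size on every side — including beyond the image
# border — so pixels outside the image count as background and the result
# equals the strict set-theoretic opening (union of all structuring-element
# translates contained in the mask).
mm_opening <- function(mask, kern) {
  m <- mask_as_numeric(mask)
  nz <- which(m != 0)
  if (length(nz) == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  rows <- range((nz - 1L) %% nr + 1L)
  cols <- range((nz - 1L) %/% nr + 1L)
  pr <- nrow(kern) + 1L; pc <- ncol(kern) + 1L
  r0 <- rows[1] - pr; r1 <- rows[2] + pr
  c0 <- cols[1] - pc; c1 <- cols[2] + pc
  sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
  rin <- max(r0, 1L):min(r1, nr); cin <- max(c0, 1L):min(c1, nc)
  sub[rin - r0 + 1L, cin - c0 + 1L] <- m[rin, cin]
  op <- EBImage::opening(sub, kern)
  out <- matrix(0, nr, nc)
  out[rin, cin] <- op[rin - r0 + 1L, cin - c0 + 1L]
  out
}

# for binary masks the opening is contained in the mask, so the white
# top-hat is a plain difference
white_tophat <- function(mask, kern) {
  m <- mask_as_numeric(mask)
  m - mm_opening(m, kern)
}

#' Size-selective top-hat bandpass filter
#'
#' `BPFilter = Tophat(mask, ee1) - Tophat(mask, ee2)` with linear structuring
#' elements `ee1` of length twice and `ee2` of length half the expected
#' feature size: regions larger than twice or smaller than half the expected
#' size along the element's orientation are eliminated, keeping compact
#' features near the expected scale.
#'
#' @param mask binary matrix (the binarized hue image).
#' @param orientation `"vertical"`, `"horizontal"` or `"diag135"`.
#' @param expected_size expected feature extent in pixels (>= 2).
#' @return logical matrix.
#' @export
tophat_bandpass <- function(mask, orientation = c("vertical", "horizontal", "diag135"),
                            expected_size) {
  orientation <- match.arg(orientation)
  if (!is.numeric(expected_size) || expected_size < 2)
    stop("tophat_bandpass: expected_size must be >= 2 px")
  ee1 <- se_line(2 * expected_size, orientation)
  ee2 <- se_line(expected_size / 2, orientation)
  bp <- white_tophat(mask, ee1) - white_tophat(mask, ee2)
  bp > 0
}

#' Morphological reconstruction of markers within a mask
#'
#' Geodesic reconstruction by dilation of binary markers under a binary mask:
#' the union of the connected components of `mask` that intersect `markers`.
#' Markers are intersected with the mask first, so stray marker pixels
#' outside the mask are ignored.
#'
#' @param markers binary matrix of seed regions.
#' @param mask binary matrix constraining the reconstruction.
#' @return logical matrix.
#' @export
reconstruct_markers <- function(markers, mask) {
  mk <- markers & mask
  if (!any(mk)) return(matrix(FALSE, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask_as_numeric(mask))
  keep <- unique(lab[mk])
  keep <- keep[keep > 0]
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Connected-component polygon candidates
#'
#' Labels the connected components of a binary mask and summarizes each as a
#' polygon candidate: bounding box, upper-left corner, centroid and area.
#'
#' @param mask binary matrix.
#' @param min_area drop components smaller than this many pixels.
#' @return data.frame with columns `label`, `xmin`, `ymin`, `xmax`, `ymax`
#'   (bounding box, pixel units; `(xmin, ymin)` is the upper-left corner),
#'   `cx`, `cy` (centroid) and `area` (px^2).
#' @export
polygon_candidates <- function(mask, min_area = 1) {
  lab <- EBImage::bwlabel(mask_as_numeric(mask))
  n <- max(lab)
  if (n == 0)
    return(data.frame(label = integer(0), xmin = numeric(0), ymin = numeric(0),
                      xmax = numeric(0), ymax = numeric(0), cx = numeric(0),
                      cy = numeric(0), area = numeric(0)))
  idx <- which(lab > 0)
  l <- lab[idx]
  nr <- nrow(mask)
  y <- (idx - 1L) %% nr + 1L
  x <- (idx - 1L) %/% nr + 1L
  df <- data.frame(
    label = sort(unique(l)),
    xmin = as.numeric(tapply(x, l, min)),
    ymin = as.numeric(tapply(y, l, min)),
    xmax = as.numeric(tapply(x, l, max)),
    ymax = as.numeric(tapply(y, l, max)),
    cx = as.numeric(tapply(x, l, mean)),
    cy = as.numeric(tapply(y, l, mean)),
    area = as.numeric(tapply(x, l, length)))
  df[df$area >= min_area, , drop = FALSE]
}
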