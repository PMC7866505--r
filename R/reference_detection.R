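#' Detection configuration
#'
#' Parameters of the reference-corner and barbell-mark detectors. Defaults
#' follow the red-white warning tape / yellow barbell mark setup; for
#' black-yellow tape set `hue_target = 1/6` and a contrasting `mark_hue`.
#'
#' @param hue_target tape hue in `[0, 1)` (red = 0, yellow = 1/6).
#' @param mark_hue barbell-mark hue (yellow = 1/6 by default).
#' @param saturation_min saturation gate (default 0.5).
#' @param expected_polygon_px expected tape-stripe extent in pixels; `NULL`
#'   defaults to `image_height / 40` at detection time.
#' @param expected_mark_px expected barbell-mark extent in pixels; `NULL`
#'   defaults to `image_height / 60`.
#' @param min_area_frac minimum candidate area as a fraction of the squared
#'   expected size (specks below this are dropped before RANSAC).
#' @param ransac list: `threshold_px` inlier distance, `iterations`, `seed`.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(hue_target = 0, mark_hue = 1 / 6,
                             saturation_min = 0.5,
                             expected_polygon_px = NULL,
                             expected_mark_px = NULL,
                             min_area_frac = 0.05,
                             ransac = list(threshold_px = 3, iterations = 200,
                                           seed = 1)) {
  ransac <- utils::modifyList(list(threshold_px = 3, iterations = 200, seed = 1),
                              ransac)
  structure(list(hue_target = hue_target, mark_hue = mark_hue,
                 saturation_min = saturation_min,
                 expected_polygon_px = expected_polygon_px,
                 expected_mark_px = expected_mark_px,
                 min_area_frac = min_area_frac, ransac = ransac),
            class = "detection_config")
}

# Robust fit of the line x = a*y + b through points, RANSAC with
# least-squares refit on the consensus set.
ransac_line <- function(x, y, threshold_px = 3, iterations = 200, seed = 1,
                        min_inliers = 2) {
  n <- length(x)
  stopifnot(n == length(y))
  if (n < 2) stop("ransac_line: need at least 2 points")
  if (diff(range(x)) < 1e-9 && diff(range(y)) < 1e-9)
    stop("ransac_line: degenerate (all points coincident)")
  fit_ls <- function(idx) {
    yy <- y[idx]; xx <- x[idx]
    if (diff(range(yy)) < 1e-9) return(NULL)  # horizontal set: not x = a*y + b
    a <- stats::cov(yy, xx) / stats::var(yy)
    c(a = a, b = mean(xx) - a * mean(yy))
  }
  if (n == 2) {
    ab <- fit_ls(1:2)
    if (is.null(ab)) stop("ransac_line: degenerate pair")
    return(list(a = ab[1], b = ab[2], inliers = rep(TRUE, 2)))
  }
  best <- NULL; best_count <- -1L
  with_local_seed(seed, {
    for (it in seq_len(iterations)) {
      s <- sample.int(n, 2)
      if (abs(y[s[1]] - y[s[2]]) < 1e-9) next
      a <- (x[s[1]] - x[s[2]]) / (y[s[1]] - y[s[2]])
      b <- x[s[1]] - a * y[s[1]]
      resid <- abs(x - (a * y + b))
      count <- sum(resid <= threshold_px)
      if (count > best_count) {
        best_count <- count
        best <- resid <= threshold_px
      }
    }
  })
  if (is.null(best) || best_count < min_inliers)
    stop("ransac_line: consensus below minimum")
  ab <- fit_ls(which(best))
  if (is.null(ab)) stop("ransac_line: inlier set degenerate in y")
  resid <- abs(x - (ab[1] * y + ab[2]))
  list(a = unname(ab[1]), b = unname(ab[2]), inliers = resid <= threshold_px)
}

#' Detect the four tape reference corners in a frame
#'
#' Runs the full reference-marker pipeline on one frame: circular-hue
#' similarity to the tape hue, saturation gating, binarization, two top-hat
#' bandpass filters (vertical and 135-degree linear structuring elements,
#' intersected), morphological reconstruction, and connected-component
#' extraction. The left and right image halves are then processed
#' independently: a first-degree polynomial `x = a*y + b` is fitted to the
#' upper-left corners of the candidate polygons with RANSAC, outliers are
#' eliminated, and the upper-left corners of the highest and lowest inlier
#' polygons become the reference points.
#'
#' @param frame RGB array (rows x cols x 3) in `[0, 1]`.
#' @param config [detection_config()].
#' @return list of class `reference_detection`: `corners` (4x2 pixel matrix
#'   ordered P1 top-left, P2 bottom-left, P3 bottom-right, P4 top-right),
#'   `left`, `right` (data.frames of inlier polygon candidates), `mask`
#'   (the reconstructed binary image).
#' @export
detect_reference_corners <- function(frame, config = detection_config()) {
  d <- dim(frame)
  H <- d[1]; W <- d[2]
  s <- config$expected_polygon_px %||% (H / 40)
  bin <- binary_hue_mask(frame, config$hue_target, config$saturation_min)
  if (!any(bin))
    stop("detect_reference_corners: no pixels match the tape hue")
  bp_v <- tophat_bandpass(bin, "vertical", s)
  bp_d <- tophat_bandpass(bin, "diag135", s)
  markers <- bp_v & bp_d
  rec <- reconstruct_markers(markers, bin)
  cand <- polygon_candidates(rec, min_area = config$min_area_frac * s^2)
  if (nrow(cand) == 0)
    stop("detect_reference_corners: no candidate polygons after filtering")
  sides <- list(left = cand[cand$cx < W / 2, , drop = FALSE],
                right = cand[cand$cx >= W / 2, , drop = FALSE])
  out <- list()
  for (side in names(sides)) {
    cs <- sides[[side]]
    if (nrow(cs) < 2)
      stop(sprintf("detect_reference_corners: fewer than 2 polygons on the %s side", side))
    fit <- ransac_line(cs$xmin, cs$ymin,
                       threshold_px = config$ransac$threshold_px,
                       iterations = config$ransac$iterations,
                       seed = config$ransac$seed)
    inl <- cs[fit$inliers, , drop = FALSE]
    if (nrow(inl) < 2)
      stop(sprintf("detect_reference_corners: fewer than 2 inlier polygons on the %s side", side))
    out[[side]] <- inl
  }
  top_ul <- function(df) {
    i <- which.min(df$ymin); c(df$xmin[i], df$ymin[i])
  }
  bot_ul <- function(df) {
    i <- which.max(df$ymin); c(df$xmin[i], df$ymin[i])
  }
  corners <- rbind(P1 = top_ul(out$left), P2 = bot_ul(out$left),
                   P3 = bot_ul(out$right), P4 = top_ul(out$right))
  colnames(corners) <- c("x", "y")
  structure(list(corners = corners, left = out$left, right = out$right,
                 mask = rec, expected_polygon_px = s),
            class = "reference_detection")
}

#' @export
print.reference_detection <- function(x, ...) {
  cat("reference_detection: corners (px)\n")
  print(round(x$corners, 2))
  cat(sprintf(" inlier polygons: %d left, %d right\n", nrow(x$left), nrow(x$right)))
  invisible(x)
}
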