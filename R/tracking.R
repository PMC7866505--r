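#' Search strips for barbell-mark detection
#'
#' Restricts per-frame mark detection to two narrow vertical strips, built
#' from the reference-detection inliers. For the left side, the line `L1`
#' (`x = a*y + b`) is fitted with RANSAC to the bottom-right corners of the
#' inlier tape polygons; `L2` is `L1` shifted right by half the polygon
#' width; the strip spans from `L2` to the line midway between `L2` and the
#' image's vertical bisector. The right side is mirrored (bottom-left
#' corners, shift left).
#'
#' @param left,right data.frames of inlier polygon candidates (from
#'   [detect_reference_corners()]).
#' @param image_width frame width in pixels.
#' @param config [detection_config()] (for the RANSAC parameters).
#' @return object of class `search_strips`: per side the `L2` line
#'   coefficients (`a`, `b`) and the inner boundary, plus conservative
#'   integer column ranges.
#' @export
build_search_strips <- function(left, right, image_width,
                                config = detection_config()) {
  for (df in list(left, right))
    if (nrow(df) < 2)
      stop("build_search_strips: need at least 2 inlier polygons per side")
  rs <- config$ransac
  mk <- function(df, side) {
    w <- mean(df$xmax - df$xmin + 1)
    xc <- if (side == "left") df$xmax else df$xmin
    fit <- ransac_line(xc, df$ymax, threshold_px = rs$threshold_px,
                       iterations = rs$iterations, seed = rs$seed)
    shift <- if (side == "left") w / 2 else -w / 2
    list(side = side, a = fit$a, b = fit$b + shift, half_width = w / 2)
  }
  structure(list(left = mk(left, "left"), right = mk(right, "right"),
                 image_width = image_width),
            class = "search_strips")
}

# x-bounds of a strip at image row y (vector). Left: [L2(y), mid(y)];
# right: [mid(y), L2(y)].
strip_bounds <- function(strips, side, y) {
  s <- strips[[side]]
  l2 <- s$a * y + s$b
  mid <- (l2 + strips$image_width / 2) / 2
  if (side == "left") cbind(lo = l2, hi = mid) else cbind(lo = mid, hi = l2)
}

# conservative integer column range of one strip over rows 1..image_height
strip_cols <- function(strips, side, image_height) {
  b <- strip_bounds(strips, side, c(1, image_height))
  c(max(1L, floor(min(b))), min(strips$image_width, ceiling(max(b))))
}

#' Detect barbell-mark candidates inside one search strip
#'
#' Applies the same hue pipeline used for the reference points to the strip
#' subimage (`ImBarbellStrip`): circular-hue similarity to the mark hue,
#' saturation gate, binarization, then top-hat bandpass filters with vertical
#' and horizontal linear structuring elements sized to the expected mark,
#' intersected and reconstructed. Pixels outside the strip are zeroed.
#' An empty candidate list is a valid result (no, one, or several candidates
#' may be present).
#'
#' @param frame full RGB frame, or the strip subimage when `cols` gives its
#'   column range in the full frame.
#' @param strips [build_search_strips()] result.
#' @param side `"left"` or `"right"`.
#' @param config [detection_config()].
#' @param cols optional integer `c(first, last)` column range of `frame`
#'   within the full image.
#' @return data.frame of polygon candidates in full-frame pixel coordinates.
#' @export
detect_marker_candidates <- function(frame, strips, side,
                                     config = detection_config(),
                                     cols = NULL) {
  H <- dim(frame)[1]
  s <- config$expected_mark_px %||% (H / 60)
  if (is.null(cols)) {
    cols <- strip_cols(strips, side, H)
    frame <- frame[, cols[1]:cols[2], , drop = FALSE]
  }
  off <- cols[1] - 1L
  bin <- binary_hue_mask(frame, config$mark_hue, config$saturation_min)
  nz <- which(bin)
  if (length(nz) == 0) return(polygon_candidates(matrix(FALSE, 1, 1)))
  # crop to the nonzero support (plus the bandpass reach) so the remaining
  # morphology touches only the neighbourhood of the mark
  nr <- nrow(bin)
  pad <- ceiling(2 * s) + 2L
  rr <- range((nz - 1L) %% nr + 1L)
  cc <- range((nz - 1L) %/% nr + 1L)
  r0 <- max(1L, rr[1] - pad); r1 <- min(nr, rr[2] + pad)
  c0 <- max(1L, cc[1] - pad); c1 <- min(ncol(bin), cc[2] + pad)
  bin <- bin[r0:r1, c0:c1, drop = FALSE]
  # zero pixels outside the strip boundaries (per-row bounds)
  b <- strip_bounds(strips, side, r0:r1)
  xg <- col(bin) + (off + c0 - 1L)
  bin <- bin & (xg >= b[, "lo"]) & (xg <= b[, "hi"])
  if (!any(bin)) return(polygon_candidates(matrix(FALSE, 1, 1)))
  bp_v <- tophat_bandpass(bin, "vertical", s)
  bp_h <- tophat_bandpass(bin, "horizontal", s)
  rec <- reconstruct_markers(bp_v & bp_h, bin)
  cand <- polygon_candidates(rec, min_area = config$min_area_frac * s^2)
  cand$xmin <- cand$xmin + off + c0 - 1L; cand$xmax <- cand$xmax + off + c0 - 1L
  cand$cx <- cand$cx + off + c0 - 1L
  cand$ymin <- cand$ymin + r0 - 1L; cand$ymax <- cand$ymax + r0 - 1L
  cand$cy <- cand$cy + r0 - 1L
  cand
}

#' Pair left and right mark candidates
#'
#' The barbell is rigid, so its two end marks share the same height: among
#' all left/right candidate pairs the one minimizing the absolute difference
#' of the upper-left-corner row coordinates is selected; ties are broken by
#' the largest combined area. With candidates on only one side a partial
#' result is returned (largest candidate on that side).
#'
#' @param left,right candidate data.frames for one frame.
#' @return list with elements `left` and `right`, each a one-row data.frame
#'   or `NULL` when missing.
#' @export
pair_candidates <- function(left, right) {
  nl <- nrow(left); nr <- nrow(right)
  if (nl == 0 && nr == 0) return(list(left = NULL, right = NULL))
  if (nl == 0) return(list(left = NULL, right = right[which.max(right$area), ]))
  if (nr == 0) return(list(left = left[which.max(left$area), ], right = NULL))
  dy <- abs(outer(left$ymin, right$ymin, "-"))
  area <- outer(left$area, right$area, "+")
  best <- which(dy == min(dy), arr.ind = TRUE)
  if (nrow(best) > 1) best <- best[which.max(area[best]), , drop = FALSE]
  list(left = left[best[1, 1], ], right = right[best[1, 2], ])
}

#' Track the barbell marks across a frame sequence
#'
#' For every frame, detects mark candidates inside both search strips, pairs
#' them, and records the upper-left corner of each chosen mark. Missing
#' detections are filled by interpolation afterwards with
#' [fill_missing_detections()] and mapped to metric guide-plane coordinates
#' with [track_world_positions()].
#'
#' @param source a frame source (see [frame_source()]).
#' @param strips [build_search_strips()] result.
#' @param config [detection_config()].
#' @return data.frame of class `marker_track`: one row per side per frame
#'   with `frame`, `time_s`, `side`, `px_x`, `px_y`, `status`
#'   (`detected` / `interpolated` / `missing`).
#' @export
track_barbell <- function(source, strips, config = detection_config()) {
  n <- source$n_frames
  H <- source$height
  cl <- strip_cols(strips, "left", H)
  cr <- strip_cols(strips, "right", H)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fl <- source$get(i, cols = cl)
    fr <- source$get(i, cols = cr)
    pair <- pair_candidates(
      detect_marker_candidates(fl, strips, "left", config, cols = cl),
      detect_marker_candidates(fr, strips, "right", config, cols = cr))
    row1 <- function(side, cand) {
      if (is.null(cand))
        data.frame(frame = i, side = side, px_x = NA_real_, px_y = NA_real_,
                   status = "missing")
      else
        data.frame(frame = i, side = side, px_x = cand$xmin, px_y = cand$ymin,
                   status = "detected")
    }
    rows[[i]] <- rbind(row1("left", pair$left), row1("right", pair$right))
  }
  track <- do.call(rbind, rows)
  track$time_s <- (track$frame - 1) / source$fps
  track <- track[, c("frame", "time_s", "side", "px_x", "px_y", "status")]
  structure(track, class = c("marker_track", "data.frame"),
            fps = source$fps, n_frames = n)
}

#' Fill missing detections by temporal interpolation
#'
#' Internal gaps in each side's corner trajectory are filled by linear
#' interpolation between the neighbouring detections; leading and trailing
#' gaps are held at the nearest detection. Filled rows are flagged
#' `interpolated`; gaps longer than `max_gap` frames are additionally flagged
#' in the `low_confidence` column.
#'
#' @param track a `marker_track` from [track_barbell()].
#' @param max_gap gap length (frames) above which interpolations are marked
#'   low-confidence.
#' @return the track with interpolated coordinates.
#' @export
fill_missing_detections <- function(track, max_gap = 5) {
  fps <- attr(track, "fps"); nfr <- attr(track, "n_frames")
  track$low_confidence <- FALSE
  for (side in c("left", "right")) {
    idx <- which(track$side == side)
    sub <- track[idx, ]
    det <- sub$status == "detected"
    if (!any(det)) stop("fill_missing_detections: no detections on the ", side, " side")
    if (all(det)) next
    fr <- sub$frame
    for (col in c("px_x", "px_y")) {
      track[idx, col] <- approx(fr[det], sub[[col]][det], xout = fr,
                                method = "linear", rule = 2)$y
    }
    track$status[idx][!det] <- "interpolated"
    # flag long runs of interpolation
    r <- rle(!det)
    ends <- cumsum(r$lengths)
    for (j in which(r$values & r$lengths > max_gap)) {
      run <- (ends[j] - r$lengths[j] + 1):ends[j]
      track$low_confidence[idx][run] <- TRUE
    }
  }
  structure(track, class = c("marker_track", "data.frame"),
            fps = fps, n_frames = nfr)
}

#' Map tracked mark corners to metric guide-plane coordinates
#'
#' Applies `H_g^-1` to the upper-left corner of each detected mark only
#' (never to whole frames, keeping the per-frame cost to at most two mapped
#' points), yielding `(X_g, Y_g)` in metres on the barbell plane. The barbell
#' height series is `-Y_g` of the left/right midpoint (Y grows downward), so
#' ascent increases height; using the midpoint makes the height robust to
#' small bar tilt.
#'
#' @param track a filled `marker_track`.
#' @param Hg guide-plane homography from [calibrate_machine()].
#' @return the track with `X_g_m`, `Y_g_m` and `height_m` columns; the
#'   per-frame height series is attached as attribute `height` (with `fps`).
#' @export
track_world_positions <- function(track, Hg) {
  ok <- !is.na(track$px_x)
  n_mapped <- sum(ok)
  if (n_mapped > 2 * attr(track, "n_frames"))
    stop("track_world_positions: more than 2 points per frame")
  w <- matrix(NA_real_, nrow(track), 2)
  if (any(ok)) w[ok, ] <- map_pixel_to_plane(cbind(track$px_x[ok], track$px_y[ok]), Hg)
  track$X_g_m <- w[, 1]; track$Y_g_m <- w[, 2]
  yl <- track$Y_g_m[track$side == "left"]
  yr <- track$Y_g_m[track$side == "right"]
  height <- -rowMeans(cbind(yl, yr), na.rm = TRUE)
  # one row per side per frame; heights repeat per frame
  track$height_m <- height[track$frame]
  structure(track, class = c("marker_track", "data.frame"),
            fps = attr(track, "fps"), n_frames = attr(track, "n_frames"),
            height = height)
}

#' Height series of a world-mapped track
#' @param track output of [track_world_positions()].
#' @return numeric vector of per-frame barbell heights (m, up positive).
#' @export
track_height <- function(track) {
  h <- attr(track, "height")
  if (is.null(h)) stop("track_height: track has no world positions yet")
  h
}

#' Write a marker track to CSV
#' @param track a `marker_track`.
#' @param path output path.
#' @export
write_track <- function(track, path) {
  write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}
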