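#' Kinematics configuration
#'
#' Thresholds for concentric-phase segmentation of a barbell height series.
#' The ascent trigger fires when upward velocity exceeds `v_start` for
#' `run_start` consecutive samples; the start index is then refined backwards
#' to the last sample of the preceding rest plateau ("the instant before the
#' beginning of the ascent"). Movement is considered ceased when velocity
#' stays below `v_stop` for `run_stop` samples and the height does not rise
#' by more than `pos_tol_m` within the following `rest_window_s`; the end
#' index is the first sample reaching that final plateau. `pos_tol_m` should
#' be of the order of the spatial quantization of the video (about one pixel,
#' ~2 mm at 1920-pixel coverage of 4 m).
#'
#' @param v_start ascent velocity threshold, m/s.
#' @param v_stop stop velocity threshold, m/s.
#' @param run_start,run_stop consecutive samples required.
#' @param pos_tol_m position tolerance for plateau refinement, metres.
#' @param rest_window_s lookahead confirming cessation, seconds.
#' @param min_range_m discard segments with smaller total range, metres.
#' @param smooth_window moving-average window (samples) applied to the height
#'   series before differentiating for segmentation; 0 disables smoothing.
#' @return list of class `kinematics_config`.
#' @export
kinematics_config <- function(v_start = 0.05, v_stop = 0.02,
                              run_start = 3, run_stop = 3,
                              pos_tol_m = 0.003, rest_window_s = 0.1,
                              min_range_m = 0.05, smooth_window = 0) {
  structure(list(v_start = v_start, v_stop = v_stop, run_start = run_start,
                 run_stop = run_stop, pos_tol_m = pos_tol_m,
                 rest_window_s = rest_window_s, min_range_m = min_range_m,
                 smooth_window = smooth_window),
            class = "kinematics_config")
}

#' Numerical differentiation of a uniformly sampled series
#'
#' Central differences in the interior and one-sided differences at the ends,
#' with optional centered moving-average pre-smoothing. Applied once it turns
#' position into velocity; applied to the velocity it yields acceleration.
#'
#' @param x numeric series (metres, or m/s for a second differentiation).
#' @param fps sampling rate, frames per second.
#' @param smooth_window moving-average window in samples (0 or 1 = off).
#' @return numeric series of the same length.
#' @export
differentiate_series <- function(x, fps, smooth_window = 0) {
  n <- length(x)
  if (n < 3) stop("differentiate_series: need at least 3 samples")
  stopifnot(fps > 0, all(is.finite(x)))
  if (smooth_window > 1) x <- moving_average(x, smooth_window)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fps / 2
  v[1] <- (x[2] - x[1]) * fps
  v[n] <- (x[n] - x[n - 1]) * fps
  v
}

moving_average <- function(x, w) {
  w <- as.integer(w)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- (w - 1) %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (w - 1 - half), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Load configuration for force computation
#'
#' @param m_a athlete body mass, kg.
#' @param m_l external load mass, kg.
#' @param g gravitational acceleration, m/s^2 (default 9.81).
#' @return list of class `load_config`.
#' @export
load_config <- function(m_a, m_l, g = 9.81) {
  stopifnot(m_a >= 0, m_l >= 0, g > 0)
  structure(list(m_a = m_a, m_l = m_l, g = g), class = "load_config")
}

#' Instantaneous force and power
#'
#' `F(t) = (m_a + m_l) * (a_b(t) + g)`: the system mass (athlete plus
#' external load, the centre-of-mass displacement being equated to the
#' barbell displacement) times barbell acceleration plus gravity. Power is
#' the product of force and barbell velocity.
#'
#' @param accel barbell acceleration series, m/s^2.
#' @param vel barbell velocity series, m/s.
#' @param load [load_config()].
#' @return list with `force` (N) and `power` (W) series.
#' @export
compute_force_power <- function(accel, vel, load) {
  if (length(accel) != length(vel))
    stop("compute_force_power: series lengths differ")
  force <- (load$m_a + load$m_l) * (accel + load$g)
  list(force = force, power = force * vel)
}

#' Segment the concentric (lifting) phases of a height series
#'
#' Scans the height series for ascents: the trigger is `run_start`
#' consecutive velocity samples above `v_start`; the start is refined
#' backwards to the last sample of the preceding rest plateau. The end is
#' the first sample at the post-lift plateau, found after velocity drops
#' below `v_stop` (or turns non-positive) for `run_stop` samples and the
#' height stops rising within the `rest_window_s` lookahead. Segments with
#' range below `min_range_m` are discarded. Returns all repetitions in
#' order; no ascent is an empty result, not an error.
#'
#' @param height height series, metres (up positive).
#' @param fps sampling rate.
#' @param config [kinematics_config()].
#' @return data.frame with columns `start`, `end` (sample indices).
#' @export
segment_concentric_phase <- function(height, fps, config = kinematics_config()) {
  n <- length(height)
  if (n < ceiling(0.2 * fps))
    stop("segment_concentric_phase: series shorter than 0.2 s")
  v <- differentiate_series(height, fps, config$smooth_window)
  K <- max(1L, round(config$rest_window_s * fps))
  tol <- config$pos_tol_m
  eq <- 1e-6  # near-equality for plateau membership
  up <- v > config$v_start
  segs <- list()
  i <- 1L
  floor_idx <- 1L  # never walk back into the previous repetition
  while (i <= n - config$run_start) {
    # ascent trigger: run_start consecutive samples with v > v_start
    trig <- NA_integer_
    run <- 0L
    for (j in i:n) {
      run <- if (up[j]) run + 1L else 0L
      if (run >= config$run_start) { trig <- j - config$run_start + 1L; break }
    }
    if (is.na(trig)) break
    # walk back over the early ascent and across the rest plateau, then take
    # the last sample still at the plateau level: the instant before the
    # beginning of the ascent
    j <- trig
    while (j > floor_idx && height[j - 1] <= height[j] + eq) j <- j - 1L
    plateau <- height[j]
    start <- j
    for (k in j:trig) if (height[k] <= plateau + eq) start <- k
    # cessation: velocity low for run_stop samples and no further rise within
    # the lookahead window (pauses mid-lift look ahead and keep going)
    end <- NA_integer_
    run <- 0L
    k <- trig
    while (k <= n) {
      low <- v[k] <= 0 || abs(v[k]) < config$v_stop
      run <- if (low) run + 1L else 0L
      if (run >= config$run_stop) {
        ahead <- if (k < n) height[(k + 1):min(n, k + K)] else numeric(0)
        if (length(ahead) == 0 || max(ahead) <= height[k] + tol) {
          end <- k; break
        }
      }
      k <- k + 1L
    }
    if (is.na(end)) end <- n
    # the stop trigger can fire while the last millimetres are still rising:
    # extend to the end of the monotone rise, then take the first sample of
    # the final plateau
    while (end < n && height[end + 1] > height[end] + eq) end <- end + 1L
    plat_end <- height[end]
    e <- end
    for (k in end:trig) if (height[k] >= plat_end - eq) e <- k
    if (height[e] - height[start] >= config$min_range_m)
      segs[[length(segs) + 1L]] <- c(start = start, end = e)
    floor_idx <- end
    i <- end + 1L
  }
  if (length(segs) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  as.data.frame(do.call(rbind, segs))
}

#' Per-repetition kinematic summary
#'
#' Range, mean and peak velocity, mean force and power, and time to peak
#' velocity over one concentric segment. Mean values are computed over the
#' time interval required to complete the concentric range of motion.
#'
#' @param height height series, metres.
#' @param fps sampling rate.
#' @param segment list or one-row data.frame with `start` and `end` indices.
#' @param load [load_config()]; optional — without it force and power are
#'   `NA`.
#' @param smooth_window optional moving-average window for differentiation.
#' @return one-row data.frame of class `rep_metrics`: `range_cm`,
#'   `mean_velocity_mps`, `peak_velocity_mps`, `mean_force_N`,
#'   `mean_power_W`, `time_to_peak_ms`, `duration_s`, `valid`.
#' @export
summarize_repetition <- function(height, fps, segment, load = NULL,
                                 smooth_window = 0) {
  s <- segment$start; e <- segment$end
  if (is.null(s) || is.null(e) || length(s) != 1 || s >= e ||
      s < 1 || e > length(height))
    stop("summarize_repetition: invalid segment")
  v <- differentiate_series(height, fps, smooth_window)
  a <- differentiate_series(v, fps)
  idx <- s:e
  range_m <- height[e] - height[s]
  duration <- (e - s) / fps
  mean_v <- mean(v[idx])
  peak_i <- idx[which.max(v[idx])]
  fp <- if (!is.null(load)) compute_force_power(a[idx], v[idx], load) else
    list(force = NA_real_, power = NA_real_)
  out <- data.frame(
    range_cm = 100 * range_m,
    mean_velocity_mps = mean_v,
    peak_velocity_mps = max(v[idx]),
    mean_force_N = mean(fp$force),
    mean_power_W = mean(fp$power),
    time_to_peak_ms = 1000 * (peak_i - s) / fps,
    duration_s = duration,
    valid = range_m > 0 && mean_v > 0)
  class(out) <- c("rep_metrics", "data.frame")
  out
}

#' Analyze a height series into per-repetition metrics
#'
#' Convenience wrapper: segments the concentric phases and summarizes each.
#'
#' @param height height series (m) or a world-mapped `marker_track`.
#' @param fps sampling rate (taken from the track when omitted).
#' @param load [load_config()] or `NULL`.
#' @param config [kinematics_config()].
#' @return data.frame with one row per repetition.
#' @export
analyze_height_series <- function(height, fps = NULL, load = NULL,
                                  config = kinematics_config()) {
  if (inherits(height, "marker_track")) {
    fps <- fps %||% attr(height, "fps")
    height <- track_height(height)
  }
  stopifnot(!is.null(fps))
  segs <- segment_concentric_phase(height, fps, config)
  if (nrow(segs) == 0)
    return(data.frame(rep = integer(0), start = integer(0), end = integer(0)))
  out <- do.call(rbind, lapply(seq_len(nrow(segs)), function(i) {
    cbind(rep = i, segs[i, , drop = FALSE],
          summarize_repetition(height, fps, segs[i, ], load,
                               smooth_window = config$smooth_window))
  }))
  rownames(out) <- NULL
  out
}
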