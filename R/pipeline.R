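#' Frame sources
#'
#' A frame source is the input abstraction of the pipeline: a list with
#' `n_frames`, `fps`, `width`, `height`, and `get(i, cols = NULL)` returning
#' frame `i` as an RGB array (rows x cols x 3, values in `[0, 1]`),
#' optionally restricted to a column window `cols = c(first, last)` so that
#' per-frame strip processing never touches whole frames. Returned arrays
#' may be reused between calls and must not be kept across them.
#'
#' `read_frames()` builds a source from a directory of numbered PNG images;
#' `frame_source()` from an in-memory list of arrays.
#'
#' @param path directory containing the frames (`*.png`, sorted by name).
#' @param fps nominal frame rate; taken from configuration rather than
#'   container metadata, which is unreliable in high-speed modes.
#' @return a `frame_source` object.
#' @export
read_frames <- function(path, fps) {
  if (!dir.exists(path)) stop("read_frames: not a directory: ", path)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("read_frames: no PNG frames in ", path)
  first <- png::readPNG(files[1])
  if (length(dim(first)) == 2) first <- array(rep(first, 3), c(dim(first), 3))
  d <- dim(first)
  get <- function(i, cols = NULL) {
    if (i < 1 || i > length(files)) stop("read_frames: frame index out of range")
    f <- tryCatch(png::readPNG(files[i]),
                  error = function(e) stop("read_frames: unreadable frame ", i,
                                           " (", files[i], ")"))
    if (length(dim(f)) == 2) f <- array(rep(f, 3), c(dim(f), 3))
    if (!all(dim(f)[1:2] == d[1:2]))
      stop("read_frames: dimension mismatch at frame ", i)
    if (dim(f)[3] > 3) f <- f[, , 1:3, drop = FALSE]
    if (is.null(cols)) f else f[, cols[1]:cols[2], , drop = FALSE]
  }
  structure(list(n_frames = length(files), fps = fps, width = d[2],
                 height = d[1], get = get),
            class = "frame_source")
}

#' @rdname read_frames
#' @param frames list of RGB arrays of identical dimensions.
#' @export
frame_source <- function(frames, fps) {
  stopifnot(length(frames) >= 1)
  d <- dim(frames[[1]])
  for (f in frames) if (!all(dim(f)[1:2] == d[1:2]))
    stop("frame_source: dimension mismatch between frames")
  get <- function(i, cols = NULL) {
    f <- frames[[i]]
    if (is.null(cols)) f else f[, cols[1]:cols[2], , drop = FALSE]
  }
  structure(list(n_frames = length(frames), fps = fps, width = d[2],
                 height = d[1], get = get),
            class = "frame_source")
}

#' Pipeline configuration
#'
#' @param geometry [machine_geometry()] object or path to a geometry YAML.
#' @param load [load_config()] or `NULL` (velocity/range only).
#' @param fps frame rate override (defaults to the source's).
#' @param focal_px known focal length in pixels; `NULL` self-calibrates from
#'   the structural homography (requires a non-fronto-parallel view).
#' @param detection [detection_config()].
#' @param kinematics [kinematics_config()].
#' @param dg_sign guide-plane direction, see
#'   [synthesize_guide_correspondences()].
#' @param output_dir write `track.csv`, `reps.csv`, `reps.json` and
#'   `calibration.json` there when non-`NULL`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry, load = NULL, fps = NULL,
                            focal_px = NULL, detection = detection_config(),
                            kinematics = kinematics_config(), dg_sign = +1,
                            output_dir = NULL) {
  if (is.character(geometry)) geometry <- read_machine_geometry(geometry)
  stopifnot(inherits(geometry, "machine_geometry"))
  structure(list(geometry = geometry, load = load, fps = fps,
                 focal_px = focal_px, detection = detection,
                 kinematics = kinematics, dg_sign = dg_sign,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full measurement pipeline
#'
#' Calibrate on the first frame (reference-corner detection, two-plane
#' homography calibration), track the barbell marks across all frames inside
#' the search strips, fill detection gaps by interpolation, map the mark
#' corners to metric guide-plane coordinates, and extract per-repetition
#' kinematics. Per-frame detection failures are logged and bridged by
#' interpolation; calibration failure aborts with a stage-named error.
#'
#' @param input a `frame_source`, a [render_scene()] result, or a directory
#'   path of PNG frames.
#' @param config [pipeline_config()].
#' @return list of class `pipeline_result`: `calibration`, `track`, `reps`,
#'   `height`, `counts` (detected/interpolated/missing), `timings_s`.
#' @export
run_pipeline <- function(input, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(input, "rendered_scene")) input <- input$source
  if (is.character(input)) {
    if (is.null(config$fps)) stop("input: fps must be set in the config for frame directories")
    input <- read_frames(input, config$fps)
  }
  if (!inherits(input, "frame_source")) stop("input: not a frame source")
  fps <- config$fps %||% input$fps
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  first <- input$get(1)
  det <- tryCatch(detect_reference_corners(first, config$detection),
                  error = function(e) stop("calibration: ", conditionMessage(e),
                                           call. = FALSE))
  calib <- tryCatch(calibrate_machine(det$corners, config$geometry,
                                      image_size = c(input$width, input$height),
                                      focal_px = config$focal_px,
                                      dg_sign = config$dg_sign),
                    error = function(e) stop("calibration: ", conditionMessage(e),
                                             call. = FALSE))
  strips <- build_search_strips(det$left, det$right, input$width,
                                config$detection)
  timings["calibration"] <- tic() - t0

  t0 <- tic()
  track <- track_barbell(input, strips, config$detection)
  track <- fill_missing_detections(track)
  track <- track_world_positions(track, calib$Hg)
  timings["tracking"] <- tic() - t0

  t0 <- tic()
  height <- track_height(track)
  reps <- analyze_height_series(height, fps, config$load, config$kinematics)
  timings["kinematics"] <- tic() - t0

  counts <- table(factor(track$status,
                         levels = c("detected", "interpolated", "missing")))
  res <- structure(list(calibration = calib, track = track, reps = reps,
                        height = height, fps = fps,
                        counts = as.list(counts),
                        timings_s = as.list(round(timings, 3))),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_result(res, config$output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d frames at %g fps; %d detected, %d interpolated, %d missing\n",
              attr(x$track, "n_frames"), x$fps, x$counts$detected,
              x$counts$interpolated, x$counts$missing))
  if (nrow(x$reps)) {
    cat(sprintf(" %d repetition(s):\n", nrow(x$reps)))
    print(x$reps[, c("rep", "range_cm", "mean_velocity_mps",
                     "peak_velocity_mps", "mean_force_N", "mean_power_W")],
          row.names = FALSE)
  } else cat(" no concentric repetitions found\n")
  invisible(x)
}

#' Write pipeline outputs (track CSV, rep report CSV/JSON, calibration JSON)
#' @param res [run_pipeline()] result.
#' @param dir output directory (created).
#' @export
write_pipeline_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_track(res$track, file.path(dir, "track.csv"))
  write.csv(res$reps, file.path(dir, "reps.csv"), row.names = FALSE)
  jsonlite::write_json(list(reps = res$reps, counts = res$counts,
                            fps = res$fps),
                       file.path(dir, "reps.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  write_calibration(res$calibration, file.path(dir, "calibration.json"))
  invisible(dir)
}
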