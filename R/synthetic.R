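# Synthetic multipower-machine scenes with full ground truth. Two parallel
# planes: striped warning tape on the structural plane (Z = 0) and colored
# barbell marks on the guide plane (Z = Dg), projected through a pinhole
# camera at an arbitrary pose and rasterized without anti-aliasing, so the
# ground-truth pixel positions are exact projections.

#' Barbell motion profile
#'
#' A rest -> concentric lift -> rest height trajectory with closed-form mean
#' and peak velocity. Families: `"constant"` (constant-velocity ramp),
#' `"half_sine"` (half-sine velocity pulse, peak = pi/2 times the mean) and
#' `"min_jerk"` (minimum-jerk, peak = 1.875 times the mean).
#'
#' @param family profile family.
#' @param range_m lift range, metres (> 0).
#' @param duration_s lift duration, seconds (> 0).
#' @param fps frame rate.
#' @param rest_before_s,rest_after_s rest padding, seconds.
#' @return list of class `motion_profile`: sampled `height` (m, starting at
#'   0), `times`, `fps`, and `truth` (range, duration, mean and peak
#'   velocity, lift start/end times).
#' @export
motion_profile <- function(family = c("constant", "half_sine", "min_jerk"),
                           range_m, duration_s, fps,
                           rest_before_s = 0.25, rest_after_s = 0.25) {
  family <- match.arg(family)
  if (!is.numeric(range_m) || range_m <= 0 || !is.numeric(duration_s) ||
      duration_s <= 0 || fps <= 0)
    stop("motion_profile: range, duration and fps must be positive")
  disp <- switch(family,
    constant = function(tau) tau,
    half_sine = function(tau) (1 - cos(pi * tau)) / 2,
    min_jerk = function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  peak_factor <- switch(family, constant = 1, half_sine = pi / 2,
                        min_jerk = 1.875)
  total <- rest_before_s + duration_s + rest_after_s
  n <- floor(total * fps) + 1
  times <- (seq_len(n) - 1) / fps
  tau <- pmin(pmax((times - rest_before_s) / duration_s, 0), 1)
  height <- range_m * disp(tau)
  structure(list(height = height, times = times, fps = fps, family = family,
                 truth = list(range_m = range_m, duration_s = duration_s,
                              mean_velocity_mps = range_m / duration_s,
                              peak_velocity_mps = peak_factor * range_m / duration_s,
                              lift_start_s = rest_before_s,
                              lift_end_s = rest_before_s + duration_s)),
            class = "motion_profile")
}

#' Synthetic scene specification
#'
#' Geometry of the virtual machine, the tape and mark layout, and the camera.
#' Scene coordinates: X rightward from the left edge of the left tape, Y
#' downward from the top of the left tape, Z away from the camera; the
#' structural plane is Z = 0 and the guide (barbell) plane Z = `Dg`. The
#' default portrait camera (1080 x 1920) at 2.2 m frames a 150 cm-wide
#' machine with a pixel pitch of about 2 mm.
#'
#' @param image_width,image_height sensor size, pixels.
#' @param machine_width_m distance between the outer tape edges, metres.
#' @param tape_width_m,stripe_period_m,n_stripes tape strip layout; each tape
#'   carries `n_stripes` colored stripes of height `stripe_period_m / 2`.
#' @param right_tape_offset_y_m vertical offset of the right tape (real tapes
#'   are never glued perfectly level).
#' @param Dg_m structural-to-guide plane gap.
#' @param palette `"red_white"` (red stripes, hue 0) or `"black_yellow"`
#'   (yellow stripes, hue 1/6).
#' @param mark_hue,mark_size_m,mark_offset_x_m barbell mark color, square
#'   side, and horizontal offset of each mark from its pillar.
#' @param bar_y0_m initial (lowest) Y of the mark's upper-left corner.
#' @param camera_distance_m,camera_tilt_deg,camera_yaw_deg camera pose: the
#'   optical axis always aims at the machine centre.
#' @param focal_px focal length; `NULL` picks one framing `coverage_m`
#'   horizontally.
#' @param coverage_m horizontal scene coverage at the structural plane.
#' @param background_gray background intensity.
#' @param noise_sd additive Gaussian pixel noise SD (0 = noiseless).
#' @param illumination_gradient peak-to-peak relative multiplicative
#'   brightness gradient across the image (0 = flat).
#' @param seed RNG seed for noise.
#' @param blank_frames frames in which marks are not drawn (occlusion tests).
#' @param distractors list of world-rectangle distractors, each
#'   `list(x, y, w, h, color)` on the structural plane.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(image_width = 1080, image_height = 1920,
                       machine_width_m = 1.5,
                       tape_width_m = 0.07, stripe_period_m = 0.19,
                       n_stripes = 7, right_tape_offset_y_m = 0.02,
                       Dg_m = 0.15,
                       palette = c("red_white", "black_yellow"),
                       mark_hue = NULL, mark_size_m = 0.05,
                       mark_offset_x_m = 0.18, bar_y0_m = 1.0,
                       camera_distance_m = 2.2, camera_tilt_deg = 0,
                       camera_yaw_deg = 0, focal_px = NULL,
                       coverage_m = 2.1, background_gray = 0.55,
                       noise_sd = 0, illumination_gradient = 0, seed = 1,
                       blank_frames = integer(0), distractors = list()) {
  palette <- match.arg(palette)
  stripe_hue <- if (palette == "red_white") 0 else 1 / 6
  mark_hue <- mark_hue %||% (if (palette == "red_white") 1 / 6 else 0)
  focal_px <- focal_px %||% (image_width * camera_distance_m / coverage_m)
  spec <- list(image_width = image_width, image_height = image_height,
               machine_width_m = machine_width_m, tape_width_m = tape_width_m,
               stripe_period_m = stripe_period_m, n_stripes = n_stripes,
               right_tape_offset_y_m = right_tape_offset_y_m, Dg_m = Dg_m,
               palette = palette, stripe_hue = stripe_hue,
               mark_hue = mark_hue, mark_size_m = mark_size_m,
               mark_offset_x_m = mark_offset_x_m, bar_y0_m = bar_y0_m,
               camera_distance_m = camera_distance_m,
               camera_tilt_deg = camera_tilt_deg,
               camera_yaw_deg = camera_yaw_deg, focal_px = focal_px,
               background_gray = background_gray, noise_sd = noise_sd,
               illumination_gradient = illumination_gradient, seed = seed,
               blank_frames = as.integer(blank_frames),
               distractors = distractors)
  class(spec) <- "scene_spec"
  spec
}

hue_rgb <- function(hue) as.numeric(grDevices::col2rgb(grDevices::hsv(hue, 1, 1))) / 255

scene_camera <- function(spec) {
  intr <- camera_intrinsics(f_x = spec$focal_px,
                            width = spec$image_width,
                            height = spec$image_height)
  tape_len <- spec$n_stripes * spec$stripe_period_m
  centre <- c(spec$machine_width_m / 2, tape_len / 2, 0)
  tilt <- spec$camera_tilt_deg * pi / 180
  yaw <- spec$camera_yaw_deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(tilt), -sin(tilt), 0, sin(tilt), cos(tilt)),
               3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(yaw), 0, sin(yaw), 0, 1, 0, -sin(yaw), 0, cos(yaw)),
               3, 3, byrow = TRUE)
  R <- Rx %*% Ry
  # camera centre chosen so the optical axis passes through the machine centre
  C <- centre - spec$camera_distance_m * as.numeric(t(R) %*% c(0, 0, 1))
  pose <- plane_pose(R, as.numeric(-R %*% C))
  list(intr = intr, pose = pose)
}

# world rectangles (structural plane) of the red/yellow stripes on one tape
scene_stripes <- function(spec, side) {
  x0 <- if (side == "left") 0 else spec$machine_width_m - spec$tape_width_m
  y0 <- if (side == "left") 0 else spec$right_tape_offset_y_m
  p <- spec$stripe_period_m
  lapply(seq_len(spec$n_stripes) - 1, function(j)
    list(x = x0, y = y0 + j * p, w = spec$tape_width_m, h = p / 2))
}

scene_mark_rect <- function(spec, side, height_m) {
  x0 <- if (side == "left") spec$mark_offset_x_m else
    spec$machine_width_m - spec$mark_offset_x_m - spec$mark_size_m
  list(x = x0, y = spec$bar_y0_m - height_m, w = spec$mark_size_m,
       h = spec$mark_size_m)
}

rect_corners <- function(r, z) {
  cbind(X = c(r$x, r$x + r$w, r$x + r$w, r$x),
        Y = c(r$y, r$y, r$y + r$h, r$y + r$h),
        Z = z)
}

# fill a convex quad (4x2 projected pixel corners, in cyclic order) with a
# color; a pixel is covered when its centre (at integer coordinates) lies
# inside the polygon. `cols_range` gives the full-frame column range when
# `img` is a column crop.
raster_fill <- function(img, quad, color, cols_range = NULL) {
  H <- dim(img)[1]; W <- dim(img)[2]
  clo <- if (is.null(cols_range)) 1L else as.integer(cols_range[1])
  chi <- if (is.null(cols_range)) W else as.integer(cols_range[2])
  off <- clo - 1L
  xr <- range(quad[, 1]); yr <- range(quad[, 2])
  c0 <- max(clo, ceiling(xr[1] - 1e-9)); c1 <- min(chi, floor(xr[2] + 1e-9))
  r0 <- max(1L, ceiling(yr[1] - 1e-9)); r1 <- min(H, floor(yr[2] + 1e-9))
  if (c0 > c1 || r0 > r1) return(img)
  cc <- c0:c1; rr <- r0:r1
  px <- rep(cc, each = length(rr))
  py <- rep(rr, times = length(cc))
  s <- matrix(0, length(px), 4)
  for (i in 1:4) {
    j <- i %% 4 + 1
    ex <- quad[j, 1] - quad[i, 1]; ey <- quad[j, 2] - quad[i, 2]
    s[, i] <- ex * (py - quad[i, 2]) - ey * (px - quad[i, 1])
  }
  inside <- rowSums(s >= 0) == 4 | rowSums(s <= 0) == 4
  if (!any(inside)) return(img)
  ri <- py[inside]; ci <- px[inside] - off
  for (ch in 1:3) img[cbind(ri, ci, ch)] <- color[ch]
  img
}

project_rect <- function(r, z, cam) {
  project_point(rect_corners(r, z), cam$intr, cam$pose)
}

#' Render a synthetic lift sequence
#'
#' Rasterizes the scene for every frame of a motion profile and records the
#' exact ground truth. Returns a frame source (frames are composed on
#' demand, optionally restricted to a column window) plus ground truth:
#' true reference-corner pixels, the machine geometry measured from the true
#' corner coordinates, per-frame true mark positions (world and pixel), and
#' the true height series.
#'
#' @param spec [scene_spec()].
#' @param profile [motion_profile()].
#' @return list of class `rendered_scene` with elements `source` (a frame
#'   source: `n_frames`, `fps`, `width`, `height`, `get(i, cols)`), `truth`,
#'   `geometry` ([machine_geometry()]), `camera` (intrinsics + pose).
#' @export
render_scene <- function(spec, profile) {
  cam <- scene_camera(spec)
  W <- spec$image_width; H <- spec$image_height
  stripe_col <- hue_rgb(spec$stripe_hue)
  base_col <- if (spec$palette == "red_white") c(1, 1, 1) else c(0, 0, 0)
  mark_col <- hue_rgb(spec$mark_hue)
  bg <- array(spec$background_gray, c(H, W, 3))

  # static layer: tape base rectangles and stripes, plus distractors
  static <- bg
  tape_len <- spec$n_stripes * spec$stripe_period_m
  for (side in c("left", "right")) {
    x0 <- if (side == "left") 0 else spec$machine_width_m - spec$tape_width_m
    y0 <- if (side == "left") 0 else spec$right_tape_offset_y_m
    base <- list(x = x0, y = y0, w = spec$tape_width_m, h = tape_len)
    static <- raster_fill(static, project_rect(base, 0, cam), base_col)
    for (s in scene_stripes(spec, side))
      static <- raster_fill(static, project_rect(s, 0, cam), stripe_col)
  }
  for (d in spec$distractors)
    static <- raster_fill(static, project_rect(d, 0, cam), d$color %||% hue_rgb(0))

  # ground truth: reference corners are the upper-left corners of the highest
  # and lowest stripes on each side
  corner_world <- function(side, which) {
    s <- scene_stripes(spec, side)
    r <- if (which == "top") s[[1]] else s[[length(s)]]
    c(r$x, r$y)
  }
  ref_world <- rbind(P1 = corner_world("left", "top"),
                     P2 = corner_world("left", "bottom"),
                     P3 = corner_world("right", "bottom"),
                     P4 = corner_world("right", "top"))
  colnames(ref_world) <- c("X", "Y")
  ref_pix <- project_point(cbind(ref_world, Z = 0), cam$intr, cam$pose)
  dists <- quad_distances(ref_world)
  geometry <- machine_geometry(dists["D12s"], dists["D23s"], dists["D34s"],
                               dists["D41s"], dists["D13s"], dists["D24s"],
                               spec$Dg_m)

  n <- length(profile$height)
  if (any(spec$blank_frames < 1 | spec$blank_frames > n))
    stop("render_scene: blank_frames outside the sequence")
  mark_world <- array(NA_real_, c(n, 2, 2),
                      dimnames = list(NULL, c("left", "right"), c("X", "Y")))
  mark_pix <- mark_world
  for (i in seq_len(n)) {
    for (side in c("left", "right")) {
      r <- scene_mark_rect(spec, side, profile$height[i])
      mark_world[i, side, ] <- c(r$x, r$y)
      mark_pix[i, side, ] <- project_point(c(r$x, r$y, spec$Dg_m),
                                           cam$intr, cam$pose)
    }
  }
  # field-of-view check on the mark path
  bad <- which(mark_pix[, , 1] < 1 | mark_pix[, , 1] > W |
               mark_pix[, , 2] < 1 | mark_pix[, , 2] > H, arr.ind = TRUE)
  if (length(bad))
    stop("render_scene: bar path leaves the field of view at frames ",
         paste(unique(bad[, 1]), collapse = ", "))

  illum <- NULL
  if (spec$illumination_gradient > 0)
    illum <- 1 + spec$illumination_gradient * ((seq_len(H) - 1) / (H - 1) - 0.5)

  get <- function(i, cols = NULL) {
    stopifnot(i >= 1, i <= n)
    cr <- if (is.null(cols)) c(1L, W) else as.integer(cols)
    frame <- static[, cr[1]:cr[2], , drop = FALSE]
    if (!(i %in% spec$blank_frames)) {
      for (side in c("left", "right")) {
        r <- scene_mark_rect(spec, side, profile$height[i])
        frame <- raster_fill(frame, project_rect(r, spec$Dg_m, cam),
                             mark_col, cols_range = cr)
      }
    }
    if (!is.null(illum)) frame <- frame * illum  # recycles down rows
    if (spec$noise_sd > 0) {
      frame <- frame + with_local_seed(spec$seed + i,
        array(rnorm(length(frame), 0, spec$noise_sd), dim(frame)))
    }
    if (!is.null(illum) || spec$noise_sd > 0)
      frame <- pmin(pmax(frame, 0), 1)
    frame
  }
  source <- list(n_frames = n, fps = profile$fps, width = W, height = H,
                 get = get)
  class(source) <- "frame_source"
  truth <- list(ref_world = ref_world, ref_pix = ref_pix,
                mark_world = mark_world, mark_pix = mark_pix,
                height = profile$height - profile$height[1],
                profile = profile$truth, fps = profile$fps)
  structure(list(source = source, truth = truth, geometry = geometry,
                 camera = cam, spec = spec),
            class = "rendered_scene")
}

#' Generate paired measurements with a known agreement structure
#'
#' Emulates a two-instrument validation study: each subject has a true mean
#' drawn from `Normal(mu, between_sd^2)`; each repetition adds
#' `Normal(0, within_sd^2)`; system A measures the repetition value exactly
#' and system B differs by the systematic bias and instrument noise, so that
#' `a - b` has mean `bias` and SD `instrument_sd`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param reps_per_subject repetitions per subject.
#' @param mu grand mean of the measured variable.
#' @param between_sd between-subject SD (> 0).
#' @param within_sd within-subject (biological) SD (> 0).
#' @param bias systematic difference `a - b`.
#' @param instrument_sd SD of the instrument noise in the differences.
#' @param seed RNG seed (reproducible).
#' @return data.frame with columns `subject`, `rep`, `a`, `b`.
#' @export
generate_paired_measurements <- function(n_subjects, reps_per_subject,
                                         mu = 0.58, between_sd = 0.12,
                                         within_sd = 0.05, bias = -0.016,
                                         instrument_sd = 0.009, seed = 1) {
  if (n_subjects < 2 || reps_per_subject < 1 || between_sd <= 0 ||
      within_sd < 0 || instrument_sd < 0)
    stop("generate_paired_measurements: invalid parameters")
  with_local_seed(seed, {
    subj <- rep(seq_len(n_subjects), each = reps_per_subject)
    means <- rnorm(n_subjects, mu, between_sd)
    a <- means[subj] + rnorm(length(subj), 0, within_sd)
    b <- a - bias + rnorm(length(subj), 0, instrument_sd)
    data.frame(subject = subj,
               rep = rep(seq_len(reps_per_subject), n_subjects),
               a = a, b = b)
  })
}

#' Write rendered frames to a directory of PNGs plus a ground-truth JSON
#'
#' @param scene [render_scene()] output.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_scene_fixture <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- scene$source$n_frames
  for (i in seq_len(n))
    png::writePNG(scene$source$get(i),
                  file.path(dir, sprintf("frame_%05d.png", i)))
  tr <- scene$truth
  jsonlite::write_json(list(fps = tr$fps, height = tr$height,
                            ref_pix = tr$ref_pix, profile = tr$profile),
                       file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  write_machine_geometry(scene$geometry, file.path(dir, "geometry.yaml"))
  invisible(dir)
}
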