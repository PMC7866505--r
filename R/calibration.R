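#' Machine geometry measured with a tape measure
#'
#' Six distances between the four tape reference corners on the structural
#' pillars (four sides `D12s`, `D23s`, `D34s`, `D41s` and two diagonals
#' `D13s`, `D24s`), plus the perpendicular gap `Dg` between the structural
#' plane and the parallel guide (barbell) plane. Internally everything is
#' stored in metres; `units = "cm"` inputs are converted.
#'
#' Corner labels: P1 top-left, P2 bottom-left, P3 bottom-right, P4 top-right,
#' with image-like axes (x rightward, y downward).
#'
#' @param D12s,D23s,D34s,D41s side lengths of the reference quadrilateral.
#' @param D13s,D24s diagonals (P1-P3 and P2-P4).
#' @param Dg structural-to-guide plane gap.
#' @param units `"m"` (default) or `"cm"`.
#' @return An object of class `machine_geometry` (all fields in metres).
#' @export
machine_geometry <- function(D12s, D23s, D34s, D41s, D13s, D24s, Dg,
                             units = c("m", "cm")) {
  units <- match.arg(units)
  d <- c(D12s = unname(D12s), D23s = unname(D23s), D34s = unname(D34s),
         D41s = unname(D41s), D13s = unname(D13s), D24s = unname(D24s),
         Dg = unname(Dg))
  if (units == "cm") d <- d / 100
  if (any(!is.finite(d)) || any(d <= 0))
    stop("machine_geometry: all distances must be finite and positive")
  g <- as.list(d)
  # triangle inequalities for the four corner triangles
  tri <- list(P1P2P3 = c(g$D12s, g$D23s, g$D13s),
              P1P3P4 = c(g$D13s, g$D34s, g$D41s),
              P1P2P4 = c(g$D12s, g$D41s, g$D24s),
              P2P3P4 = c(g$D23s, g$D34s, g$D24s))
  for (nm in names(tri)) {
    s <- sort(tri[[nm]])
    if (s[1] + s[2] <= s[3])
      stop(sprintf("machine_geometry: triangle inequality violated in %s", nm))
  }
  structure(g, class = "machine_geometry")
}

#' @export
print.machine_geometry <- function(x, ...) {
  cat("machine_geometry (m): sides", sprintf("%.4f", c(x$D12s, x$D23s, x$D34s, x$D41s)),
      "diagonals", sprintf("%.4f", c(x$D13s, x$D24s)), "Dg", sprintf("%.4f", x$Dg), "\n")
  invisible(x)
}

#' Read/write a machine-geometry YAML file
#'
#' Expected YAML keys: `units` (`cm` or `m`), `D12s`, `D23s`, `D34s`, `D41s`,
#' `D13s`, `D24s`, `Dg`.
#'
#' @param path file path.
#' @return [machine_geometry()] object.
#' @export
read_machine_geometry <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("D12s", "D23s", "D34s", "D41s", "D13s", "D24s", "Dg")
  if (!all(need %in% names(y)))
    stop("read_machine_geometry: missing keys: ",
         paste(setdiff(need, names(y)), collapse = ", "))
  machine_geometry(y$D12s, y$D23s, y$D34s, y$D41s, y$D13s, y$D24s, y$Dg,
                   units = y$units %||% "m")
}

#' @rdname read_machine_geometry
#' @param geom [machine_geometry()] object.
#' @param units units to write (`"m"` or `"cm"`).
#' @export
write_machine_geometry <- function(geom, path, units = "m") {
  stopifnot(inherits(geom, "machine_geometry"))
  f <- if (units == "cm") 100 else 1
  yaml::write_yaml(c(list(units = units),
                     lapply(unclass(geom), function(v) v * f)), path)
  invisible(path)
}

#' Reconstruct the reference quadrilateral from the six measured distances
#'
#' Embeds the four structural reference points in the plane `Z = 0` by the law
#' of cosines: `P1 = (0, 0)` at the highest, leftmost corner, `P2` along +Y
#' (downward) at distance `D12s`, `P3` triangulated from `P1` (via the
#' diagonal `D13s`) and `P2` (via `D23s`) with `X > 0`, and `P4` triangulated
#' from `P1` (via `D41s`) and `P3` (via `D34s`) on the opposite side of the
#' P1-P3 diagonal from `P2`. The sixth, redundant distance `D24s` is a
#' consistency check on the tape measurements: a mismatch beyond
#' `tolerance_m` (default 5 mm, a realistic tape-measure error) is an error.
#'
#' @param geom [machine_geometry()].
#' @param tolerance_m tolerance for the redundant-distance check, metres.
#' @return 4x2 matrix of class `reference_quad` (rows P1..P4, columns X, Y in
#'   metres, `Z = 0` implied).
#' @export
reconstruct_reference_quad <- function(geom, tolerance_m = 0.005) {
  stopifnot(inherits(geom, "machine_geometry"))
  P1 <- c(0, 0)
  P2 <- c(0, geom$D12s)
  P3 <- triangulate_xy(P1, P2, geom$D13s, geom$D23s, sign = +1)
  # P4: distances to P1 (D41s) and P3 (D34s); pick the intersection on the
  # opposite side of the P1-P3 line from P2 (simple quadrilateral).
  cand <- triangulate_two(P1, P3, geom$D41s, geom$D34s)
  side <- function(p) sign((P3[1] - P1[1]) * (p[2] - P1[2]) -
                           (P3[2] - P1[2]) * (p[1] - P1[1]))
  P4 <- if (side(cand$a) != side(P2)) cand$a else cand$b
  quad <- rbind(P1 = P1, P2 = P2, P3 = P3, P4 = P4)
  colnames(quad) <- c("X", "Y")
  d24 <- vec_norm(quad["P2", ] - quad["P4", ])
  if (abs(d24 - geom$D24s) > tolerance_m)
    stop(sprintf(paste0("reconstruct_reference_quad: measurement inconsistency in D24s ",
                        "(reconstructed %.4f m vs measured %.4f m)"), d24, geom$D24s))
  structure(quad, class = c("reference_quad", class(quad)), geom = geom)
}

# intersection of circles |P-A| = ra, |P-B| = rb, both solutions
triangulate_two <- function(A, B, ra, rb) {
  d <- vec_norm(B - A)
  if (d <= 0) stop("triangulate: coincident base points")
  u <- (B - A) / d
  v <- c(-u[2], u[1])
  along <- (ra^2 - rb^2 + d^2) / (2 * d)
  h2 <- ra^2 - along^2
  if (h2 < -1e-12 * ra^2) stop("triangulate: circles do not intersect")
  h <- sqrt(max(h2, 0))
  list(a = A + along * u + h * v, b = A + along * u - h * v)
}

triangulate_xy <- function(A, B, ra, rb, sign = +1) {
  cand <- triangulate_two(A, B, ra, rb)
  if (sign * cand$a[1] >= 0) cand$a else cand$b
}

#' Pairwise distances of a reference quad
#' @param quad 4x2 matrix of corner coordinates (rows P1..P4).
#' @return named vector of the six distances (m), in `machine_geometry` order.
#' @export
quad_distances <- function(quad) {
  d <- function(i, j) vec_norm(quad[i, ] - quad[j, ])
  c(D12s = d(1, 2), D23s = d(2, 3), D34s = d(3, 4), D41s = d(4, 1),
    D13s = d(1, 3), D24s = d(2, 4))
}

#' Estimate the structural-plane homography and camera pose
#'
#' Computes `H_s` from the reconstructed reference quad and its four detected
#' pixel corners (ordered P1..P4), self-calibrates the focal length from
#' `H_s` when no intrinsics are supplied (principal point assumed at the
#' image centre), and recovers the scene-to-camera pose `T_scene2cam`.
#'
#' @param quad [reconstruct_reference_quad()] output (or any 4x2 metric quad).
#' @param pixels 4x2 matrix of pixel corners matching P1..P4.
#' @param intr optional [camera_intrinsics()]; if `NULL`, self-calibrated.
#' @param image_size `c(width, height)` in pixels, required when `intr` is
#'   `NULL`.
#' @param focal_px optional known focal length in pixels (e.g. from camera
#'   metadata), used instead of self-calibration when `intr` is `NULL`.
#' @return list of class `structural_calibration` with `Hs`, `pose`, `intr`
#'   and `residual_px` (max reprojection error of `Hs` on the four corners).
#' @export
calibrate_structural <- function(quad, pixels, intr = NULL, image_size = NULL,
                                 focal_px = NULL) {
  quad <- rbind2mat(quad); pixels <- rbind2mat(pixels)
  Hs <- estimate_homography(quad, pixels)
  if (is.null(intr)) {
    if (is.null(image_size))
      stop("calibrate_structural: image_size is required to place the principal point")
    cx <- image_size[1] / 2; cy <- image_size[2] / 2
    f <- focal_px %||% estimate_focal_from_homography(Hs, cx, cy)
    intr <- camera_intrinsics(f_x = f, c_x = cx, c_y = cy,
                              width = image_size[1], height = image_size[2])
  }
  pose <- pose_from_homography(Hs, intr)
  proj <- homography_apply(Hs, quad)
  residual <- max(sqrt(rowSums((proj - pixels)^2)))
  structure(list(Hs = Hs, pose = pose, intr = intr, residual_px = residual),
            class = "structural_calibration")
}

homography_apply <- function(H, pts) {
  pts <- rbind2mat(pts)
  v <- cbind(pts, 1) %*% t(H)
  cbind(v[, 1] / v[, 3], v[, 2] / v[, 3])
}

#' Synthesize guide-plane correspondences
#'
#' Places one virtual point behind each structural reference corner on the
#' guide pillars: `P_ig = (X_is, Y_is, Dg)` with Z oriented away from the
#' camera, so the guide plane is the farther of the two. The points are
#' projected through the recovered pose to obtain their pixel positions.
#'
#' @param quad reference quad (4x2, metres).
#' @param geom [machine_geometry()] supplying `Dg`.
#' @param intr [camera_intrinsics()].
#' @param pose [plane_pose()] from [calibrate_structural()].
#' @param dg_sign +1 (default) when the guide plane is behind the structural
#'   plane as seen from the camera; -1 for mirrored setups.
#' @return list with `world` (4x2 guide-plane `(X, Y)`) and `pixels` (4x2).
#' @export
synthesize_guide_correspondences <- function(quad, geom, intr, pose,
                                             dg_sign = +1) {
  quad <- rbind2mat(quad)
  world3 <- cbind(quad, Z = dg_sign * geom$Dg)
  pix <- project_point(world3, intr, pose)
  list(world = quad, pixels = pix)
}

#' Estimate the guide-plane homography
#'
#' @param guide_pairs output of [synthesize_guide_correspondences()].
#' @return 3x3 homography `H_g` mapping guide-plane `(X, Y)` (metres) to
#'   pixels.
#' @export
calibrate_guide <- function(guide_pairs) {
  estimate_homography(guide_pairs$world, guide_pairs$pixels)
}

#' Full two-plane machine calibration
#'
#' Runs the complete autocalibration for a session: reconstructs the metric
#' reference quad from the measured distances, estimates `H_s` and the camera
#' pose from the detected corner pixels, synthesizes the four guide-plane
#' correspondences at gap `Dg`, and computes `H_g`. `H_g` is computed once
#' per session and reused for every frame.
#'
#' @param corners 4x2 pixel matrix ordered P1..P4 (see
#'   [detect_reference_corners()]).
#' @param geom [machine_geometry()].
#' @param image_size `c(width, height)` pixels.
#' @param intr,focal_px,dg_sign see [calibrate_structural()] and
#'   [synthesize_guide_correspondences()].
#' @param tolerance_m redundant-distance tolerance passed to
#'   [reconstruct_reference_quad()].
#' @return list of class `calibration_result`: `Hs`, `pose`, `intr`, `Hg`,
#'   `quad`, `corners`, `geom`, `residual_px`.
#' @export
calibrate_machine <- function(corners, geom, image_size, intr = NULL,
                              focal_px = NULL, dg_sign = +1,
                              tolerance_m = 0.005) {
  quad <- reconstruct_reference_quad(geom, tolerance_m = tolerance_m)
  sc <- calibrate_structural(quad, corners, intr = intr,
                             image_size = image_size, focal_px = focal_px)
  gp <- synthesize_guide_correspondences(quad, geom, sc$intr, sc$pose,
                                         dg_sign = dg_sign)
  Hg <- calibrate_guide(gp)
  structure(list(Hs = sc$Hs, pose = sc$pose, intr = sc$intr, Hg = Hg,
                 quad = quad, corners = corners, geom = geom,
                 guide_pairs = gp, residual_px = sc$residual_px),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: residual %.3g px, f = %.1f px, Dg = %.3f m\n",
              x$residual_px, x$intr$f_x, x$geom$Dg))
  invisible(x)
}

#' Serialize a calibration result to JSON
#'
#' Writes intrinsics, `H_s`, pose (R, t), `H_g`, the reference quad, the
#' geometry (echoed bit-exact) and the reprojection residual.
#'
#' @param calib [calibrate_machine()] result.
#' @param path output path.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_result"))
  obj <- list(
    intrinsics = unclass(calib$intr),
    Hs = calib$Hs, Hg = calib$Hg,
    pose = list(rotation = calib$pose$rotation,
                translation = calib$pose$translation),
    quad = unclass(calib$quad),
    corners = calib$corners,
    geometry = unclass(calib$geom),
    residual_px = calib$residual_px)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  intr <- do.call(camera_intrinsics, o$intrinsics[c("f_x", "f_y", "c_x", "c_y",
                                                    "width", "height", "skew")])
  quad <- as.matrix(o$quad); colnames(quad) <- c("X", "Y")
  geom <- do.call(machine_geometry, o$geometry)
  structure(list(Hs = as.matrix(o$Hs), pose = plane_pose(as.matrix(o$pose$rotation),
                                                         o$pose$translation),
                 intr = intr, Hg = as.matrix(o$Hg), quad = quad,
                 corners = as.matrix(o$corners), geom = geom,
                 residual_px = o$residual_px),
            class = "calibration_result")
}
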