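#' Camera intrinsics
#'
#' Pinhole-camera intrinsic parameters. Pixel coordinates have their origin at
#' the upper-left image corner, x rightward and y downward. The skew factor is
#' fixed at 0 by default: modern smartphone sensors have square, axis-aligned
#' pixels, so the intrinsic matrix is `K = [[f_x, 0, c_x], [0, f_y, c_y],
#' [0, 0, 1]]`.
#'
#' @param f_x,f_y focal length in pixel units (`f_y` defaults to `f_x`).
#' @param c_x,c_y principal point in pixels from the upper-left corner.
#' @param width,height sensor size in pixels.
#' @param skew sensor skew factor, dimensionless (default 0).
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(f_x, f_y = f_x, c_x = width / 2, c_y = height / 2,
                              width, height, skew = 0) {
  stopifnot(is.numeric(f_x), f_x > 0, f_y > 0,
            c_x >= 0, c_x <= width, c_y >= 0, c_y <= height)
  structure(list(f_x = f_x, f_y = f_y, skew = skew,
                 c_x = c_x, c_y = c_y, width = width, height = height),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: f = (%.2f, %.2f) px, c = (%.2f, %.2f), %d x %d px\n",
              x$f_x, x$f_y, x$c_x, x$c_y, x$width, x$height))
  invisible(x)
}

#' Intrinsic matrix K
#' @param intr a [camera_intrinsics()] object.
#' @return 3x3 numeric matrix.
#' @export
intrinsics_matrix <- function(intr) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  matrix(c(intr$f_x, 0, 0,
           intr$skew, intr$f_y, 0,
           intr$c_x, intr$c_y, 1), 3, 3)
}

#' Rigid scene-to-camera transform
#'
#' The pose `T_scene2cam` mapping scene coordinates (metres) to camera
#' coordinates: `p_cam = R p_scene + t`. The rotation must be orthonormal with
#' determinant +1 (checked within 1e-8).
#'
#' @param rotation 3x3 orthonormal matrix.
#' @param translation length-3 numeric vector, metres.
#' @return An object of class `plane_pose`.
#' @export
plane_pose <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("plane_pose: rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("plane_pose: rotation determinant is not +1")
  structure(list(rotation = rotation, translation = translation),
            class = "plane_pose")
}

#' @export
print.plane_pose <- function(x, ...) {
  cat("plane_pose (T_scene2cam):\n rotation:\n")
  print(round(x$rotation, 6))
  cat(" translation (m):", round(x$translation, 6), "\n")
  invisible(x)
}

#' Perspective projection of scene points
#'
#' Projects world points through the pinhole model: with homogeneous pixel
#' coordinates `(a, b, c) = K (R P + t)`, the image position is `x = a/c`,
#' `y = b/c`. Points must lie in front of the camera (positive depth).
#'
#' @param p numeric length-3 vector or n x 3 matrix of scene points, metres.
#' @param intr [camera_intrinsics()].
#' @param pose [plane_pose()]; defaults to the identity pose.
#' @return n x 2 matrix of pixel coordinates (columns `x`, `y`).
#' @export
project_point <- function(p, intr, pose = plane_pose(diag(3), c(0, 0, 0))) {
  p <- rbind2mat(p)
  pc <- p %*% t(pose$rotation)
  pc <- sweep(pc, 2, pose$translation, "+")
  if (any(pc[, 3] <= 0))
    stop("project_point: point behind camera (non-positive depth)")
  K <- intrinsics_matrix(intr)
  h <- pc %*% t(K)
  cbind(x = h[, 1] / h[, 3], y = h[, 2] / h[, 3])
}

rbind2mat <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p <- as.matrix(p)
  stopifnot(is.numeric(p), all(is.finite(p)))
  p
}

#' Estimate a plane-to-image homography (DLT)
#'
#' Direct linear transform with Hartley normalization (both point sets are
#' translated to zero centroid and scaled to RMS distance sqrt(2) before
#' assembling the design matrix). At least four correspondences are required
#' and no three world points may be collinear.
#'
#' @param world_pts n x 2 matrix of plane coordinates (metres).
#' @param pixel_pts n x 2 matrix of matching pixel coordinates.
#' @return 3x3 homography matrix mapping `(X, Y, 1)` to homogeneous pixels,
#'   normalized so the (3,3) entry is 1 when nonzero (unit Frobenius norm
#'   otherwise).
#' @export
estimate_homography <- function(world_pts, pixel_pts) {
  W <- rbind2mat(world_pts); Q <- rbind2mat(pixel_pts)
  if (nrow(W) < 4 || nrow(Q) < 4)
    stop("estimate_homography: at least 4 correspondences are required")
  if (nrow(W) != nrow(Q))
    stop("estimate_homography: point counts differ")
  if (any_three_collinear(W))
    stop("estimate_homography: degenerate configuration (3 collinear world points)")
  if (anyDuplicated(round(Q, 9)))
    stop("estimate_homography: degenerate configuration (coincident pixels)")
  nw <- hartley_normalize(W); nq <- hartley_normalize(Q)
  Wn <- nw$pts; Qn <- nq$pts
  n <- nrow(Wn)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- Wn[i, 1]; Y <- Wn[i, 2]; x <- Qn[i, 1]; y <- Qn[i, 2]
    A[2 * i - 1, ] <- c(-X, -Y, -1, 0, 0, 0, x * X, x * Y, x)
    A[2 * i, ]     <- c(0, 0, 0, -X, -Y, -1, y * X, y * Y, y)
  }
  # right-singular vector of the smallest singular value (null space of A)
  h <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9]
  H <- solve(nq$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% nw$T
  normalize_homography(H)
}

normalize_homography <- function(H) {
  if (abs(H[3, 3]) > 1e-12 * max(abs(H))) H / H[3, 3] else H / vec_norm(as.numeric(H))
}

hartley_normalize <- function(P) {
  ctr <- colMeans(P)
  d <- sqrt(rowSums(sweep(P, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  T <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
  list(pts = cbind(s * (P[, 1] - ctr[1]), s * (P[, 2] - ctr[2])), T = T)
}

any_three_collinear <- function(P, tol = 1e-9) {
  n <- nrow(P)
  if (n < 3) return(FALSE)
  scale <- max(apply(P, 2, function(x) diff(range(x))), 1e-12)
  idx <- utils::combn(n, 3)
  for (j in seq_len(ncol(idx))) {
    a <- P[idx[1, j], ]; b <- P[idx[2, j], ]; c <- P[idx[3, j], ]
    area2 <- abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    if (area2 < tol * scale^2) return(TRUE)
  }
  FALSE
}

#' Self-calibrate the focal length from a metric-plane homography
#'
#' For a homography `H = K [r1 r2 t]` (up to scale) from a metric plane, the
#' rotation columns satisfy `r1 . r2 = 0` and `|r1| = |r2|`. With square
#' pixels, zero skew and known principal point these two constraints are
#' linear in `1/f^2`; they are combined by least squares. An exactly
#' fronto-parallel view makes both constraints degenerate, in which case the
#' focal length cannot be recovered and the caller should supply one (e.g.
#' from camera metadata).
#'
#' @param H 3x3 homography from plane (metres) to pixels.
#' @param c_x,c_y principal point in pixels.
#' @return focal length in pixels.
#' @export
estimate_focal_from_homography <- function(H, c_x, c_y) {
  a <- H[1, 1:2] - c_x * H[3, 1:2]
  b <- H[2, 1:2] - c_y * H[3, 1:2]
  cc <- H[3, 1:2]
  # constraint i: p_i + q_i * f^2 = 0
  p1 <- a[1] * a[2] + b[1] * b[2];           q1 <- cc[1] * cc[2]
  p2 <- a[1]^2 + b[1]^2 - a[2]^2 - b[2]^2;   q2 <- cc[1]^2 - cc[2]^2
  scale <- max(abs(c(p1, p2)), 1e-12)
  if (q1^2 + q2^2 < 1e-18 * scale^2)
    stop("estimate_focal_from_homography: fronto-parallel (degenerate) view; supply the focal length")
  f2 <- -(p1 * q1 + p2 * q2) / (q1^2 + q2^2)
  if (!is.finite(f2) || f2 <= 0)
    stop("estimate_focal_from_homography: constraints give non-positive f^2; supply the focal length")
  sqrt(f2)
}

#' Recover the plane pose from a homography
#'
#' Decomposes `H = K [r1 r2 t]`: the columns of `K^-1 H` are rescaled so the
#' mean of `|r1|` and `|r2|` is one, `r3 = r1 x r2`, and the rotation is
#' re-orthonormalized by projection onto the nearest orthogonal matrix (SVD).
#' The sign of the scale is chosen so the plane lies in front of the camera
#' (positive `t_z`).
#'
#' @param H 3x3 homography from a metric plane to pixels.
#' @param intr [camera_intrinsics()].
#' @return A [plane_pose()].
#' @export
pose_from_homography <- function(H, intr) {
  K <- intrinsics_matrix(intr)
  if (abs(det(H)) < 1e-15 * max(abs(H))^3)
    stop("pose_from_homography: homography is not invertible")
  M <- solve(K, H)
  lambda <- 2 / (vec_norm(M[, 1]) + vec_norm(M[, 2]))
  if ((lambda * M[3, 3]) < 0) lambda <- -lambda
  r1 <- lambda * M[, 1]; r2 <- lambda * M[, 2]
  R0 <- cbind(r1, r2, cross3(r1, r2))
  sv <- svd(R0)
  R <- sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  plane_pose(R, lambda * M[, 3])
}

#' Map image pixels back to the metric plane
#'
#' Applies the inverse homography with homogeneous normalization, recovering
#' plane coordinates `(X, Y)` in true magnitude (metres).
#'
#' @param q length-2 vector or n x 2 matrix of pixel coordinates.
#' @param H 3x3 plane-to-image homography.
#' @return n x 2 matrix of plane coordinates (columns `X`, `Y`).
#' @export
map_pixel_to_plane <- function(q, H) {
  q <- rbind2mat(q)
  Hi <- solve(H)
  v <- cbind(q, 1) %*% t(Hi)
  if (any(abs(v[, 3]) < 1e-12 * apply(abs(v), 1, max)))
    stop("map_pixel_to_plane: pixel maps to the plane at infinity")
  cbind(X = v[, 1] / v[, 3], Y = v[, 2] / v[, 3])
}
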