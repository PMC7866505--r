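# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit matrix products, brute-force set
# morphology, and aov()-based mean squares.

# explicit K [R | t] homogeneous projection
oracle_project <- function(p, K, R, t) {
  ph <- K %*% (R %*% p + t)
  c(ph[1] / ph[3], ph[2] / ph[3])
}

# brute-force morphological opening: union of all translates of the
# structuring element that fit entirely inside the mask (origin-free
# definition, independent of any kernel-centre convention)
oracle_opening <- function(mask, se) {
  nr <- nrow(mask); nc <- ncol(mask)
  off <- which(se == 1, arr.ind = TRUE)
  out <- matrix(FALSE, nr, nc)
  for (r in 1:(nr - nrow(se) + 1)) {
    for (c in 1:(nc - ncol(se) + 1)) {
      pos <- cbind(off[, 1] + r - 1L, off[, 2] + c - 1L)
      if (all(mask[pos])) out[pos] <- TRUE
    }
  }
  out
}

# the odd-length rule of the package's linear structuring elements
oracle_se_len <- function(L) {
  L <- max(1L, as.integer(round(L)))
  if (L %% 2L == 0L) L + 1L else L
}

oracle_se <- function(L, orientation) {
  L <- oracle_se_len(L)
  switch(orientation,
         vertical = matrix(1, L, 1),
         horizontal = matrix(1, 1, L),
         diag135 = { k <- matrix(0, L, L); k[cbind(1:L, L:1)] <- 1; k })
}

oracle_tophat_bandpass <- function(mask, orientation, s) {
  mask <- mask != 0
  th <- function(L) mask & !oracle_opening(mask, oracle_se(L, orientation))
  th(2 * s) & !th(s / 2)
}

# ICC(2,1) from aov()-style mean squares via anova(lm())
oracle_icc21 <- function(a, b) {
  n <- length(a)
  d <- data.frame(y = c(a, b),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  an <- anova(lm(y ~ subj + rater, data = d))
  MSR <- an["subj", "Mean Sq"]; MSC <- an["rater", "Mean Sq"]
  MSE <- an["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + MSE + 2 * (MSC - MSE) / n)
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                            3, 3, byrow = TRUE)

# random valid camera pose looking roughly down +Z
random_pose <- function() {
  ang <- runif(3, -0.3, 0.3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  plane_pose(Rx %*% Ry %*% Rz, c(runif(2, -0.2, 0.2), runif(1, 1.5, 3)))
}

# homography synthesized from known intrinsics and pose (plane Z = 0)
make_homography <- function(f, cx, cy, pose) {
  K <- matrix(c(f, 0, cx, 0, f, cy, 0, 0, 1), 3, 3, byrow = TRUE)
  H <- K %*% cbind(pose$rotation[, 1:2], pose$translation)
  H / H[3, 3]
}
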