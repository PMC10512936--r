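#' Marker trajectory container
#'
#' A labelled time series of 3-D landmark positions in the lab frame.
#' Positions are in meters; the lab convention used throughout the package is
#' x to the subject's right, y anterior (direction of progression), z up.
#'
#' @param positions numeric T x 3 matrix of positions (m).
#' @param rate sampling rate in Hz.
#' @param label marker label (e.g. `"heel_L"`).
#' @return An object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(positions, rate, label = "") {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be a T x 3 matrix")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("rate must be a positive scalar (Hz)")
  }
  structure(list(positions = positions, rate = rate, label = label),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory '%s': %d samples @ %g Hz>\n",
              x$label, nrow(x$positions), x$rate))
  invisible(x)
}

as_positions <- function(x) {
  if (inherits(x, "marker_trajectory")) x$positions else as.matrix(x)
}

#' Segment coordinate-frame series
#'
#' Per-sample origin and orthonormal right-handed axes of a body segment.
#' `axes` is a T x 3 x 3 array: `axes[s, , k]` is the k-th axis (x, y, z,
#' i.e. right/left, anterior/posterior, superior/inferior) at sample `s`,
#' expressed in the lab frame.
#'
#' @param origin T x 3 matrix of origins (m).
#' @param axes T x 3 x 3 array of unit axes (columns x, y, z per sample).
#' @param validate check orthonormality and handedness (tolerance 1e-9).
#' @return An object of class `segment_frame`.
#' @export
segment_frame <- function(origin, axes, validate = TRUE) {
  origin <- as.matrix(origin)
  if (length(dim(axes)) != 3 || any(dim(axes)[2:3] != c(3, 3))) {
    stop("axes must be a T x 3 x 3 array")
  }
  if (nrow(origin) != dim(axes)[1]) stop("origin and axes sample counts differ")
  if (validate) {
    chk <- frame_orthonormality_error(axes)
    if (chk$ortho > 1e-9) {
      stop(sprintf("axes not orthonormal (max deviation %.3g)", chk$ortho))
    }
    if (any(chk$det < 0)) stop("axes are left-handed (determinant < 0)")
  }
  structure(list(origin = origin, axes = axes), class = "segment_frame")
}

#' @export
print.segment_frame <- function(x, ...) {
  cat(sprintf("<segment_frame: %d samples>\n", nrow(x$origin)))
  invisible(x)
}

n_samples <- function(frame) dim(frame$axes)[1]

# Max deviation of axes' Gram matrix from identity, and per-sample determinant.
frame_orthonormality_error <- function(axes) {
  x <- axes[, , 1, drop = FALSE][, , 1]
  y <- axes[, , 2, drop = FALSE][, , 1]
  z <- axes[, , 3, drop = FALSE][, , 1]
  if (is.null(dim(x))) { x <- rbind(x); y <- rbind(y); z <- rbind(z) }
  g <- cbind(rowSums(x * x) - 1, rowSums(y * y) - 1, rowSums(z * z) - 1,
             rowSums(x * y), rowSums(x * z), rowSums(y * z))
  det3 <- rowSums(x * cross_rows(y, z))
  list(ortho = max(abs(g)), det = det3)
}

axes_array <- function(x, y, z) {
  a <- array(0, dim = c(nrow(x), 3, 3))
  a[, , 1] <- x; a[, , 2] <- y; a[, , 3] <- z
  a
}

#' Build the foot local coordinate system from five landmarks
#'
#' Constructs the foot segment frame from the heel, first and fifth
#' metatarsal-head, and medial/lateral malleolus markers:
#' origin = midpoint of the heel and the metatarsal-head midpoint;
#' y (anterior) = unit vector from the heel to the metatarsal-head midpoint;
#' z (superior) = unit cross product of (MT1 - heel) with y for the left
#' foot (order flipped for the right foot so z stays superior);
#' x = y x z, giving a right-handed frame with x along right/left.
#'
#' @param heel,mt1,mt5,mml,lml [marker_trajectory] (or T x 3 matrices) for the
#'   heel, first/fifth metatarsal heads, and medial/lateral malleoli.
#' @param side `"left"` or `"right"`.
#' @return A [segment_frame].
#' @export
build_foot_frame <- function(heel, mt1, mt5, mml, lml, side = c("left", "right")) {
  side <- match.arg(side)
  p_heel <- as_positions(heel); p_mt1 <- as_positions(mt1)
  p_mt5 <- as_positions(mt5)
  p_mml <- as_positions(mml); p_lml <- as_positions(lml)
  ns <- vapply(list(p_heel, p_mt1, p_mt5, p_mml, p_lml), nrow, 0L)
  if (length(unique(ns)) != 1) stop("all five markers must share sample count")
  mid_mt <- (p_mt1 + p_mt5) / 2
  origin <- (p_heel + mid_mt) / 2
  y <- unit_rows(mid_mt - p_heel, "foot anterior axis")
  v <- p_mt1 - p_heel
  zr <- if (side == "left") cross_rows(v, y) else cross_rows(y, v)
  z <- unit_rows(zr, "foot superior axis (collinear heel/MT1/MT5?)")
  x <- cross_rows(y, z)
  segment_frame(origin, axes_array(x, y, z), validate = FALSE)
}

#' Build a proximal segment frame
#'
#' Minimal documented construction of a pelvis/thigh/shank frame from three
#' landmark trajectories: `origin` anchors the frame, the long axis to
#' `long_end` defines z (superior), and `plane_point` fixes the x axis as the
#' component of (plane_point - origin) orthogonal to z; y = z x x completes a
#' right-handed frame. If a [segment_frame] is supplied (e.g. orientations
#' carried by the synthetic generator) it is passed through unchanged.
#'
#' @param origin landmark at the frame origin, or a [segment_frame].
#' @param long_end landmark defining the segment long axis (z points from
#'   `origin` towards it).
#' @param plane_point landmark fixing the frontal plane (x axis side).
#' @return A [segment_frame].
#' @export
build_proximal_frame <- function(origin, long_end = NULL, plane_point = NULL) {
  if (inherits(origin, "segment_frame")) return(origin)
  o <- as_positions(origin)
  a <- as_positions(long_end)
  p <- as_positions(plane_point)
  z <- unit_rows(a - o, "segment long axis")
  w <- p - o
  x0 <- w - z * rowSums(w * z)
  x <- unit_rows(x0, "segment frontal axis (collinear landmarks?)")
  y <- cross_rows(z, x)
  segment_frame(o, axes_array(x, y, z), validate = FALSE)
}

#' Cardan x-y-z angle extraction
#'
#' Decomposes a proper rotation as R = Rx(alpha) Ry(beta) Rz(gamma); alpha is
#' the sagittal-plane angle, with beta constrained to \[-90, 90\] degrees.
#' Near gimbal lock (|R\[1,3\]| within 1e-8 of 1) gamma is set to 0 and alpha
#' absorbs the free rotation; such samples are flagged in the `"gimbal"`
#' attribute.
#'
#' @param R a 3 x 3 rotation matrix or a T x 3 x 3 array of them.
#' @return Angles in degrees: a length-3 vector `(alpha, beta, gamma)` for a
#'   single matrix, or a T x 3 matrix, with a logical `"gimbal"` attribute.
#' @export
cardan_xyz <- function(R) {
  single <- length(dim(R)) == 2
  if (single) R <- array(R, dim = c(1, 3, 3), dimnames = NULL)
  r11 <- R[, 1, 1]; r12 <- R[, 1, 2]; r13 <- R[, 1, 3]
  r21 <- R[, 2, 1]; r22 <- R[, 2, 2]
  r23 <- R[, 2, 3]; r33 <- R[, 3, 3]
  s <- pmin(pmax(r13, -1), 1)
  beta <- asin(s)
  gimbal <- abs(r13) >= 1 - 1e-8
  alpha <- atan2(-r23, r33)
  gamma <- atan2(-r12, r11)
  if (any(gimbal)) {
    # beta = +/-90 deg: only alpha -/+ gamma is determined; put it all in alpha
    alpha[gimbal] <- atan2(r21[gimbal], r22[gimbal])
    gamma[gimbal] <- 0
  }
  out <- cbind(alpha, beta, gamma) * 180 / pi
  colnames(out) <- c("alpha", "beta", "gamma")
  if (single) {
    out <- out[1, ]
    attr(out, "gimbal") <- gimbal[1]
  } else {
    attr(out, "gimbal") <- gimbal
  }
  out
}

# Relative rotation series t(prox) %*% dist, vectorized over samples.
relative_rotation <- function(prox_axes, dist_axes) {
  t_ <- dim(prox_axes)[1]
  R <- array(0, dim = c(t_, 3, 3))
  for (i in 1:3) {
    for (j in 1:3) {
      R[, i, j] <- rowSums(prox_axes[, , i] * dist_axes[, , j])
    }
  }
  R
}

#' Sagittal joint angles from segment frames
#'
#' For each joint the relative rotation is R = t(axes_proximal) %*%
#' axes_distal per sample; the sagittal component is the Cardan x-y-z alpha.
#' Signs are mapped so that hip flexion, knee flexion, and ankle dorsiflexion
#' are positive (the knee alpha is negated: knee flexion rotates the shank
#' backwards relative to the thigh).
#'
#' @param pelvis,thigh,shank,foot [segment_frame] series sharing sample count.
#' @return T x 3 matrix with columns `hip`, `knee`, `ankle` (degrees).
#' @export
joint_angles <- function(pelvis, thigh, shank, foot) {
  ts <- c(n_samples(pelvis), n_samples(thigh), n_samples(shank), n_samples(foot))
  if (length(unique(ts)) != 1) stop("segment frames must share sample count")
  hip <- cardan_xyz(relative_rotation(pelvis$axes, thigh$axes))[, 1]
  knee <- -cardan_xyz(relative_rotation(thigh$axes, shank$axes))[, 1]
  ankle <- cardan_xyz(relative_rotation(shank$axes, foot$axes))[, 1]
  out <- cbind(hip = hip, knee = knee, ankle = ankle)
  out
}

#' Virtual foot marker
#'
#' The mid-foot point: midpoint of the metatarsal-head midpoint (MT1/MT5) and
#' the malleoli midpoint (MML/LML), i.e. the pointwise average of the four
#' landmarks. Its acceleration norm is the "foot acceleration" feature.
#'
#' @param mt1,mt5,mml,lml [marker_trajectory] (or T x 3 matrices).
#' @param rate sampling rate (Hz), taken from `mt1` if it is a trajectory.
#' @return A [marker_trajectory] labelled `"virtual_foot"`.
#' @export
virtual_foot_marker <- function(mt1, mt5, mml, lml, rate = NULL) {
  if (is.null(rate)) {
    if (!inherits(mt1, "marker_trajectory")) stop("rate required for matrix input")
    rate <- mt1$rate
  }
  p <- (as_positions(mt1) + as_positions(mt5) +
          as_positions(mml) + as_positions(lml)) / 4
  marker_trajectory(p, rate, "virtual_foot")
}

#' Linear acceleration by central differences
#'
#' a_i = (p_(i+1) - 2 p_i + p_(i-1)) * rate^2 at interior samples; the first
#' and last samples carry `NA` and are excluded from any extracted cycle.
#'
#' @param traj a [marker_trajectory] (or T x 3 matrix with `rate` given).
#' @param rate sampling rate in Hz (if `traj` is a plain matrix).
#' @return T x 3 matrix of accelerations (m/s^2) with `NA` endpoints.
#' @export
linear_acceleration <- function(traj, rate = NULL) {
  p <- as_positions(traj)
  if (is.null(rate)) rate <- traj$rate
  t_ <- nrow(p)
  if (t_ < 3) stop("need at least 3 samples for central differences")
  a <- matrix(NA_real_, t_, 3)
  i <- 2:(t_ - 1)
  a[i, ] <- (p[i + 1, ] - 2 * p[i, ] + p[i - 1, ]) * rate^2
  a
}

# Vectorized rotation-matrix -> unit quaternion (w, x, y, z), Shepperd's
# case selection for numerical robustness.
rotmat_to_quat <- function(axes) {
  r11 <- axes[, 1, 1]; r12 <- axes[, 1, 2]; r13 <- axes[, 1, 3]
  r21 <- axes[, 2, 1]; r22 <- axes[, 2, 2]; r23 <- axes[, 2, 3]
  r31 <- axes[, 3, 1]; r32 <- axes[, 3, 2]; r33 <- axes[, 3, 3]
  t0 <- 1 + r11 + r22 + r33
  t1 <- 1 + r11 - r22 - r33
  t2 <- 1 - r11 + r22 - r33
  t3 <- 1 - r11 - r22 + r33
  tm <- pmax(t0, t1, t2, t3)
  q <- matrix(0, length(t0), 4)
  i0 <- tm == t0
  if (any(i0)) {
    s <- 2 * sqrt(t0[i0])
    q[i0, ] <- cbind(s / 4, (r32[i0] - r23[i0]) / s,
                     (r13[i0] - r31[i0]) / s, (r21[i0] - r12[i0]) / s)
  }
  i1 <- tm == t1 & !i0
  if (any(i1)) {
    s <- 2 * sqrt(t1[i1])
    q[i1, ] <- cbind((r32[i1] - r23[i1]) / s, s / 4,
                     (r12[i1] + r21[i1]) / s, (r13[i1] + r31[i1]) / s)
  }
  i2 <- tm == t2 & !i0 & !i1
  if (any(i2)) {
    s <- 2 * sqrt(t2[i2])
    q[i2, ] <- cbind((r13[i2] - r31[i2]) / s, (r12[i2] + r21[i2]) / s,
                     s / 4, (r23[i2] + r32[i2]) / s)
  }
  i3 <- tm == t3 & !i0 & !i1 & !i2
  if (any(i3)) {
    s <- 2 * sqrt(t3[i3])
    q[i3, ] <- cbind((r21[i3] - r12[i3]) / s, (r13[i3] + r31[i3]) / s,
                     (r23[i3] + r32[i3]) / s, s / 4)
  }
  q / sqrt(rowSums(q^2))
}

#' Unit quaternion series of a segment frame
#'
#' Converts each sample's rotation matrix (the frame axes, an axis-angle /
#' Rodrigues representation of the segment attitude) to a unit quaternion
#' (w, x, y, z), with the sign of each quaternion chosen so that the dot
#' product with its predecessor is non-negative (sign continuity, required
#' for finite differencing).
#'
#' @param frame a [segment_frame].
#' @return T x 4 matrix of unit quaternions, columns `w, x, y, z`.
#' @export
frame_quaternions <- function(frame) {
  q <- rotmat_to_quat(frame$axes)
  t_ <- nrow(q)
  if (t_ > 1) {
    d <- rowSums(q[-1, , drop = FALSE] * q[-t_, , drop = FALSE])
    flip <- cumprod(ifelse(d < 0, -1, 1))
    q[-1, ] <- q[-1, , drop = FALSE] * flip
  }
  colnames(q) <- c("w", "x", "y", "z")
  q
}

# Hamilton product of row-wise quaternions a x b.
quat_multiply <- function(a, b) {
  cbind(
    a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

#' Angular velocity from a quaternion series
#'
#' omega_i = 2 vec(dq_i x conj(q_i)) with dq by central differences at the
#' given rate; endpoints carry `NA`. Only the norm of omega is consumed
#' downstream, which is identical between body- and lab-frame expressions.
#'
#' @param q T x 4 matrix of sign-continuous unit quaternions (w, x, y, z).
#' @param rate sampling rate in Hz.
#' @return T x 3 matrix of angular velocity (rad/s) with `NA` endpoints.
#' @export
angular_velocity <- function(q, rate) {
  q <- as.matrix(q)
  t_ <- nrow(q)
  if (t_ < 3) stop("need at least 3 samples for central differences")
  i <- 2:(t_ - 1)
  dq <- (q[i + 1, , drop = FALSE] - q[i - 1, , drop = FALSE]) * rate / 2
  conj_q <- q[i, , drop = FALSE] * matrix(c(1, -1, -1, -1), length(i), 4, byrow = TRUE)
  w <- 2 * quat_multiply(dq, conj_q)[, 2:4, drop = FALSE]
  out <- matrix(NA_real_, t_, 3)
  out[i, ] <- w
  out
}

#' Per-sample Euclidean norm
#'
#' The norm of a three-axis series is invariant under any fixed rotation of
#' the sensor or lab frame, which is what makes norm features robust to
#' sensor tilt.
#'
#' @param v T x 3 matrix (acceleration in m/s^2 or angular velocity in rad/s).
#' @return Numeric vector of length T (`NA` rows propagate).
#' @export
norm_series <- function(v) {
  v <- as.matrix(v)
  sqrt(rowSums(v^2))
}
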