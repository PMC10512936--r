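test_that("foot frame matches the printed construction on a static layout", {
  m <- static_foot_markers()
  fr <- build_foot_frame(m$heel, m$mt1, m$mt5, m$mml, m$lml, "left")
  expect_equal(fr$origin[1, ], c(0, 0.1, 0), tolerance = 1e-12)
  expect_equal(fr$axes[1, , 2], c(0, 1, 0), tolerance = 1e-12)  # y anterior
  expect_equal(fr$axes[1, , 3], c(0, 0, 1), tolerance = 1e-12)  # z up
  expect_equal(fr$axes[1, , 1], c(1, 0, 0), tolerance = 1e-12)  # x = y x z
})

test_that("foot frames are orthonormal, right-handed, and rotation-equivariant", {
  set.seed(21)
  trial <- small_trials()[[1]]
  m <- trial$markers$left
  fr <- build_foot_frame(m$heel, m$mt1, m$mt5, m$mml, m$lml, "left")
  chk <- gaitnorms:::frame_orthonormality_error(fr$axes)
  expect_lt(chk$ortho, 1e-9)
  expect_true(all(chk$det > 0))
  # right side as well
  mr <- trial$markers$right
  frr <- build_foot_frame(mr$heel, mr$mt1, mr$mt5, mr$mml, mr$lml, "right")
  expect_true(all(gaitnorms:::frame_orthonormality_error(frr$axes)$det > 0))
  # equivariance: rotating the five markers by Q rotates the axes by Q
  Q <- random_rotation()
  rot <- lapply(m, function(x) marker_trajectory(x$positions %*% t(Q), x$rate))
  fr2 <- build_foot_frame(rot$heel, rot$mt1, rot$mt5, rot$mml, rot$lml, "left")
  for (k in 1:3) {
    expect_equal(fr2$axes[, , k], fr$axes[, , k] %*% t(Q), tolerance = 1e-9)
  }
})

test_that("collinear foot landmarks raise a degenerate-geometry error", {
  t_ <- 3
  mk <- function(p) marker_trajectory(matrix(rep(p, each = t_), t_, 3), 200)
  expect_error(
    build_foot_frame(mk(c(0, 0, 0)), mk(c(0, 0.1, 0)), mk(c(0, 0.3, 0)),
                     mk(c(0, 0.05, 0)), mk(c(0, 0.06, 0)), "left"),
    "sample 1"
  )
})

test_that("proximal frame construction aligns z with the long axis", {
  t_ <- 5
  mk <- function(p) marker_trajectory(matrix(rep(p, each = t_), t_, 3), 200)
  fr <- build_proximal_frame(mk(c(0, 0, 0)), mk(c(0, 0, 0.4)), mk(c(0.1, 0, 0.2)))
  expect_equal(fr$axes[1, , 3], c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$axes[1, , 1], c(1, 0, 0), tolerance = 1e-12)
  chk <- gaitnorms:::frame_orthonormality_error(fr$axes)
  expect_lt(chk$ortho, 1e-9)
  expect_true(all(chk$det > 0))
  # generator-emitted frames pass through unchanged
  expect_identical(build_proximal_frame(fr), fr)
})

test_that("Cardan x-y-z decomposition inverts composition away from gimbal lock", {
  expect_equal(unname(cardan_xyz(diag(3))[1:3]), c(0, 0, 0))
  r30 <- gaitnorms:::rot_x(pi / 6)
  expect_equal(unname(cardan_xyz(r30)[1:3]), c(30, 0, 0), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    ang <- c(stats::runif(1, -180, 180), stats::runif(1, -85, 85),
             stats::runif(1, -180, 180))
    R <- gaitnorms:::rot_x(ang[1] * pi / 180) %*%
      gaitnorms:::rot_y(ang[2] * pi / 180) %*%
      gaitnorms:::rot_z(ang[3] * pi / 180)
    expect_equal(unname(cardan_xyz(R)[1:3]), ang, tolerance = 1e-9)
  }
})

test_that("gimbal-proximate rotations are flagged with gamma zeroed", {
  R <- gaitnorms:::rot_x(0.3) %*% gaitnorms:::rot_y(pi / 2) %*%
    gaitnorms:::rot_z(0.2)
  out <- cardan_xyz(R)
  expect_true(attr(out, "gimbal"))
  expect_equal(unname(out[3]), 0)
  # the recovered alpha absorbs the free rotation: recomposition matches R
  R2 <- gaitnorms:::rot_x(out[1] * pi / 180) %*%
    gaitnorms:::rot_y(out[2] * pi / 180)
  expect_equal(R2, R, tolerance = 1e-6)
})

test_that("joint angles are zero for coincident frames and signed per convention", {
  t_ <- 4
  id_axes <- gaitnorms:::rx_axes(rep(0, t_))
  org <- matrix(0, t_, 3)
  f0 <- segment_frame(org, id_axes)
  ang <- joint_angles(f0, f0, f0, f0)
  expect_equal(max(abs(ang)), 0)
  # distal pre-rotated by Rx(10 deg): hip/ankle read +10, knee reads -(-10)
  f10 <- segment_frame(org, gaitnorms:::rx_axes(rep(10 * pi / 180, t_)))
  ang <- joint_angles(f0, f10, f0, f0)
  expect_equal(unname(ang[1, "hip"]), 10, tolerance = 1e-10)
  expect_equal(unname(ang[1, "knee"]), 10, tolerance = 1e-10)  # shank behind thigh
  ang2 <- joint_angles(f0, f0, f0, f10)
  expect_equal(unname(ang2[1, "ankle"]), 10, tolerance = 1e-10)
})

test_that("virtual foot marker is the midpoint of midpoints", {
  t_ <- 3
  mk <- function(p) marker_trajectory(matrix(rep(p, each = t_), t_, 3), 200)
  vm <- virtual_foot_marker(mk(c(0.1, 0, 0)), mk(c(-0.1, 0, 0)),
                            mk(c(0, 0.1, 0)), mk(c(0, -0.1, 0)))
  expect_equal(max(abs(vm$positions)), 0)
  p <- c(0.3, -0.2, 0.9)
  vm2 <- virtual_foot_marker(mk(p), mk(p), mk(p), mk(p))
  expect_equal(vm2$positions[2, ], p)
  # affinity: translating all inputs translates the output
  v <- c(1, 2, 3)
  vm3 <- virtual_foot_marker(mk(c(0.1, 0, 0) + v), mk(c(-0.1, 0, 0) + v),
                             mk(c(0, 0.1, 0) + v), mk(c(0, -0.1, 0) + v))
  expect_equal(vm3$positions[1, ], v)
})

test_that("central differences are exact on quadratics and O(rate^-2) on sinusoids", {
  rate <- 200
  t <- seq(0, 1, by = 1 / rate)
  g <- c(0.3, -9.81, 1.2)
  p <- outer(t^2 / 2, g)
  a <- linear_acceleration(marker_trajectory(p, rate))
  expect_true(all(is.na(a[1, ])) && all(is.na(a[nrow(a), ])))
  i <- 2:(length(t) - 1)
  expect_equal(a[i, ], matrix(g, length(i), 3, byrow = TRUE), tolerance = 1e-9)
  # constant position -> zero acceleration
  a0 <- linear_acceleration(marker_trajectory(matrix(1, 50, 3), rate))
  expect_equal(max(abs(a0[2:49, ])), 0)
  # sinusoid: a = -w^2 p with relative error O(rate^-2)
  w <- 2 * pi * 5
  ps <- cbind(sin(w * t), 0, 0)
  as <- linear_acceleration(marker_trajectory(ps, rate))
  rel <- max(abs(as[i, 1] + w^2 * ps[i, 1])) / w^2
  expect_lt(rel, (w / rate)^2)
  expect_error(linear_acceleration(marker_trajectory(matrix(0, 2, 3), rate)),
               "3 samples")
})

test_that("frame quaternions represent the axes and stay sign-continuous", {
  t_ <- 3
  idf <- segment_frame(matrix(0, t_, 3), gaitnorms:::rx_axes(rep(0, t_)))
  q <- frame_quaternions(idf)
  expect_equal(q[1, ], c(w = 1, x = 0, y = 0, z = 0))
  # Rz(90 deg) -> (sqrt(2)/2, 0, 0, sqrt(2)/2)
  a <- array(0, c(1, 3, 3)); a[1, , ] <- gaitnorms:::rot_z(pi / 2)
  qz <- frame_quaternions(segment_frame(matrix(0, 1, 3), a))
  expect_equal(unname(qz[1, ]), c(sqrt(2) / 2, 0, 0, sqrt(2) / 2), tolerance = 1e-12)
  # round trip on a walking foot frame + sign continuity
  trial <- small_trials()[[1]]
  m <- trial$markers$left
  fr <- build_foot_frame(m$heel, m$mt1, m$mt5, m$mml, m$lml, "left")
  qs <- frame_quaternions(fr)
  back <- gaitnorms:::quat_to_axes(qs)
  expect_equal(back, fr$axes, tolerance = 1e-9)
  dots <- rowSums(qs[-1, ] * qs[-nrow(qs), ])
  expect_true(all(dots >= 0))
})

test_that("angular velocity recovers constant-rate rotations and is frame-invariant", {
  rate <- 200
  t <- seq(0, 1, by = 1 / rate)
  omega <- 3.2  # rad/s about z
  axes <- array(0, c(length(t), 3, 3))
  for (i in seq_along(t)) axes[i, , ] <- gaitnorms:::rot_z(omega * t[i])
  fr <- segment_frame(matrix(0, length(t), 3), axes)
  q <- frame_quaternions(fr)
  w <- angular_velocity(q, rate)
  i <- 2:(length(t) - 1)
  expect_true(all(is.na(w[1, ])))
  expect_equal(norm_series(w)[i], rep(omega, length(i)),
               tolerance = (omega / rate)^2)
  # constant attitude -> zero angular velocity
  q0 <- matrix(rep(c(1, 0, 0, 0), each = 10), 10, 4)
  expect_equal(max(abs(angular_velocity(q0, rate)[2:9, ])), 0)
  # premultiplying every frame by one fixed rotation leaves the norm unchanged
  Q <- random_rotation()
  axes2 <- axes
  for (k in 1:3) axes2[, , k] <- axes[, , k] %*% t(Q)
  w2 <- angular_velocity(frame_quaternions(
    segment_frame(matrix(0, length(t), 3), axes2)), rate)
  expect_equal(norm_series(w2)[i], norm_series(w)[i], tolerance = 1e-9)
})

test_that("per-sample norms behave as Euclidean norms", {
  expect_equal(norm_series(matrix(c(3, 4, 0), 1, 3)), 5)
  expect_equal(norm_series(matrix(0, 2, 3)), c(0, 0))
  set.seed(3)
  v <- matrix(stats::rnorm(30), 10, 3)
  Q <- random_rotation()
  expect_equal(norm_series(v %*% t(Q)), norm_series(v), tolerance = 1e-12)
})
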