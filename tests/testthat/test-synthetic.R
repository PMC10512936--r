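test_that("configuration invariants are enforced", {
  expect_error(gait_config(n_subjects = 4), "n_subjects")
  expect_error(gait_config(grf_rate = 900), "integer multiple")
  expect_error(gait_config(cycle_fraction_stance = 1.2), "stance")
  expect_s3_class(gait_config(n_subjects = 5), "gait_config")
})

test_that("profiles are deterministic and scale with the subject effect", {
  cfg <- small_config()
  p1 <- make_profiles(cfg)
  p2 <- make_profiles(cfg)
  expect_identical(p1, p2)
  expect_length(make_profiles(gait_config(n_subjects = 200)), 200)
  # zero subject effect collapses all between-subject variation
  cfg0 <- gait_config(n_subjects = 6, subject_effect_sd = 0)
  p0 <- make_profiles(cfg0)
  for (p in p0) {
    expect_equal(unname(p$amplitude_scales), c(1, 1, 1))
    expect_equal(unname(p$offset_shifts), c(0, 0, 0))
    expect_equal(p$cadence, p0[[1]]$cadence)
  }
})

test_that("angle templates are periodic, knee-flexion dominated, with analytic means", {
  prof <- make_profiles(small_config())[[1]]
  expect_equal(joint_angle_templates(prof, 0), joint_angle_templates(prof, 1))
  phase <- seq(0, 1, length.out = 2001)[-2001]
  tpl <- joint_angle_templates(prof, phase)
  expect_true(min(tpl[, "knee"]) > -5)        # flexion-dominated
  expect_gt(max(tpl[, "knee"]), 40)           # swing flexion peak present
  # cycle mean equals offset + amplitude * constant Fourier term
  tpls <- gaitnorms:::.gait_templates
  for (j in c("hip", "knee", "ankle")) {
    expect_equal(mean(tpl[, j]),
                 prof$offset_shifts[[j]] + prof$amplitude_scales[[j]] * tpls[[j]]$a0,
                 tolerance = 1e-10)
  }
  # degenerate amplitude: output is the constant offset
  prof0 <- prof
  prof0$amplitude_scales <- c(hip = 0, knee = 0, ankle = 0)
  t0 <- joint_angle_templates(prof0, phase)
  for (j in c("hip", "knee", "ankle")) {
    expect_equal(unname(t0[, j]), rep(prof0$offset_shifts[[j]], length(phase)))
  }
})

test_that("forward kinematics transports rigid feet and scales with stride length", {
  prof <- make_profiles(small_config())[[2]]
  t_grid <- seq(0, 2, by = 1 / 200)
  ang <- joint_angle_templates(prof, t_grid * prof$cadence)
  fk <- forward_kinematics(prof, ang, t_grid, "left")
  # rigid-body consistency: pairwise marker distances constant to 1e-9 m
  nm <- names(fk$markers)
  for (i in 1:4) for (j in (i + 1):5) {
    d <- norm_series(fk$markers[[nm[i]]]$positions - fk$markers[[nm[j]]]$positions)
    expect_lt(max(d) - min(d), 1e-9)
  }
  # frozen angles give a frozen foot attitude and constant distances
  angc <- matrix(rep(c(12, 25, -5), each = length(t_grid)), ncol = 3,
                 dimnames = list(NULL, c("hip", "knee", "ankle")))
  fkc <- forward_kinematics(prof, angc, t_grid, "right")
  fr <- build_foot_frame(fkc$markers$heel, fkc$markers$mt1, fkc$markers$mt5,
                         fkc$markers$mml, fkc$markers$lml, "right")
  for (k in 1:3) {
    expect_lt(max(abs(sweep(fr$axes[, , k], 2, fr$axes[1, , k]))), 1e-9)
  }
  # doubling stride length doubles pelvis displacement per unit time
  prof2 <- prof
  prof2$stride_length <- 2 * prof$stride_length
  fk2 <- forward_kinematics(prof2, ang, t_grid, "left")
  d1 <- fk$frames$pelvis$origin[length(t_grid), 2] - fk$frames$pelvis$origin[1, 2]
  d2 <- fk2$frames$pelvis$origin[length(t_grid), 2] - fk2$frames$pelvis$origin[1, 2]
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  expect_error(forward_kinematics(prof, ang * NA, t_grid, "left"), "non-finite")
})

test_that("angle extraction from generated markers recovers the stored truth", {
  trial <- small_trials()[[3]]
  side <- trial$side
  m <- trial$markers[[side]]
  fr <- build_foot_frame(m$heel, m$mt1, m$mt5, m$mml, m$lml, side)
  ang <- joint_angles(trial$frames$pelvis, trial$frames[[side]]$thigh,
                      trial$frames[[side]]$shank, fr)
  err <- ang - trial$truth_angles[[side]]
  expect_lt(sqrt(mean(err^2)), 0.5)
})

test_that("datasets have the scheduled structure and are byte-identical on regeneration", {
  cfg <- small_config()
  trials <- small_trials()
  expect_length(trials, cfg$n_subjects * cfg$n_trials_per_subject)
  expect_identical(synthesize_dataset(cfg), trials)
  tr <- trials[[1]]
  # GRF: nonnegative, exactly zero in swing, two-peaked in stance
  expect_true(all(tr$grf$left >= 0))
  expect_gt(mean(tr$grf$left == 0), 0.2)
  expect_gte(length(tr$schedule[[tr$side]]), 2)
  # truth and markers share the marker-rate sample count
  expect_equal(nrow(tr$truth_angles$left), length(tr$time))
  expect_equal(nrow(tr$markers$left$heel$positions), length(tr$time))
  # heel contacts found on the raw GRF sit on the scheduled onsets
  for (side in c("left", "right")) {
    ev <- detect_heel_contacts(tr$grf[[side]], tr$grf_rate)
    sched <- tr$schedule[[side]]
    expect_length(ev, length(sched))
    expect_lt(max(abs(ev - sched)) * tr$grf_rate, 1 + 1e-9)
  }
})

test_that("zero noise and zero subject effect make all trials' truth identical", {
  cfg <- gait_config(n_subjects = 5, n_trials_per_subject = 2,
                     noise_sd_angle = 0, subject_effect_sd = 0,
                     master_seed = 11)
  trials <- synthesize_dataset(cfg)
  lefts <- Filter(function(x) x$side == "left", trials)
  ref <- lefts[[1]]$truth_angles$left
  for (tr in lefts[-1]) expect_equal(tr$truth_angles$left, ref)
})

test_that("trial GRF template retains its two stance peaks", {
  u <- seq(0.01, 0.99, by = 0.01)
  f <- gaitnorms:::grf_stance_template(u)
  mid <- f[u > 0.45 & u < 0.55]
  early <- max(f[u < 0.4])
  late <- max(f[u > 0.6])
  expect_lt(max(mid), early)
  expect_lt(max(mid), late)
  expect_true(all(f > 0))
})
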