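# Synthetic gait generator: walking trials (markers, vertical GRF,
# ground-truth joint angles) with the structure of an instrumented-walkway
# motion-capture study, so the whole pipeline is testable with a known oracle.

# Normative sagittal joint-angle templates over one gait cycle (heel contact
# at phase 0), as truncated Fourier series: constant term plus 5 harmonics.
# Coefficients are fixed package constants obtained by projecting smooth
# periodic curves through textbook normative landmarks onto the Fourier basis.
.gait_templates <- list(
  hip = list(
    a0 = 12.7680,
    a = c(20.1187, -2.2467, -0.6742, -0.2421, 0.1971),
    b = c(-3.9977, -2.7145, 1.2512, 0.2207, 0.3792)
  ),
  knee = list(
    a0 = 21.5475,
    a = c(-2.3554, -14.0470, 0.9954, -0.7147, -0.1344),
    b = c(-19.1411, 7.9177, 3.4543, -0.7656, -0.3960)
  ),
  ankle = list(
    a0 = 0.4193,
    a = c(-0.5481, 0.0495, -2.8040, 2.2206, -0.4060),
    b = c(5.9468, -6.6046, 0.6428, -1.7443, -0.4584)
  )
)

eval_template <- function(tpl, phase) {
  out <- rep(tpl$a0, length(phase))
  for (k in seq_along(tpl$a)) {
    out <- out + tpl$a[k] * cos(2 * pi * k * phase) +
      tpl$b[k] * sin(2 * pi * k * phase)
  }
  out
}

#' Synthetic-dataset generator configuration
#'
#' @param n_subjects number of subjects (>= 5 so a five-group subject-level
#'   split is feasible). Default 200, the size of the emulated study.
#' @param n_trials_per_subject trials per subject; odd trial ids analyze the
#'   left limb and even ids the right, giving the conventional "five trials
#'   per leg" layout at the default of 10.
#' @param marker_rate marker sampling rate (Hz), default 200.
#' @param grf_rate ground-reaction-force sampling rate (Hz), default 1000;
#'   must be an integer multiple of `marker_rate`.
#' @param cycle_fraction_stance fraction of the gait cycle spent in stance
#'   (vertical GRF > 0), default 0.6.
#' @param noise_sd_angle SD (degrees) of the smooth additive per-trial angle
#'   noise (stride-to-stride variability); default 0.75.
#' @param subject_effect_sd unitless SD governing all between-subject
#'   variation (amplitude scales, angle offsets, cadence, stride, stature);
#'   0 makes every subject identical. Default 0.2, putting the
#'   between-subject waveform SD at several times the stride-to-stride SD, as
#'   in adult gait data.
#' @param master_seed integer seed from which all subject/trial streams are
#'   derived.
#' @return An object of class `gait_config`.
#' @export
gait_config <- function(n_subjects = 200, n_trials_per_subject = 10,
                        marker_rate = 200, grf_rate = 1000,
                        cycle_fraction_stance = 0.6,
                        noise_sd_angle = 0.75, subject_effect_sd = 0.2,
                        master_seed = 20190901L) {
  if (n_subjects < 5) stop("configuration error: n_subjects must be >= 5")
  if (n_trials_per_subject < 1) stop("configuration error: need >= 1 trial")
  if (marker_rate <= 0 || grf_rate <= 0) stop("configuration error: rates must be positive")
  if (grf_rate %% marker_rate != 0) {
    stop("configuration error: grf_rate must be an integer multiple of marker_rate")
  }
  if (cycle_fraction_stance <= 0 || cycle_fraction_stance >= 1) {
    stop("configuration error: cycle_fraction_stance must lie in (0,1)")
  }
  if (noise_sd_angle < 0 || subject_effect_sd < 0) {
    stop("configuration error: SDs must be non-negative")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_subject = as.integer(n_trials_per_subject),
    marker_rate = marker_rate, grf_rate = grf_rate,
    cycle_fraction_stance = cycle_fraction_stance,
    noise_sd_angle = noise_sd_angle, subject_effect_sd = subject_effect_sd,
    master_seed = as.integer(master_seed)
  ), class = "gait_config")
}

#' @export
print.gait_config <- function(x, ...) {
  cat(sprintf(paste0("<gait_config: %d subjects x %d trials, markers %g Hz, ",
                     "GRF %g Hz, stance %.0f%%, angle noise %.2g deg, ",
                     "subject effect %.2g>\n"),
              x$n_subjects, x$n_trials_per_subject, x$marker_rate, x$grf_rate,
              100 * x$cycle_fraction_stance, x$noise_sd_angle,
              x$subject_effect_sd))
  invisible(x)
}

#' Draw per-subject gait profiles
#'
#' Each profile is a pure function of `(master_seed, subject index)`, so
#' subjects are reproducible independently of generation order. All
#' between-subject variation scales with `subject_effect_sd`.
#'
#' @param config a [gait_config].
#' @return List of `subject_profile` objects (cadence in strides/s, stride
#'   length and segment lengths in m, unitless per-joint amplitude scales,
#'   per-joint offset shifts in degrees).
#' @export
make_profiles <- function(config) {
  stopifnot(inherits(config, "gait_config"))
  ses <- config$subject_effect_sd
  lapply(seq_len(config$n_subjects), function(i) {
    seed <- mix_seed(config$master_seed, i)
    z <- with_seed(seed, stats::rnorm(6))
    body <- exp(0.6 * ses * z[3])  # common stature scale
    amps <- stats::setNames(exp(ses * z[4:6]), c("hip", "knee", "ankle"))
    if (ses == 0) amps <- c(hip = 1, knee = 1, ankle = 1)
    # Mean-posture shifts are tied deterministically to the excursion scales
    # (larger excursions come with a proportionally shifted mean posture), so
    # every degree of freedom of the truth angles is expressed in the foot
    # kinematics; a constant offset drawn independently of the movement would
    # be invisible to any derivative-based (acceleration/angular-velocity)
    # feature.
    offsets <- c(hip = 10, knee = 10, ankle = 10) * (amps - 1)
    structure(list(
      subject_id = sprintf("S%03d", i),
      cadence = 0.9 + 0.5 * ses * z[1],
      stride_length = 1.30 + 0.8 * ses * z[2],
      segment_lengths = c(thigh = 0.42 * body, shank = 0.43 * body,
                          foot = 0.20 * body),
      amplitude_scales = amps,
      offset_shifts = offsets,
      seed = seed
    ), class = "subject_profile")
  })
}

#' Ground-truth joint-angle templates for a subject
#'
#' Evaluates the subject's hip/knee/ankle sagittal angle curves at the given
#' cycle phases: `offset_shift + amplitude_scale * template(phase)`, where the
#' template is the package's truncated-Fourier normative curve (periodic, so
#' phase 0 and phase 1 agree).
#'
#' @param profile a `subject_profile` from [make_profiles()].
#' @param cycle_phase numeric vector of phases in \[0, 1\] (values outside are
#'   wrapped).
#' @return length(cycle_phase) x 3 matrix, columns `hip`, `knee`, `ankle`
#'   (degrees; flexion/dorsiflexion positive).
#' @export
joint_angle_templates <- function(profile, cycle_phase) {
  phase <- cycle_phase %% 1
  out <- sapply(c("hip", "knee", "ankle"), function(j) {
    profile$offset_shifts[[j]] +
      profile$amplitude_scales[[j]] * eval_template(.gait_templates[[j]], phase)
  })
  out <- matrix(out, ncol = 3, dimnames = list(NULL, c("hip", "knee", "ankle")))
  out
}

# Marker positions of one foot in its local frame (ankle-joint center at the
# origin, y anterior, z up); `med` is the medial direction (+1 or -1 in x).
foot_marker_layout <- function(foot_len, med) {
  w <- 0.035 * foot_len / 0.2
  h <- -0.07
  list(
    heel = c(0, -0.3 * foot_len, h),
    mt1 = c(med * w, 0.6 * foot_len, h),
    mt5 = c(-med * w, 0.6 * foot_len, h),
    mml = c(med * w, 0, 0),
    lml = c(-med * w, 0, 0)
  )
}

# Rotate a fixed local vector by Rx(theta) per sample and translate; theta in
# radians, base a T x 3 matrix. Returns T x 3.
transport_x <- function(base, theta, local) {
  ct <- cos(theta); st <- sin(theta)
  cbind(base[, 1] + local[1],
        base[, 2] + local[2] * ct - local[3] * st,
        base[, 3] + local[2] * st + local[3] * ct)
}

rx_axes <- function(theta) {
  t_ <- length(theta)
  ct <- cos(theta); st <- sin(theta)
  zero <- numeric(t_); one <- rep(1, t_)
  axes_array(cbind(one, zero, zero), cbind(zero, ct, st), cbind(zero, -st, ct))
}

#' Forward kinematics of one limb's sagittal chain
#'
#' Builds rigid-body-consistent foot markers (heel, MT1, MT5, MML, LML) and
#' pelvis/thigh/shank frames from joint-angle series, using a planar sagittal
#' chain: the pelvis translates along the anterior (y) axis at
#' `stride_length * cadence` with identity orientation; thigh, shank, and
#' foot rotate about the lab x (right/left) axis by the hip angle, hip minus
#' knee, and hip minus knee plus ankle angle respectively. Inverting these
#' markers through the kinematics pipeline recovers `angles` exactly (up to
#' filtering), which is the ground-truth oracle used in the tests.
#'
#' @param profile a `subject_profile`.
#' @param angles T x 3 matrix (`hip`, `knee`, `ankle`, degrees).
#' @param time_grid time stamps (s), length T, uniformly spaced.
#' @param side `"left"` or `"right"`.
#' @param pelvis_origin optional T x 3 pelvis-origin override (m).
#' @return List with `markers` (named list of [marker_trajectory]: heel, mt1,
#'   mt5, mml, lml), `frames` (named list of [segment_frame]: pelvis, thigh,
#'   shank), and `rate`.
#' @export
forward_kinematics <- function(profile, angles, time_grid,
                               side = c("left", "right"),
                               pelvis_origin = NULL) {
  side <- match.arg(side)
  angles <- as.matrix(angles)
  if (!all(is.finite(angles))) stop("input error: non-finite joint angles")
  t_ <- nrow(angles)
  if (length(time_grid) != t_) stop("angles and time_grid lengths differ")
  rate <- 1 / stats::median(diff(time_grid))
  lt <- profile$segment_lengths[["thigh"]]
  ls <- profile$segment_lengths[["shank"]]
  lf <- profile$segment_lengths[["foot"]]
  sgn <- if (side == "left") -1 else 1   # limb offset along x (x = right)
  med <- -sgn                            # medial direction points to midline
  if (is.null(pelvis_origin)) {
    speed <- profile$stride_length * profile$cadence
    pelvis_origin <- cbind(0, speed * time_grid, lt + ls + 0.08)
  }
  h <- deg2rad(angles[, "hip"])
  s <- h - deg2rad(angles[, "knee"])
  f <- s + deg2rad(angles[, "ankle"])
  hip <- pelvis_origin + matrix(c(sgn * 0.09, 0, 0), t_, 3, byrow = TRUE)
  knee <- hip + lt * cbind(0, sin(h), -cos(h))
  ankle <- knee + ls * cbind(0, sin(s), -cos(s))
  layout <- foot_marker_layout(lf, med)
  markers <- lapply(layout, function(loc) {
    marker_trajectory(transport_x(ankle, f, loc), rate)
  })
  for (nm in names(markers)) markers[[nm]]$label <- nm
  frames <- list(
    pelvis = segment_frame(pelvis_origin, rx_axes(rep(0, t_)), validate = FALSE),
    thigh = segment_frame(hip, rx_axes(h), validate = FALSE),
    shank = segment_frame(knee, rx_axes(s), validate = FALSE)
  )
  list(markers = markers, frames = frames, rate = rate)
}

# Two-peaked vertical GRF stance template on u in [0,1); includes a small
# heel-strike step (7% of the peak scale) so the threshold crossing of the
# raw force coincides with the scheduled contact sample.
grf_stance_template <- function(u, peak = 700) {
  peak * (sin(pi * u) + 0.25 * sin(3 * pi * u) + 0.07 * (1 - u))
}

# Vertical GRF series for one limb given its heel-contact times.
make_grf <- function(t_grid, contacts, stance_dur, peak = 700) {
  f <- numeric(length(t_grid))
  for (hc in contacts) {
    u <- (t_grid - hc) / stance_dur
    in_stance <- u >= 0 & u < 1
    f[in_stance] <- grf_stance_template(u[in_stance], peak)
  }
  f
}

# Smooth (low-pass) additive noise field with the requested SD. The default
# band (3 Hz) models slow stride-to-stride drift of the joint-angle pattern.
smooth_noise <- function(n, sd, rate, seed, cutoff = 3) {
  if (sd == 0) return(numeric(n))
  w <- with_seed(seed, stats::rnorm(n))
  x <- zero_lag_butterworth(w, cutoff, rate)
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s < 1e-12) return(numeric(n))
  x * (sd / s)
}

#' Generate one synthetic walking trial
#'
#' Simulates both limbs over three full ipsilateral gait cycles (plus lead-in
#' and tail margin so interior cycles have valid central differences), the
#' contralateral limb being the same chain phase-shifted by exactly half a
#' cycle. Per-trial smooth angle noise is added to the template angles and
#' the markers are generated from the noisy angles, so the stored
#' `truth_angles` are exactly consistent with the marker data.
#'
#' @param profile a `subject_profile`.
#' @param trial_id integer trial id (odd = left ipsilateral, even = right).
#' @param config the [gait_config].
#' @return An object of class `synthetic_trial`: markers and proximal-segment
#'   frames per limb, per-limb vertical GRF (N) at `grf_rate`, per-limb truth
#'   angle matrices (degrees) at `marker_rate`, the ipsilateral `side`, and
#'   the scheduled heel-contact times (`schedule`, seconds).
#' @export
make_trial <- function(profile, trial_id, config) {
  side <- if (trial_id %% 2 == 1) "left" else "right"
  other <- if (side == "left") "right" else "left"
  tc <- 1 / profile$cadence
  n_cycles <- 3
  lead <- 0.3 * tc
  t_end <- lead + n_cycles * tc + 0.4 * tc
  dt <- 1 / config$marker_rate
  t_grid <- seq(0, t_end, by = dt)
  t_ <- length(t_grid)
  hc <- list()
  hc[[side]] <- lead + (0:n_cycles) * tc
  hc[[other]] <- lead + ((0:n_cycles) + 0.5) * tc
  hc[[other]] <- c(hc[[other]][1] - tc, hc[[other]])
  hc[[other]] <- hc[[other]][hc[[other]] >= 0 & hc[[other]] <= t_end]
  trial_seed <- mix_seed(profile$seed, trial_id)
  angles <- list()
  for (lim in c("left", "right")) {
    # phase measured from this limb's first scheduled contact; any contact of
    # the limb works since contacts are exactly one cycle apart
    phase <- (t_grid - hc[[lim]][1]) / tc
    base <- joint_angle_templates(profile, phase)
    noise <- sapply(1:3, function(j) {
      smooth_noise(t_, config$noise_sd_angle, config$marker_rate,
                   mix_seed(trial_seed, if (lim == "left") 10 else 20, j))
    })
    angles[[lim]] <- base + noise
    colnames(angles[[lim]]) <- c("hip", "knee", "ankle")
  }
  fk <- lapply(c(left = "left", right = "right"), function(lim) {
    forward_kinematics(profile, angles[[lim]], t_grid, lim)
  })
  stance_dur <- config$cycle_fraction_stance * tc
  tg <- seq(0, t_end, by = 1 / config$grf_rate)
  grf <- lapply(c(left = "left", right = "right"), function(lim) {
    cts <- c(hc[[lim]][1] - tc, hc[[lim]])  # cover stance begun before t=0
    make_grf(tg, cts[cts + stance_dur > 0], stance_dur)
  })
  structure(list(
    subject_id = profile$subject_id, trial_id = trial_id, side = side,
    marker_rate = config$marker_rate, grf_rate = config$grf_rate,
    time = t_grid,
    markers = list(left = fk$left$markers, right = fk$right$markers),
    frames = list(pelvis = fk[[side]]$frames$pelvis,
                  left = fk$left$frames[c("thigh", "shank")],
                  right = fk$right$frames[c("thigh", "shank")]),
    grf = grf,
    truth_angles = angles,
    schedule = hc,
    cadence = profile$cadence
  ), class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial %s/%d (%s): %d marker samples @ %g Hz>\n",
              x$subject_id, x$trial_id, x$side, length(x$time), x$marker_rate))
  invisible(x)
}

#' Generate a full synthetic gait dataset
#'
#' @param config a [gait_config].
#' @return List of `n_subjects * n_trials_per_subject` [make_trial()] objects,
#'   ordered by subject then trial. Byte-identical for identical
#'   configurations.
#' @export
synthesize_dataset <- function(config) {
  profiles <- make_profiles(config)
  out <- vector("list", config$n_subjects * config$n_trials_per_subject)
  k <- 1
  for (p in profiles) {
    for (tr in seq_len(config$n_trials_per_subject)) {
      out[[k]] <- make_trial(p, tr, config)
      k <- k + 1
    }
  }
  out
}
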