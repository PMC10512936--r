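# Gait-event processing: zero-lag filtering, heel-contact detection from
# vertical GRF, cycle extraction, 200-point time normalization, and assembly
# of the input (norm-feature) and output (joint-angle) waveform matrices.

#' Zero-lag Butterworth low-pass filter
#'
#' Forward-backward (zero phase shift) application of a Butterworth low-pass
#' filter whose combined response is 4th order (order 2 per pass). DC gain
#' is 1, so constant signals pass unchanged.
#'
#' @param series numeric vector.
#' @param cutoff cutoff frequency (Hz); must be below the Nyquist rate.
#' @param rate sampling rate (Hz).
#' @return Filtered vector of the same length.
#' @export
zero_lag_butterworth <- function(series, cutoff, rate) {
  if (cutoff <= 0 || cutoff >= rate / 2) {
    stop("configuration error: cutoff must lie in (0, rate/2)")
  }
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  n <- length(series)
  # odd-reflection padding at both ends so the forward-backward pass carries
  # no startup transient into the data
  pad <- min(n - 1, max(9, ceiling(6 * rate / cutoff)))
  head_pad <- 2 * series[1] - series[seq(pad + 1, 2)]
  tail_pad <- 2 * series[n] - series[seq(n - 1, n - pad)]
  y <- signal::filtfilt(bf, c(head_pad, series, tail_pad))
  as.numeric(y[(pad + 1):(pad + n)])
}

filter_positions <- function(p, cutoff, rate) {
  apply(p, 2, zero_lag_butterworth, cutoff = cutoff, rate = rate)
}

#' Detect heel contacts from vertical ground-reaction force
#'
#' Heel contacts are ascending crossings of a force threshold, separated by
#' at least a refractory interval (to ignore re-crossings within one stance).
#' A series already above threshold at its first sample has no crossing
#' there: a stance phase in progress when recording starts is not a contact.
#'
#' @param force vertical GRF (N), one limb.
#' @param rate sampling rate of the force series (Hz).
#' @param threshold force threshold (N), default 20.
#' @param refractory minimum event separation (s), default 0.2.
#' @return Event times in seconds (possibly empty), where time 0 is the first
#'   sample.
#' @export
detect_heel_contacts <- function(force, rate, threshold = 20, refractory = 0.2) {
  above <- force >= threshold
  ups <- which(!above[-length(above)] & above[-1]) + 1
  times <- (ups - 1) / rate
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Extract ipsilateral gait cycles
#'
#' Pairs consecutive heel-contact events into cycles (heel contact to the
#' next ipsilateral heel contact), maps event times to the nearest
#' marker-rate sample, and discards cycles touching the trial endpoints
#' (where central-difference derivatives are invalid).
#'
#' @param events heel-contact times (s) of one limb.
#' @param n_samples number of marker-rate samples in the trial.
#' @param marker_rate marker sampling rate (Hz).
#' @return Data frame with columns `start`, `end` (marker-sample indices,
#'   1-based).
#' @export
extract_cycles <- function(events, n_samples, marker_rate) {
  if (length(events) < 2) {
    stop("no-cycle error: fewer than two ipsilateral heel contacts")
  }
  idx <- round(events * marker_rate) + 1
  start <- idx[-length(idx)]
  end <- idx[-1]
  ok <- start > 1 & end < n_samples & end > start
  data.frame(start = start[ok], end = end[ok])
}

#' Time-normalize a channel over one gait cycle
#'
#' Linearly interpolates the samples of one cycle onto 200 points at phases
#' i/199, i = 0..199 (both the heel contact and the next ipsilateral heel
#' contact included).
#'
#' @param values channel samples over the cycle (length >= 2).
#' @param n_points number of output points, default 200.
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(values, n_points = 200) {
  n <- length(values)
  if (n < 2) stop("cycle too short to normalize")
  if (anyNA(values)) stop("cycle contains invalid (NA) samples")
  stats::approx(seq(0, 1, length.out = n), values,
                xout = seq(0, 1, length.out = n_points))$y
}

#' Processing parameters for the event/feature pipeline
#'
#' @param marker_cutoff marker low-pass cutoff (Hz), default 10.
#' @param grf_cutoff GRF low-pass cutoff (Hz), default 56.
#' @param threshold heel-contact force threshold (N), default 20.
#' @param refractory heel-contact refractory period (s), default 0.2.
#' @param n_points time-normalization length, default 200.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(marker_cutoff = 10, grf_cutoff = 56,
                            threshold = 20, refractory = 0.2, n_points = 200) {
  structure(list(marker_cutoff = marker_cutoff, grf_cutoff = grf_cutoff,
                 threshold = threshold, refractory = refractory,
                 n_points = n_points), class = "pipeline_params")
}

# Norm-feature channels (acceleration and angular-velocity norms of one foot)
# from filtered markers.
foot_norm_channels <- function(markers, side, rate, cutoff) {
  filt <- lapply(markers, function(m) {
    marker_trajectory(filter_positions(m$positions, cutoff, rate), rate, m$label)
  })
  frame <- build_foot_frame(filt$heel, filt$mt1, filt$mt5, filt$mml, filt$lml,
                            side = side)
  vm <- virtual_foot_marker(filt$mt1, filt$mt5, filt$mml, filt$lml)
  acc <- norm_series(linear_acceleration(vm))
  q <- frame_quaternions(frame)
  omega <- norm_series(angular_velocity(q, rate))
  list(acc = acc, omega = omega, frame = frame)
}

#' Process one trial into a feature row and a target row
#'
#' Runs the full per-trial pipeline: low-pass marker filtering, foot-frame
#' construction for both feet, virtual-foot-marker acceleration norms and
#' foot angular-velocity norms, ipsilateral joint angles from the segment
#' frames, GRF filtering and heel-contact detection, extraction of the first
#' valid ipsilateral cycle, and 200-point time normalization. The feature row
#' concatenates, in fixed order, the ipsilateral acceleration norm, the
#' ipsilateral angular-velocity norm, and the contralateral pair (800 values
#' at the default length); the target row concatenates the ipsilateral hip,
#' knee, and ankle angles (600 values).
#'
#' @param trial a `synthetic_trial` (or an object with the same fields).
#' @param params a [pipeline_params].
#' @return List with `features` (length 4 * n_points), `targets`
#'   (3 * n_points), `cycle` (start/end sample indices), and `angles`
#'   (full-trial ipsilateral angle matrix).
#' @export
process_trial <- function(trial, params = pipeline_params()) {
  side <- trial$side
  other <- if (side == "left") "right" else "left"
  rate <- trial$marker_rate
  ipsi <- foot_norm_channels(trial$markers[[side]], side, rate, params$marker_cutoff)
  contra <- foot_norm_channels(trial$markers[[other]], other, rate, params$marker_cutoff)
  ang <- joint_angles(trial$frames$pelvis, trial$frames[[side]]$thigh,
                      trial$frames[[side]]$shank, ipsi$frame)
  grf <- zero_lag_butterworth(trial$grf[[side]], params$grf_cutoff, trial$grf_rate)
  events <- detect_heel_contacts(grf, trial$grf_rate, params$threshold,
                                 params$refractory)
  cycles <- extract_cycles(events, length(trial$time), rate)
  # derivative channels are NA at trial endpoints; keep cycles clear of them
  ok <- cycles$start > 1 & cycles$end < length(trial$time)
  cycles <- cycles[ok, , drop = FALSE]
  if (nrow(cycles) == 0) stop("no-cycle error: no interior cycle in trial")
  cyc <- cycles[1, ]
  sl <- cyc$start:cyc$end
  np <- params$n_points
  features <- c(time_normalize(ipsi$acc[sl], np),
                time_normalize(ipsi$omega[sl], np),
                time_normalize(contra$acc[sl], np),
                time_normalize(contra$omega[sl], np))
  targets <- c(time_normalize(ang[sl, "hip"], np),
               time_normalize(ang[sl, "knee"], np),
               time_normalize(ang[sl, "ankle"], np))
  list(features = features, targets = targets, cycle = cyc, angles = ang)
}

#' Assemble the input and output waveform matrices
#'
#' Builds the model's input matrix (one norm-feature row per analyzed gait
#' cycle, one cycle per trial) and output matrix (ipsilateral joint-angle
#' row), with rows ordered deterministically by `(subject_id, trial_id)` so
#' the result does not depend on processing order.
#'
#' @param trials list of `synthetic_trial` objects (order irrelevant).
#' @param params a [pipeline_params].
#' @return List of class `waveform_matrices`: `input` (n x 4*n_points),
#'   `output` (n x 3*n_points), and `index` (data frame `subject_id`,
#'   `trial_id`, `side` per row).
#' @export
assemble_matrices <- function(trials, params = pipeline_params()) {
  ord <- order(vapply(trials, function(x) x$subject_id, ""),
               vapply(trials, function(x) x$trial_id, 0))
  trials <- trials[ord]
  rows <- lapply(trials, process_trial, params = params)
  nf <- lengths(lapply(rows, `[[`, "features"))
  if (length(unique(nf)) != 1) stop("assembly error: feature width mismatch")
  input <- do.call(rbind, lapply(rows, `[[`, "features"))
  output <- do.call(rbind, lapply(rows, `[[`, "targets"))
  index <- data.frame(
    subject_id = vapply(trials, function(x) x$subject_id, ""),
    trial_id = vapply(trials, function(x) x$trial_id, 0),
    side = vapply(trials, function(x) x$side, "")
  )
  structure(list(input = input, output = output, index = index),
            class = "waveform_matrices")
}

#' @export
print.waveform_matrices <- function(x, ...) {
  cat(sprintf("<waveform_matrices: input %d x %d, output %d x %d, %d subjects>\n",
              nrow(x$input), ncol(x$input), nrow(x$output), ncol(x$output),
              length(unique(x$index$subject_id))))
  invisible(x)
}
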