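# Accuracy metrics for actual vs predicted 200-point joint-angle waveforms:
# per-joint average RMSE (deg), NRMSE (% of the actual waveform's range),
# Pearson correlation, and mean absolute errors of clinically used
# angles-at-timings.

joint_slices <- function(d, joints = c("hip", "knee", "ankle")) {
  np <- d / length(joints)
  stats::setNames(lapply(seq_along(joints), function(j) {
    ((j - 1) * np + 1):(j * np)
  }), joints)
}

#' Waveform accuracy metrics
#'
#' For every trial and joint: RMSE over the cycle points, NRMSE = 100 * RMSE
#' / (max - min) of the actual waveform, and the Pearson correlation between
#' actual and predicted waveforms; each is then averaged over trials. Trials
#' whose actual waveform is constant have undefined NRMSE/correlation; they
#' are excluded from those averages with a warning.
#'
#' @param actual,predicted n x (3 * n_points) matrices, columns ordered hip,
#'   knee, ankle.
#' @return Object of class `metrics_report`: `summary` (per-joint mean RMSE,
#'   NRMSE, rho) and `trials` (per-trial breakdown).
#' @export
waveform_metrics <- function(actual, predicted) {
  actual <- as.matrix(actual); predicted <- as.matrix(predicted)
  if (!all(dim(actual) == dim(predicted))) stop("shape mismatch")
  if (nrow(actual) < 1) stop("need at least one trial")
  slices <- joint_slices(ncol(actual))
  rows <- list()
  for (joint in names(slices)) {
    a <- actual[, slices[[joint]], drop = FALSE]
    p <- predicted[, slices[[joint]], drop = FALSE]
    rmse <- sqrt(rowMeans((a - p)^2))
    rng <- apply(a, 1, function(v) diff(range(v)))
    const <- rng < 1e-12
    if (any(const)) {
      warning(sprintf("%d constant actual %s waveform(s): NRMSE/rho excluded",
                      sum(const), joint))
    }
    nrmse <- ifelse(const, NA_real_, 100 * rmse / rng)
    rho <- vapply(seq_len(nrow(a)), function(i) {
      if (const[i]) NA_real_ else stats::cor(a[i, ], p[i, ])
    }, 0)
    rows[[joint]] <- data.frame(trial = seq_len(nrow(a)), joint = joint,
                                rmse = rmse, nrmse = nrmse, rho = rho)
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  summary <- do.call(rbind, lapply(names(slices), function(joint) {
    tj <- trials[trials$joint == joint, ]
    data.frame(joint = joint,
               rmse = mean(tj$rmse),
               nrmse = mean(tj$nrmse, na.rm = TRUE),
               rho = mean(tj$rho, na.rm = TRUE))
  }))
  structure(list(summary = summary, trials = trials), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Waveform accuracy (averaged over trials):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s RMSE %5.2f deg  NRMSE %5.1f %%  rho %.3f\n",
                s$joint[i], s$rmse[i], s$nrmse[i], s$rho[i]))
  }
  invisible(x)
}

#' Angles at clinically used timings
#'
#' Extracts, from one 200-point joint-angle waveform: the value at heel
#' contact (first point) and the cycle extrema. Hip: flexion at heel contact
#' and peak extension (cycle minimum, flexion-positive convention). Knee:
#' peak flexion (maximum). Ankle: dorsiflexion at heel contact, peak
#' dorsiflexion (maximum), peak plantar flexion (minimum). Peaks are taken
#' over the full cycle.
#'
#' @param waveform numeric joint-angle waveform over one cycle (degrees).
#' @param joint `"hip"`, `"knee"`, or `"ankle"`.
#' @return Named numeric vector of timing angles (degrees).
#' @export
timing_angles <- function(waveform, joint = c("hip", "knee", "ankle")) {
  joint <- match.arg(joint)
  switch(joint,
    hip = c(hip_flexion_at_hc = waveform[1],
            peak_hip_extension = min(waveform)),
    knee = c(peak_knee_flexion = max(waveform)),
    ankle = c(ankle_dorsiflexion_at_hc = waveform[1],
              peak_ankle_dorsiflexion = max(waveform),
              peak_ankle_plantarflexion = min(waveform))
  )
}

trial_timing_angles <- function(row, slices) {
  unlist(lapply(names(slices), function(j) {
    timing_angles(row[slices[[j]]], j)
  }))
}

#' Mean absolute errors of angles at timings
#'
#' Computes the six timing angles ([timing_angles()]) for each paired
#' actual/predicted trial and reports the mean and SD of the absolute
#' differences across trials.
#'
#' @param actual,predicted n x (3 * n_points) matrices (paired rows).
#' @return Data frame with columns `quantity`, `mae`, `sd` (degrees).
#' @export
timing_mae <- function(actual, predicted) {
  actual <- as.matrix(actual); predicted <- as.matrix(predicted)
  if (!all(dim(actual) == dim(predicted))) stop("shape mismatch")
  if (nrow(actual) < 1) stop("empty trial set")
  slices <- joint_slices(ncol(actual))
  a <- t(apply(actual, 1, trial_timing_angles, slices = slices))
  p <- t(apply(predicted, 1, trial_timing_angles, slices = slices))
  err <- abs(a - p)
  data.frame(quantity = colnames(a),
             mae = colMeans(err),
             sd = apply(err, 2, function(v) if (length(v) < 2) 0 else stats::sd(v)),
             row.names = NULL)
}
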