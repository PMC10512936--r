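# Plain-text interchange: the package's trial TSV dialect, dataset manifests,
# waveform matrices as CSV with a JSON row-index sidecar, and estimator
# bundles. All positions are meters, forces Newtons, angles degrees.

quat_to_axes <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  a <- array(0, dim = c(nrow(q), 3, 3))
  a[, 1, 1] <- 1 - 2 * (y^2 + z^2); a[, 1, 2] <- 2 * (x * y - w * z)
  a[, 1, 3] <- 2 * (x * z + w * y)
  a[, 2, 1] <- 2 * (x * y + w * z); a[, 2, 2] <- 1 - 2 * (x^2 + z^2)
  a[, 2, 3] <- 2 * (y * z - w * x)
  a[, 3, 1] <- 2 * (x * z - w * y); a[, 3, 2] <- 2 * (y * z + w * x)
  a[, 3, 3] <- 1 - 2 * (x^2 + y^2)
  a
}

marker_names <- c("heel", "mt1", "mt5", "mml", "lml")

#' Write / read one trial in the package TSV dialect
#'
#' One tab-separated table per trial at the GRF rate, with a `sample` index
#' column; marker positions (m), ground-truth joint angles (deg), and
#' proximal-frame orientation quaternions are filled on marker-rate rows and
#' empty elsewhere; per-limb vertical GRF (N) fills every row. Metadata
#' (subject, trial, side, rates) travels in `#`-prefixed header lines.
#' Frame origins are not serialized: joint angles depend only on segment
#' orientations.
#'
#' @param trial a `synthetic_trial`.
#' @param path output file path.
#' @return `write_trial_tsv` returns `path` invisibly; `read_trial_tsv`
#'   returns a `synthetic_trial`.
#' @export
write_trial_tsv <- function(trial, path) {
  step <- trial$grf_rate / trial$marker_rate
  n_g <- length(trial$grf$left)
  n_m <- length(trial$time)
  tab <- data.frame(sample = seq_len(n_g) - 1)
  tab$time <- (tab$sample) / trial$grf_rate
  marker_rows <- seq(1, n_g, by = step)[seq_len(n_m)]
  put <- function(values) {
    v <- rep(NA_real_, n_g)
    v[marker_rows] <- values
    v
  }
  for (side in c("left", "right")) {
    for (m in marker_names) {
      p <- trial$markers[[side]][[m]]$positions
      for (k in 1:3) {
        tab[[sprintf("%s_%s_%s", side, m, c("x", "y", "z")[k])]] <- put(p[, k])
      }
    }
    for (j in c("hip", "knee", "ankle")) {
      tab[[sprintf("truth_%s_%s", side, j)]] <- put(trial$truth_angles[[side]][, j])
    }
    for (seg in c("thigh", "shank")) {
      q <- frame_quaternions(trial$frames[[side]][[seg]])
      for (k in 1:4) {
        tab[[sprintf("%s_%s_q%s", side, seg, c("w", "x", "y", "z")[k])]] <-
          put(q[, k])
      }
    }
    tab[[paste0("grf_", side)]] <- trial$grf[[side]]
  }
  qp <- frame_quaternions(trial$frames$pelvis)
  for (k in 1:4) {
    tab[[sprintf("pelvis_q%s", c("w", "x", "y", "z")[k])]] <- put(qp[, k])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject_id\t%s", trial$subject_id),
    sprintf("# trial_id\t%d", trial$trial_id),
    sprintf("# side\t%s", trial$side),
    sprintf("# marker_rate\t%g", trial$marker_rate),
    sprintf("# grf_rate\t%g", trial$grf_rate)
  ), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_tsv
#' @export
read_trial_tsv <- function(path) {
  hdr <- readLines(path, n = 5)
  meta <- lapply(strsplit(sub("^# ", "", hdr), "\t"), `[`, 2)
  names(meta) <- vapply(strsplit(sub("^# ", "", hdr), "\t"), `[`, "", 1)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  marker_rate <- as.numeric(meta$marker_rate)
  grf_rate <- as.numeric(meta$grf_rate)
  step <- grf_rate / marker_rate
  mrows <- seq(1, nrow(tab), by = step)
  mrows <- mrows[!is.na(tab$pelvis_qw[mrows])]
  markers <- list(); truth <- list(); frames <- list(); grf <- list()
  for (side in c("left", "right")) {
    markers[[side]] <- lapply(stats::setNames(marker_names, marker_names), function(m) {
      p <- as.matrix(tab[mrows, sprintf("%s_%s_%s", side, m, c("x", "y", "z"))])
      dimnames(p) <- NULL
      marker_trajectory(p, marker_rate, m)
    })
    truth[[side]] <- as.matrix(tab[mrows, sprintf("truth_%s_%s", side,
                                                  c("hip", "knee", "ankle"))])
    dimnames(truth[[side]]) <- list(NULL, c("hip", "knee", "ankle"))
    frames[[side]] <- lapply(stats::setNames(c("thigh", "shank"),
                                             c("thigh", "shank")), function(seg) {
      q <- as.matrix(tab[mrows, sprintf("%s_%s_q%s", side, seg,
                                        c("w", "x", "y", "z"))])
      segment_frame(matrix(0, length(mrows), 3), quat_to_axes(q), validate = FALSE)
    })
    grf[[side]] <- tab[[paste0("grf_", side)]]
  }
  qp <- as.matrix(tab[mrows, sprintf("pelvis_q%s", c("w", "x", "y", "z"))])
  frames$pelvis <- segment_frame(matrix(0, length(mrows), 3), quat_to_axes(qp),
                                 validate = FALSE)
  structure(list(
    subject_id = meta$subject_id, trial_id = as.integer(meta$trial_id),
    side = meta$side, marker_rate = marker_rate, grf_rate = grf_rate,
    time = (mrows - 1) / grf_rate,
    markers = markers, frames = frames, grf = grf, truth_angles = truth,
    schedule = NULL, cadence = NA_real_
  ), class = "synthetic_trial")
}

#' Write a dataset of trials with a manifest
#'
#' Writes one TSV per trial plus `manifest.csv` (`subject_id`, `trial_id`,
#' `side`, `file`).
#'
#' @param trials list of `synthetic_trial` objects.
#' @param dir output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(trials, function(tr) {
    f <- sprintf("%s_trial%02d.tsv", tr$subject_id, tr$trial_id)
    write_trial_tsv(tr, file.path(dir, f))
    data.frame(subject_id = tr$subject_id, trial_id = tr$trial_id,
               side = tr$side, file = f)
  }))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    read_trial_tsv(file.path(dir, manifest$file[i]))
  })
}

#' Write / read assembled waveform matrices
#'
#' The input and output matrices are written as headerless CSV next to a JSON
#' sidecar carrying the row index (subject, trial, side) and the channel map.
#'
#' @param wm a [assemble_matrices()] result.
#' @param prefix path prefix; writes `<prefix>_input.csv`,
#'   `<prefix>_output.csv`, `<prefix>_index.json`.
#' @return `write_matrices` returns `prefix` invisibly; `read_matrices` the
#'   `waveform_matrices` object.
#' @export
write_matrices <- function(wm, prefix) {
  utils::write.table(wm$input, paste0(prefix, "_input.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(wm$output, paste0(prefix, "_output.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  np <- ncol(wm$input) / 4
  sidecar <- list(
    index = wm$index,
    input_channels = c("ipsi_acc_norm", "ipsi_omega_norm",
                       "contra_acc_norm", "contra_omega_norm"),
    output_channels = c("hip", "knee", "ankle"),
    n_points = np
  )
  jsonlite::write_json(sidecar, paste0(prefix, "_index.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_matrices
#' @export
read_matrices <- function(prefix) {
  input <- as.matrix(utils::read.csv(paste0(prefix, "_input.csv"), header = FALSE))
  output <- as.matrix(utils::read.csv(paste0(prefix, "_output.csv"), header = FALSE))
  dimnames(input) <- NULL; dimnames(output) <- NULL
  sidecar <- jsonlite::read_json(paste0(prefix, "_index.json"),
                                 simplifyVector = TRUE)
  structure(list(input = input, output = output, index = sidecar$index),
            class = "waveform_matrices")
}

#' Save / load a trained estimator bundle
#'
#' Writes the input/output codecs and network weights with their
#' hyperparameters into a directory of JSON files.
#'
#' @param est a [fit_main()] estimator.
#' @param dir bundle directory.
#' @return `write_estimator` returns `dir` invisibly; `read_estimator` the
#'   estimator.
#' @export
write_estimator <- function(est, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_codec(est$input_codec, file.path(dir, "input_codec.json"))
  write_codec(est$output_codec, file.path(dir, "output_codec.json"))
  net <- list(
    sizes = est$net$sizes,
    weights = lapply(est$net$weights, as.vector),
    biases = est$net$biases,
    hp = unclass(est$hp), cfg = unclass(est$cfg),
    test_group = est$test_group, train_rows = est$train_rows,
    train_mean_output = est$train_mean_output,
    history = est$net$history
  )
  jsonlite::write_json(net, file.path(dir, "network.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_estimator
#' @export
read_estimator <- function(dir) {
  net <- jsonlite::read_json(file.path(dir, "network.json"), simplifyVector = TRUE)
  sizes <- net$sizes
  weights <- lapply(seq_along(sizes)[-1] - 1, function(l) {
    matrix(net$weights[[l]], sizes[l], sizes[l + 1])
  })
  hp <- do.call(hyper_params, as.list(net$hp))
  cfg <- structure(as.list(net$cfg), class = "training_config")
  cfg$epochs <- as.integer(cfg$epochs); cfg$seed <- as.integer(cfg$seed)
  fnn <- structure(list(weights = weights, biases = net$biases, sizes = sizes,
                        hp = hp, cfg = cfg, history = net$history),
                   class = "fnn")
  structure(list(input_codec = read_codec(file.path(dir, "input_codec.json")),
                 output_codec = read_codec(file.path(dir, "output_codec.json")),
                 net = fnn, hp = hp, cfg = cfg, test_group = net$test_group,
                 train_rows = net$train_rows,
                 train_mean_output = net$train_mean_output),
            class = "trained_estimator")
}

#' Read pipeline parameters from a YAML config file
#'
#' Recognized keys: `marker_cutoff`, `grf_cutoff`, `threshold`, `refractory`,
#' `n_points`; missing keys take the [pipeline_params()] defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_params] object.
#' @export
read_pipeline_params <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs")
  }
  cfg <- yaml::read_yaml(path)
  defaults <- pipeline_params()
  for (k in names(cfg)) {
    if (!k %in% names(defaults)) stop(sprintf("unknown pipeline parameter '%s'", k))
    defaults[[k]] <- cfg[[k]]
  }
  defaults
}
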