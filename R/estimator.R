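# Subject-level splitting, the hyperparameter grid, k-fold cross-validated
# tuning on PC scores, main-model training, and prediction.

#' Subject-level random group assignment
#'
#' Randomly partitions subjects into near-equal groups (sizes differing by at
#' most one). All trials of a subject share its group, so no subject's data
#' can appear on both sides of a train/validation/test boundary.
#'
#' @param subject_ids character vector of subject ids (unique or per-trial).
#' @param n_groups number of groups, default 5.
#' @param seed RNG seed for the shuffle.
#' @return Object of class `split_assignment`: named integer vector `groups`
#'   (subject -> group) and `n_groups`.
#' @export
split_groups <- function(subject_ids, n_groups = 5, seed = 1L) {
  ids <- sort(unique(subject_ids))
  if (length(ids) < n_groups) {
    stop(sprintf("need at least %d subjects for %d groups", n_groups, n_groups))
  }
  shuffled <- with_seed(seed, sample(ids))
  groups <- rep(seq_len(n_groups), length.out = length(ids))
  assignment <- stats::setNames(groups, shuffled)[ids]
  structure(list(groups = assignment, n_groups = as.integer(n_groups)),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("<split_assignment: %d subjects in %d groups (sizes %s)>\n",
              length(x$groups), x$n_groups,
              paste(tabulate(x$groups, x$n_groups), collapse = "/")))
  invisible(x)
}

rows_in_groups <- function(split, index, groups) {
  which(split$groups[index$subject_id] %in% groups)
}

#' Hyperparameter grid
#'
#' Cartesian product of layer/node combinations, batch sizes, dropout rates,
#' and learning rates, in deterministic order (layer/node combinations
#' outermost, learning rate innermost). The default axes give 12 x 3 x 3 x 3
#' = 324 conditions and contain the combination (1 hidden layer, 80 nodes,
#' batch 512, dropout 0.5, learning rate 0.001).
#'
#' @param layer_node_combos data frame with columns `n_hidden_layers` and
#'   `nodes_per_layer`; default \{1,2,3,4\} layers x \{40,80,120\} nodes.
#' @param batch_sizes default c(128, 256, 512).
#' @param dropout_rates default c(0.3, 0.4, 0.5).
#' @param learning_rates default c(0.01, 0.001, 0.0001).
#' @return Data frame of conditions with a `condition` id column.
#' @export
hyperparameter_grid <- function(layer_node_combos = NULL,
                                batch_sizes = c(128, 256, 512),
                                dropout_rates = c(0.3, 0.4, 0.5),
                                learning_rates = c(0.01, 0.001, 0.0001)) {
  if (is.null(layer_node_combos)) {
    layer_node_combos <- data.frame(
      n_hidden_layers = rep(1:4, each = 3),
      nodes_per_layer = rep(c(40, 80, 120), times = 4)
    )
  }
  if (nrow(layer_node_combos) == 0 || length(batch_sizes) == 0 ||
      length(dropout_rates) == 0 || length(learning_rates) == 0) {
    stop("configuration error: empty grid axis")
  }
  # expand.grid varies its first factor fastest, so listing the learning rate
  # first and the layer/node combo last gives combos outermost and the
  # learning rate innermost
  g <- expand.grid(learning_rate = learning_rates,
                   dropout_rate = dropout_rates,
                   batch_size = batch_sizes,
                   combo = seq_len(nrow(layer_node_combos)))
  out <- data.frame(
    condition = seq_len(nrow(g)),
    n_hidden_layers = layer_node_combos$n_hidden_layers[g$combo],
    nodes_per_layer = layer_node_combos$nodes_per_layer[g$combo],
    batch_size = g$batch_size,
    dropout_rate = g$dropout_rate,
    learning_rate = g$learning_rate
  )
  rownames(out) <- NULL
  out
}

grid_row_hp <- function(grid, i) {
  hyper_params(grid$n_hidden_layers[i], grid$nodes_per_layer[i],
               grid$batch_size[i], grid$dropout_rate[i], grid$learning_rate[i])
}

#' Enumerate the cross-validation workload
#'
#' Lists every (dataset, condition) training run the tuning stage performs:
#' k datasets times the grid size (1,296 runs for the default grid with
#' k = 4), without training anything.
#'
#' @param grid a [hyperparameter_grid()].
#' @param k number of cross-validation folds, default 4.
#' @return Data frame with one row per scheduled fit (`dataset`, `condition`).
#' @export
cv_plan <- function(grid, k = 4) {
  expand.grid(condition = grid$condition, dataset = seq_len(k))[, c(2, 1)]
}

#' k-fold cross-validated hyperparameter tuning
#'
#' The test group is held out entirely; the remaining `n_groups - 1` groups
#' rotate as the validation set (k datasets, k = 4 with a 5-group split).
#' For each dataset the input and output codecs are fit on that dataset's
#' training groups only, train and validation rows are encoded, one network
#' is trained per grid condition, and the mean absolute error between actual
#' and predicted validation output scores (pooled over all entries) is
#' recorded. Per-condition MAEs are averaged over the k datasets and the
#' condition with the lowest mean is returned (ties broken by grid order).
#'
#' @param wm a [assemble_matrices()] result (input/output matrices + index).
#' @param split a [split_groups()] assignment.
#' @param grid a [hyperparameter_grid()].
#' @param cfg a [training_config()].
#' @param test_group group held out from tuning, default the last group.
#' @param retention codec retention rule, default `"kaiser"`.
#' @return List of class `cv_result`: `best` (a [hyper_params]), `table`
#'   (condition table with per-dataset and mean MAE), and `n_fits`.
#' @export
cross_validate <- function(wm, split, grid, cfg = training_config(),
                           test_group = split$n_groups,
                           retention = "kaiser") {
  cand <- setdiff(seq_len(split$n_groups), test_group)
  k <- length(cand)
  if (k < 2) stop("need at least two non-test groups")
  mae <- matrix(NA_real_, nrow(grid), k)
  for (di in seq_along(cand)) {
    val_group <- cand[di]
    train_groups <- setdiff(cand, val_group)
    tr <- rows_in_groups(split, wm$index, train_groups)
    va <- rows_in_groups(split, wm$index, val_group)
    if (length(unique(wm$index$subject_id[tr])) < 2) {
      stop("fold has fewer than two training subjects")
    }
    codec_in <- pca_fit(wm$input[tr, , drop = FALSE], retention = retention)
    codec_out <- pca_fit(wm$output[tr, , drop = FALSE], retention = retention)
    s_in_tr <- pca_encode(codec_in, wm$input[tr, , drop = FALSE])
    s_out_tr <- pca_encode(codec_out, wm$output[tr, , drop = FALSE])
    s_in_va <- pca_encode(codec_in, wm$input[va, , drop = FALSE])
    s_out_va <- pca_encode(codec_out, wm$output[va, , drop = FALSE])
    for (ci in seq_len(nrow(grid))) {
      hp <- grid_row_hp(grid, ci)
      fit_cfg <- cfg
      fit_cfg$seed <- mix_seed(cfg$seed, di, ci)
      net <- train_fnn(s_in_tr, s_out_tr, hp, fit_cfg)
      pred <- fnn_predict(net, s_in_va)
      mae[ci, di] <- mean(abs(s_out_va - pred))
    }
  }
  tab <- cbind(grid, stats::setNames(as.data.frame(mae),
                                     paste0("mae_dataset", seq_len(k))))
  tab$mean_mae <- rowMeans(mae)
  best_i <- which.min(tab$mean_mae)
  structure(list(best = grid_row_hp(grid, best_i),
                 best_condition = grid$condition[best_i],
                 table = tab, n_fits = k * nrow(grid)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  b <- x$best
  cat(sprintf(paste0("<cv_result: %d fits, best condition %d ",
                     "(%d layers x %d nodes, batch %d, dropout %.2g, lr %.2g), ",
                     "mean MAE %.4g>\n"),
              x$n_fits, x$best_condition, b$n_hidden_layers, b$nodes_per_layer,
              b$batch_size, b$dropout_rate,
              b$learning_rate, min(x$table$mean_mae)))
  invisible(x)
}

#' Fit the main model
#'
#' Fits the input and output codecs on the training groups only (all groups
#' except the test group), trains the network on their scores, and bundles
#' codecs, weights, and configuration into a `trained_estimator`. The row
#' audit (`train_rows`) records exactly which matrix rows influenced the fit.
#'
#' @param wm a [assemble_matrices()] result.
#' @param split a [split_groups()] assignment.
#' @param hp a [hyper_params] (typically [cross_validate()]`$best`).
#' @param cfg a [training_config()].
#' @param test_group held-out group, default the last group.
#' @param retention codec retention rule, default `"kaiser"`.
#' @return Object of class `trained_estimator`.
#' @export
fit_main <- function(wm, split, hp, cfg = training_config(),
                     test_group = split$n_groups, retention = "kaiser") {
  train_groups <- setdiff(seq_len(split$n_groups), test_group)
  tr <- rows_in_groups(split, wm$index, train_groups)
  codec_in <- pca_fit(wm$input[tr, , drop = FALSE], retention = retention)
  codec_out <- pca_fit(wm$output[tr, , drop = FALSE], retention = retention)
  s_in <- pca_encode(codec_in, wm$input[tr, , drop = FALSE])
  s_out <- pca_encode(codec_out, wm$output[tr, , drop = FALSE])
  net <- train_fnn(s_in, s_out, hp, cfg)
  structure(list(input_codec = codec_in, output_codec = codec_out, net = net,
                 hp = hp, cfg = cfg, test_group = test_group,
                 train_rows = tr, train_mean_output = colMeans(wm$output[tr, , drop = FALSE])),
            class = "trained_estimator")
}

#' @export
print.trained_estimator <- function(x, ...) {
  cat(sprintf(paste0("<trained_estimator: %d -> %s -> %d scores, ",
                     "%d training rows, test group %d>\n"),
              x$input_codec$n_components,
              paste(rep(x$hp$nodes_per_layer, x$hp$n_hidden_layers), collapse = "-"),
              x$output_codec$n_components, length(x$train_rows), x$test_group))
  invisible(x)
}

#' Predict joint-angle waveforms from norm features
#'
#' Encodes the feature rows with the input codec, runs the network forward
#' pass (dropout off), and decodes the predicted output scores back to
#' joint-angle waveforms.
#'
#' @param object a [fit_main()] estimator.
#' @param features n x (4 * n_points) norm-feature matrix.
#' @param ... unused.
#' @return n x (3 * n_points) predicted joint-angle matrix (degrees).
#' @export
predict.trained_estimator <- function(object, features, ...) {
  scores_in <- pca_encode(object$input_codec, features)
  scores_out <- fnn_predict(object$net, scores_in)
  pca_decode(object$output_codec, scores_out)
}

#' Mean-waveform baseline prediction
#'
#' Predicts the training-set mean output waveform for every test row; the
#' reference any informative estimator must beat.
#'
#' @param est a [fit_main()] estimator.
#' @param n_rows number of rows to predict.
#' @return n_rows x (3 * n_points) matrix.
#' @export
baseline_predict <- function(est, n_rows) {
  matrix(est$train_mean_output, n_rows, length(est$train_mean_output),
         byrow = TRUE)
}
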