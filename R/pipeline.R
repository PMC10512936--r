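# End-to-end convenience wrapper: synthesize -> assemble -> split -> tune ->
# train -> predict -> evaluate. Used by the command-line front end, the test
# suite, and the reproduction script.

#' Reduced tuning grid for desk-scale runs
#'
#' An 8-condition grid (1 hidden layer x \{40, 80\} nodes, batch 128, dropout
#' \{0, 0.2\}, learning rate \{0.01, 0.003\}) sized so a tune/train/test round
#' trip on a synthetic dataset runs in minutes on one CPU. The full
#' 324-condition default of [hyperparameter_grid()] remains available for
#' study-scale tuning.
#'
#' @return A hyperparameter grid data frame.
#' @export
reduced_grid <- function() {
  hyperparameter_grid(
    layer_node_combos = data.frame(n_hidden_layers = 1,
                                   nodes_per_layer = c(40, 80)),
    batch_sizes = 128,
    dropout_rates = c(0, 0.2),
    learning_rates = c(0.01, 0.003)
  )
}

#' Run the full estimation experiment on synthetic gait data
#'
#' Generates the dataset, assembles the norm-feature and joint-angle
#' matrices, splits subjects into five groups, tunes hyperparameters by
#' 4-fold cross-validation with the last group held out as the test set,
#' fits the main model on the four training groups, predicts the test group,
#' and evaluates waveform and timing accuracy against both the actual angles
#' and the mean-waveform baseline.
#'
#' @param config a [gait_config].
#' @param grid a [hyperparameter_grid()]; default [reduced_grid()].
#' @param train_cfg a [training_config()].
#' @param split_seed seed for the subject-level split.
#' @param params a [pipeline_params].
#' @param wm optional pre-assembled [assemble_matrices()] result (skips
#'   generation).
#' @return List of class `gait_experiment`: `wm`, `split`, `cv`, `estimator`,
#'   `test_rows`, `predicted`, `metrics`, `baseline_metrics`, `timing`,
#'   and `rmse_ratio` (per-joint model/baseline RMSE ratio).
#' @export
run_gait_experiment <- function(config, grid = reduced_grid(),
                                train_cfg = training_config(epochs = 100),
                                split_seed = train_cfg$seed,
                                params = pipeline_params(), wm = NULL) {
  if (is.null(wm)) {
    wm <- assemble_matrices(synthesize_dataset(config), params = params)
  }
  split <- split_groups(wm$index$subject_id, seed = split_seed)
  cv <- cross_validate(wm, split, grid, train_cfg)
  est <- fit_main(wm, split, cv$best, train_cfg)
  te <- which(split$groups[wm$index$subject_id] == est$test_group)
  pred <- predict(est, wm$input[te, , drop = FALSE])
  actual <- wm$output[te, , drop = FALSE]
  metrics <- waveform_metrics(actual, pred)
  base <- waveform_metrics(actual, baseline_predict(est, length(te)))
  structure(list(
    wm = wm, split = split, cv = cv, estimator = est, test_rows = te,
    predicted = pred, metrics = metrics, baseline_metrics = base,
    timing = timing_mae(actual, pred),
    rmse_ratio = stats::setNames(metrics$summary$rmse / base$summary$rmse,
                                 metrics$summary$joint)
  ), class = "gait_experiment")
}

#' @export
print.gait_experiment <- function(x, ...) {
  print(x$metrics)
  cat(sprintf("  model/baseline RMSE ratio: %s\n",
              paste(sprintf("%s %.2f", names(x$rmse_ratio), x$rmse_ratio),
                    collapse = ", ")))
  invisible(x)
}
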