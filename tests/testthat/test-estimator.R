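test_that("subject-level splits are balanced, exhaustive, and seed-reproducible", {
  ids <- sprintf("S%03d", 1:200)
  split <- split_groups(ids, n_groups = 5, seed = 2)
  expect_equal(unname(tabulate(split$groups, 5)), rep(40, 5))
  expect_setequal(names(split$groups), ids)
  expect_identical(split_groups(ids, seed = 2)$groups, split$groups)
  expect_false(identical(split_groups(ids, seed = 3)$groups, split$groups))
  # trials inherit their subject's group: repeated ids collapse to one subject
  split2 <- split_groups(rep(ids[1:10], each = 10), n_groups = 5, seed = 1)
  expect_length(split2$groups, 10)
  expect_error(split_groups(ids[1:3], n_groups = 5), "at least 5")
})

test_that("the default hyperparameter grid enumerates 324 ordered conditions", {
  grid <- hyperparameter_grid()
  expect_equal(nrow(grid), 324)
  hit <- grid$n_hidden_layers == 1 & grid$nodes_per_layer == 80 &
    grid$batch_size == 512 & grid$dropout_rate == 0.5 &
    grid$learning_rate == 0.001
  expect_equal(sum(hit), 1)
  # learning rate varies fastest, layer/node combos slowest
  expect_equal(grid$learning_rate[1:3], c(0.01, 0.001, 0.0001))
  expect_equal(grid$n_hidden_layers[1:27], rep(1, 27))
  g2 <- hyperparameter_grid(
    layer_node_combos = data.frame(n_hidden_layers = 1:2, nodes_per_layer = 10),
    batch_sizes = 8, dropout_rates = 0.1, learning_rates = 0.01)
  expect_equal(nrow(g2), 2)
  expect_error(hyperparameter_grid(batch_sizes = numeric(0)), "empty")
})

test_that("the tuning plan enumerates k x grid-size fits", {
  expect_equal(nrow(cv_plan(hyperparameter_grid(), k = 4)), 1296)
  expect_equal(nrow(cv_plan(reduced_grid(), k = 4)), 32)
})

test_that("a small network memorizes a toy score set", {
  set.seed(14)
  x <- matrix(stats::rnorm(20 * 4), 20, 4)
  y <- cbind(sin(x[, 1]) + 0.3 * x[, 2], x[, 3] * x[, 4])
  hp <- hyper_params(1, 80, 32, 0, 0.01)
  net <- train_fnn(x, y, hp, training_config(epochs = 2000, seed = 5))
  expect_lt(mean((fnn_predict(net, x) - y)^2), 1e-3)
})

test_that("zero learning rate freezes the network at its initialization", {
  set.seed(15)
  x <- matrix(stats::rnorm(30 * 3), 30, 3)
  y <- matrix(stats::rnorm(30 * 2), 30, 2)
  hp <- hyper_params(2, 10, 30, 0, 0)
  net <- train_fnn(x, y, hp, training_config(epochs = 20, seed = 9))
  expect_equal(stats::sd(net$history), 0)
  # output layer is zero-initialized with mean biases: prediction = column means
  expect_equal(fnn_predict(net, x),
               matrix(colMeans(y), 30, 2, byrow = TRUE), tolerance = 1e-12)
})

test_that("training is deterministic given the seed and errors on bad shapes", {
  set.seed(16)
  x <- matrix(stats::rnorm(40 * 3), 40, 3)
  y <- matrix(stats::rnorm(40 * 2), 40, 2)
  hp <- hyper_params(1, 12, 16, 0.3, 0.005)
  n1 <- train_fnn(x, y, hp, training_config(epochs = 30, seed = 4))
  n2 <- train_fnn(x, y, hp, training_config(epochs = 30, seed = 4))
  expect_identical(n1$weights, n2$weights)
  expect_identical(n1$history, n2$history)
  n3 <- train_fnn(x, y, hp, training_config(epochs = 30, seed = 5))
  expect_false(identical(n1$weights, n3$weights))
  expect_error(train_fnn(x, y[1:10, ], hp), "row counts differ")
  expect_error(fnn_predict(n1, y), "width mismatch")
})

test_that("cross-validation averages fold MAEs and returns the winning condition", {
  wm <- small_wm()
  split <- split_groups(wm$index$subject_id, seed = 3)
  grid1 <- hyperparameter_grid(
    layer_node_combos = data.frame(n_hidden_layers = 1, nodes_per_layer = 20),
    batch_sizes = 64, dropout_rates = 0, learning_rates = 0.01)
  cv1 <- cross_validate(wm, split, grid1, training_config(epochs = 10, seed = 2))
  expect_equal(cv1$best_condition, 1)
  expect_equal(cv1$n_fits, 4)
  expect_equal(dim(cv1$table), c(1, 6 + 4 + 1))
  expect_equal(cv1$table$mean_mae,
               rowMeans(cv1$table[, paste0("mae_dataset", 1:4)]))
})

test_that("a sabotaged grid is won by the only condition that can learn", {
  wm <- small_wm()
  split <- split_groups(wm$index$subject_id, seed = 3)
  # learning rate 0 freezes competitors at the mean-prediction baseline
  grid <- hyperparameter_grid(
    layer_node_combos = data.frame(n_hidden_layers = 1, nodes_per_layer = 40),
    batch_sizes = 64, dropout_rates = 0, learning_rates = c(0, 0.01, 0))
  cv <- cross_validate(wm, split, grid, training_config(epochs = 40, seed = 2))
  expect_equal(cv$n_fits, 12)
  winner <- cv$table[cv$table$condition == cv$best_condition, ]
  expect_equal(winner$learning_rate, 0.01)
  # deterministic repeat gives the identical condition table
  cv2 <- cross_validate(wm, split, grid, training_config(epochs = 40, seed = 2))
  expect_equal(cv2$table, cv$table)
})

test_that("the main model fits only on training groups and predicts test-shaped output", {
  wm <- small_wm()
  split <- split_groups(wm$index$subject_id, seed = 3)
  hp <- hyper_params(1, 20, 64, 0, 0.01)
  est <- fit_main(wm, split, hp, training_config(epochs = 20, seed = 6))
  te <- which(split$groups[wm$index$subject_id] == est$test_group)
  # leakage audit: no test row participates in codec or network fitting
  expect_length(intersect(est$train_rows, te), 0)
  expect_setequal(c(est$train_rows, te), seq_len(nrow(wm$input)))
  tr_in <- wm$input[est$train_rows, ]
  expect_equal(unname(est$input_codec$means), unname(colMeans(tr_in)))
  # prediction shape and determinism
  pred <- predict(est, wm$input[te, , drop = FALSE])
  expect_equal(dim(pred), c(length(te), 600))
  expect_true(all(is.finite(pred)))
  est2 <- fit_main(wm, split, hp, training_config(epochs = 20, seed = 6))
  expect_equal(predict(est2, wm$input[te, , drop = FALSE]), pred)
  # the training-mean feature row decodes to a finite 1 x 600 waveform
  mean_row <- matrix(colMeans(tr_in), 1)
  p0 <- predict(est, mean_row)
  expect_equal(dim(p0), c(1, 600))
  expect_true(all(is.finite(p0)))
  expect_error(predict(est, wm$input[te, 1:100]), "width mismatch")
})

test_that("estimator bundles round-trip through the on-disk archive", {
  wm <- small_wm()
  split <- split_groups(wm$index$subject_id, seed = 3)
  est <- fit_main(wm, split, hyper_params(1, 16, 64, 0, 0.01),
                  training_config(epochs = 10, seed = 1))
  dir <- tempfile("bundle")
  write_estimator(est, dir)
  est2 <- read_estimator(dir)
  expect_equal(predict(est2, wm$input[1:3, , drop = FALSE]),
               predict(est, wm$input[1:3, , drop = FALSE]), tolerance = 1e-12)
})
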