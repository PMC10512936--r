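# Small fully connected network trainer used to regress output-waveform PC
# scores on input PC scores: dense layers with Swish activations and inverted
# dropout, a linear output layer, mean-squared-error loss, and the Adam
# optimizer. Deterministic given the training seed.

#' Hyperparameter set for the FNN estimator
#'
#' @param n_hidden_layers number of hidden layers (>= 1).
#' @param nodes_per_layer nodes in each hidden layer.
#' @param batch_size minibatch size.
#' @param dropout_rate dropout probability in \[0, 1), applied after each
#'   hidden activation.
#' @param learning_rate Adam step size (>= 0; 0 freezes the weights, useful
#'   for testing).
#' @return Object of class `hyper_params`.
#' @export
hyper_params <- function(n_hidden_layers, nodes_per_layer, batch_size,
                         dropout_rate, learning_rate) {
  if (n_hidden_layers < 1 || nodes_per_layer < 1 || batch_size < 1) {
    stop("layer, node, and batch counts must be positive")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (learning_rate < 0) stop("learning_rate must be non-negative")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 nodes_per_layer = as.integer(nodes_per_layer),
                 batch_size = as.integer(batch_size),
                 dropout_rate = dropout_rate, learning_rate = learning_rate),
            class = "hyper_params")
}

#' Training configuration
#'
#' @param epochs training epochs, default 300.
#' @param seed integer RNG seed governing initialization, minibatch
#'   shuffling, and dropout masks.
#' @return Object of class `training_config`. Activation (Swish), optimizer
#'   (Adam), and loss (MSE on output scores) are fixed.
#' @export
training_config <- function(epochs = 300, seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), activation = "swish",
                 optimizer = "adam", loss = "mse", seed = as.integer(seed)),
            class = "training_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))
swish <- function(z) z * sigmoid(z)
swish_grad <- function(z) {
  s <- sigmoid(z)
  s * (1 + z * (1 - s))
}

# He-style initialization for the hidden layers; the linear output layer
# starts at zero weights with the target column means as biases, so the
# initial prediction is the training mean of the (deliberately unrescaled)
# output scores and optimization starts from the baseline model.
fnn_init <- function(n_in, n_out, hp, y_mean = NULL) {
  sizes <- c(n_in, rep(hp$nodes_per_layer, hp$n_hidden_layers), n_out)
  weights <- vector("list", length(sizes) - 1)
  biases <- vector("list", length(sizes) - 1)
  n_layers <- length(weights)
  for (l in seq_len(n_layers)) {
    sd_l <- sqrt(2 / sizes[l])
    weights[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sd_l),
                           sizes[l], sizes[l + 1])
    biases[[l]] <- numeric(sizes[l + 1])
  }
  if (!is.null(y_mean)) {
    weights[[n_layers]] <- matrix(0, sizes[n_layers], n_out)
    biases[[n_layers]] <- y_mean
  }
  list(weights = weights, biases = biases, sizes = sizes)
}

# Forward pass; dropout masks (already scaled) are used when supplied.
fnn_forward_pass <- function(net, x, masks = NULL) {
  n_layers <- length(net$weights)
  zs <- vector("list", n_layers)
  as <- vector("list", n_layers + 1)
  as[[1]] <- x
  for (l in seq_len(n_layers)) {
    z <- as[[l]] %*% net$weights[[l]] +
      matrix(net$biases[[l]], nrow(x), length(net$biases[[l]]), byrow = TRUE)
    zs[[l]] <- z
    if (l < n_layers) {
      h <- swish(z)
      if (!is.null(masks)) h <- h * masks[[l]]
      as[[l + 1]] <- h
    } else {
      as[[l + 1]] <- z  # linear output
    }
  }
  list(zs = zs, as = as, output = as[[n_layers + 1]])
}

#' Train the feedforward network on PC scores
#'
#' Minibatch training with per-epoch shuffling (the last short batch is
#' kept), Swish hidden activations, inverted dropout after each hidden
#' activation, a linear output layer, MSE loss over all output entries, and
#' Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8). All randomness derives
#' from `cfg$seed`, so identical inputs give identical weights.
#'
#' @param scores_in t x p input score matrix.
#' @param scores_out t x q output score matrix.
#' @param hp a [hyper_params].
#' @param cfg a [training_config].
#' @return Object of class `fnn`: weights, biases, `hp`, `cfg`, and
#'   `history` (mean minibatch MSE per epoch).
#' @export
train_fnn <- function(scores_in, scores_out, hp, cfg = training_config()) {
  x <- as.matrix(scores_in); y <- as.matrix(scores_out)
  if (nrow(x) != nrow(y)) stop("input and output score row counts differ")
  n <- nrow(x)
  with_seed(cfg$seed, {
    net <- fnn_init(ncol(x), ncol(y), hp, y_mean = colMeans(y))
    n_layers <- length(net$weights)
    adam <- list(
      mw = lapply(net$weights, function(w) w * 0),
      vw = lapply(net$weights, function(w) w * 0),
      mb = lapply(net$biases, function(b) b * 0),
      vb = lapply(net$biases, function(b) b * 0),
      t = 0
    )
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr <- hp$learning_rate
    history <- numeric(cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = hp$batch_size)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        rows <- ord[starts[bi]:min(starts[bi] + hp$batch_size - 1, n)]
        xb <- x[rows, , drop = FALSE]
        yb <- y[rows, , drop = FALSE]
        masks <- NULL
        if (hp$dropout_rate > 0 && n_layers > 1) {
          masks <- lapply(seq_len(n_layers - 1), function(l) {
            keep <- matrix(stats::runif(length(rows) * hp$nodes_per_layer) >=
                             hp$dropout_rate,
                           length(rows), hp$nodes_per_layer)
            keep / (1 - hp$dropout_rate)
          })
        }
        fw <- fnn_forward_pass(net, xb, masks)
        err <- fw$output - yb
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop(sprintf("divergence error: non-finite loss at epoch %d", epoch))
        }
        losses[bi] <- loss
        # backprop; dL/doutput for MSE over all entries
        delta <- 2 * err / length(err)
        gw <- vector("list", n_layers); gb <- vector("list", n_layers)
        for (l in rev(seq_len(n_layers))) {
          gw[[l]] <- crossprod(fw$as[[l]], delta)
          gb[[l]] <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(net$weights[[l]])
            if (!is.null(masks)) delta <- delta * masks[[l - 1]]
            delta <- delta * swish_grad(fw$zs[[l - 1]])
          }
        }
        adam$t <- adam$t + 1
        c1 <- 1 - b1^adam$t; c2 <- 1 - b2^adam$t
        for (l in seq_len(n_layers)) {
          adam$mw[[l]] <- b1 * adam$mw[[l]] + (1 - b1) * gw[[l]]
          adam$vw[[l]] <- b2 * adam$vw[[l]] + (1 - b2) * gw[[l]]^2
          net$weights[[l]] <- net$weights[[l]] -
            lr * (adam$mw[[l]] / c1) / (sqrt(adam$vw[[l]] / c2) + eps)
          adam$mb[[l]] <- b1 * adam$mb[[l]] + (1 - b1) * gb[[l]]
          adam$vb[[l]] <- b2 * adam$vb[[l]] + (1 - b2) * gb[[l]]^2
          net$biases[[l]] <- net$biases[[l]] -
            lr * (adam$mb[[l]] / c1) / (sqrt(adam$vb[[l]] / c2) + eps)
        }
      }
      history[epoch] <- mean(losses)
    }
    structure(list(weights = net$weights, biases = net$biases,
                   sizes = net$sizes, hp = hp, cfg = cfg, history = history),
              class = "fnn")
  })
}

#' Network forward pass (inference)
#'
#' Dropout is disabled at inference (inverted dropout needs no rescaling).
#'
#' @param net a trained [train_fnn()] network.
#' @param scores_in t x p input score matrix.
#' @return t x q output score matrix.
#' @export
fnn_predict <- function(net, scores_in) {
  x <- as.matrix(scores_in)
  if (ncol(x) != net$sizes[1]) {
    stop(sprintf("width mismatch: network expects %d inputs, got %d",
                 net$sizes[1], ncol(x)))
  }
  fnn_forward_pass(list(weights = net$weights, biases = net$biases), x)$output
}

#' @export
print.fnn <- function(x, ...) {
  cat(sprintf("<fnn: %s, final training MSE %.4g>\n",
              paste(x$sizes, collapse = "-"),
              x$history[length(x$history)]))
  invisible(x)
}
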