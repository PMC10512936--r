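# Standardize-then-PCA waveform codec. A t x d waveform matrix (t trials,
# d data points per row) is encoded as W^T = M_mean + M_sd %*% M_pcl %*%
# M_pcs^T: each column is standardized by its own mean and SD (correlation
# PCA, forced by the mean/SD structure of the reconstruction identity) and
# projected onto the leading eigenvectors of the correlation matrix.

#' Fit a PCA waveform codec
#'
#' Standardizes each column of the training matrix by its mean and SD and
#' eigen-decomposes the correlation matrix. Component retention: `"kaiser"`
#' keeps components with eigenvalue >= `kaiser_threshold` (default 1),
#' `"all"` keeps `min(t - 1, d)` components, `"fixed"` keeps `n_components`.
#' Loading signs follow a fixed convention (the largest-magnitude loading of
#' each component is positive) so results are reproducible across linear
#' algebra backends.
#'
#' @param train t x d numeric matrix (t >= 2).
#' @param retention `"kaiser"`, `"all"`, or `"fixed"`.
#' @param n_components retained components when `retention = "fixed"`.
#' @param kaiser_threshold eigenvalue cutoff for `"kaiser"`, default 1.
#' @return Object of class `pca_codec`: `means`, `sds` (length d), `loadings`
#'   (d x n), `eigenvalues` (all d, descending), `n_components`, `retention`.
#' @export
pca_fit <- function(train, retention = c("kaiser", "all", "fixed"),
                    n_components = NULL, kaiser_threshold = 1) {
  retention <- match.arg(retention)
  train <- as.matrix(train)
  t_ <- nrow(train); d <- ncol(train)
  if (t_ < 2) stop("need at least two rows to fit the codec")
  if (!all(is.finite(train))) stop("training matrix must be finite")
  means <- colMeans(train)
  sds <- apply(train, 2, stats::sd)
  bad <- which(sds < 1e-12)
  if (length(bad) > 0) {
    stop(sprintf("degenerate column %d: zero variance (flat channel)", bad[1]))
  }
  z <- sweep(sweep(train, 2, means), 2, sds, "/")
  cc <- stats::cor(train)
  eig <- eigen(cc, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  vectors <- eig$vectors
  # fixed sign convention: largest-|loading| entry positive per component
  for (j in seq_len(ncol(vectors))) {
    k <- which.max(abs(vectors[, j]))
    if (vectors[k, j] < 0) vectors[, j] <- -vectors[, j]
  }
  n <- switch(retention,
    kaiser = sum(values >= kaiser_threshold),
    all = min(t_ - 1, d),
    fixed = {
      if (is.null(n_components)) stop("n_components required for fixed retention")
      min(n_components, d)
    }
  )
  n <- max(n, 1L)
  structure(list(
    means = means, sds = sds,
    loadings = vectors[, seq_len(n), drop = FALSE],
    eigenvalues = values,
    n_components = as.integer(n), retention = retention,
    kaiser_threshold = kaiser_threshold, d = d
  ), class = "pca_codec")
}

#' @export
print.pca_codec <- function(x, ...) {
  cat(sprintf("<pca_codec: d = %d, %d components retained (%s), %.1f%% variance>\n",
              x$d, x$n_components, x$retention,
              100 * sum(x$eigenvalues[seq_len(x$n_components)]) / x$d))
  invisible(x)
}

#' Encode waveforms as principal-component scores
#'
#' Standardizes `data` with the codec's training means/SDs and projects onto
#' the retained loadings. Applied to the training matrix this reproduces the
#' fit scores (column means zero).
#'
#' @param codec a [pca_fit()] result.
#' @param data t x d matrix, d matching the codec.
#' @return t x n score matrix.
#' @export
pca_encode <- function(codec, data) {
  data <- as.matrix(data)
  if (ncol(data) != codec$d) {
    stop(sprintf("width mismatch: data has %d columns, codec expects %d",
                 ncol(data), codec$d))
  }
  z <- sweep(sweep(data, 2, codec$means), 2, codec$sds, "/")
  z %*% codec$loadings
}

#' Decode principal-component scores back to waveforms
#'
#' Evaluates the reconstruction identity: each decoded row is
#' `means + sds * (scores %*% t(loadings))`. With zero scores every row is
#' the training mean waveform; with all components retained the round trip
#' is the identity on the training data.
#'
#' @param codec a [pca_fit()] result.
#' @param scores t x n score matrix, n matching the codec.
#' @return t x d waveform matrix.
#' @export
pca_decode <- function(codec, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != codec$n_components) {
    stop(sprintf("width mismatch: scores have %d columns, codec retains %d",
                 ncol(scores), codec$n_components))
  }
  z <- scores %*% t(codec$loadings)
  sweep(sweep(z, 2, codec$sds, "*"), 2, codec$means, "+")
}

#' Serialize / restore a codec
#'
#' Writes the codec (means, SDs, loadings, eigenvalues, retention rule) to a
#' single JSON file for reuse between tuning, training, and test stages.
#'
#' @param codec a `pca_codec`.
#' @param path file path.
#' @return `write_codec` returns `path` invisibly; `read_codec` the codec.
#' @export
write_codec <- function(codec, path) {
  obj <- unclass(codec)
  obj$loadings <- as.vector(obj$loadings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_codec
#' @export
read_codec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$loadings <- matrix(obj$loadings, nrow = obj$d)
  obj$n_components <- as.integer(obj$n_components)
  structure(obj[c("means", "sds", "loadings", "eigenvalues", "n_components",
                  "retention", "kaiser_threshold", "d")], class = "pca_codec")
}
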