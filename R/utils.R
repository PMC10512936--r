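# Internal numeric helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Row-wise cross product of two T x 3 matrices.
cross_rows <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# Row-wise normalization; errors if any row is (numerically) zero.
unit_rows <- function(m, what = "vector", tol = 1e-12) {
  n <- sqrt(rowSums(m^2))
  bad <- which(n < tol)
  if (length(bad) > 0) {
    stop(sprintf("degenerate geometry: zero-length %s at sample %d",
                 what, bad[1]), call. = FALSE)
  }
  m / n
}

# Rotation about the lab x-axis (angle in radians), 3 x 3.
rot_x <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3)
}

rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3)
}

rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

# Deterministic 32-bit seed mixing so sub-streams (subjects, trials, CV fits)
# are reproducible independently of generation order.
mix_seed <- function(...) {
  parts <- c(...)
  h <- 0
  for (p in parts) {
    h <- (h * 1000003 + (as.numeric(p) %% 2147483647)) %% 2147483629
  }
  as.integer(h)
}

# Run code under a local RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
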