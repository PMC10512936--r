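# Shared fixtures and independent helper constructions for the test suite.
# Heavy objects are built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small default-noise dataset: 10 subjects x 4 trials.
small_config <- function(seed = 404) {
  gait_config(n_subjects = 10, n_trials_per_subject = 4, master_seed = seed)
}

small_trials <- function() cached("small_trials", synthesize_dataset(small_config()))

small_wm <- function() cached("small_wm", assemble_matrices(small_trials()))

# Independent rotation-matrix construction (axis-angle form, built directly
# from the Rodrigues expansion rather than the package's rotation helpers).
rodrigues_rotation <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rotation <- function() {
  rodrigues_rotation(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
}

# Rigidly rotate every lab-frame quantity of a trial by Q.
rotate_trial <- function(trial, Q) {
  rot_pts <- function(p) p %*% t(Q)
  for (side in c("left", "right")) {
    for (m in names(trial$markers[[side]])) {
      trial$markers[[side]][[m]]$positions <-
        rot_pts(trial$markers[[side]][[m]]$positions)
    }
    for (seg in c("thigh", "shank")) {
      fr <- trial$frames[[side]][[seg]]
      for (k in 1:3) fr$axes[, , k] <- fr$axes[, , k] %*% t(Q)
      fr$origin <- rot_pts(fr$origin)
      trial$frames[[side]][[seg]] <- fr
    }
  }
  fr <- trial$frames$pelvis
  for (k in 1:3) fr$axes[, , k] <- fr$axes[, , k] %*% t(Q)
  fr$origin <- rot_pts(fr$origin)
  trial$frames$pelvis <- fr
  trial
}

# Static five-marker foot layout as marker_trajectory objects (T samples).
static_foot_markers <- function(t_ = 4, rate = 200) {
  mk <- function(p) marker_trajectory(matrix(rep(p, each = t_), t_, 3), rate)
  list(heel = mk(c(0, 0, 0)), mt1 = mk(c(0.05, 0.2, 0)),
       mt5 = mk(c(-0.05, 0.2, 0)), mml = mk(c(0.03, 0.05, 0.02)),
       lml = mk(c(-0.03, 0.05, 0.02)))
}
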