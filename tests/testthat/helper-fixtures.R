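# shared fixtures, built once per test run and cached in this environment;
# simulations use 500 Hz (still > 2x the highest band edge) to keep the
# suite fast
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# one block, default planted modulation, 15 trials
small_sim <- function() cached("small_sim", {
  simulate_recording(sim_config(sampling_rate = 500, n_blocks = 1,
                                seed = 11))
})

# three blocks (45 executed trials), default planted modulation
recovery_sim <- function(seed = 21) cached(paste0("recovery_sim_", seed), {
  simulate_recording(sim_config(sampling_rate = 500, n_blocks = 3,
                                seed = seed))
})

small_features <- function() cached("small_features", {
  suppressWarnings(session_features(small_sim(), norm = "baseline",
                                    car = FALSE))
})

recovery_features <- function(seed = 21) {
  cached(paste0("recovery_features_", seed), {
    suppressWarnings(session_features(recovery_sim(seed),
                                      norm = "baseline", car = FALSE))
  })
}

# hand-built band_power object for feature-level tests
make_band_power <- function(values, features = NULL, step = 0.05,
                            channels = NULL, channel_names = NULL) {
  stopifnot(length(dim(values)) == 3)
  structure(list(
    values = values,
    features = features %||% paste0("f", seq_len(dim(values)[2])),
    frame_centers = (seq_len(dim(values)[3]) - 1) * step,
    frame_step = step,
    channels = channels,
    channel_names = channel_names %||%
      paste0("ch", seq_len(dim(values)[1]))),
    class = "band_power")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian two-class feature matrix with a given mean separation (in SD
# units) on the informative columns
gaussian_fm <- function(n_per_class = 20, n_features = 2, sep = 6,
                        informative = seq_len(n_features), seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * n_features), n, n_features)
  y <- factor(rep(c("REST", "FORCE"), each = n_per_class),
              levels = c("REST", "FORCE"))
  x[y == "FORCE", informative] <- x[y == "FORCE", informative] + sep
  colnames(x) <- paste0("feat", seq_len(n_features))
  structure(list(x = x, y = y,
                 meta = data.frame(trial_id = seq_len(n)),
                 feature_info = data.frame(column = colnames(x))),
            class = "feature_matrix")
}

# small SVM configuration for fast tests
tiny_svm_config <- function(n_repeats = 2, ...) {
  svm_config(C_grid = 4^(0:2), delta_grid = 4^(-3:-1),
             outer_folds = 3, inner_folds = 3, n_repeats = n_repeats,
             seed = 1, ...)
}
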