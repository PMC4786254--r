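trial_row <- function(onset, level = 30, grasp = "pinch") {
  data.frame(trial_id = NA, block = 1, grasp = grasp,
             level_pct_mvc = level, cue_time_s = onset - 1,
             onset_time_s = onset, offset_time_s = onset + 4,
             executed = TRUE)
}

test_that("feature cells are window means over the 50 ms grid", {
  nfr <- 1200
  n_ch <- 2
  vals <- array(3.25, c(n_ch, 7, nfr))
  times <- (seq_len(nfr) - 1) * 0.05
  bands <- c(default_bands()$name, "lmp")
  chans <- data.frame(channel = c("A1", "A2"), shaft_id = "A",
                      contact_index = 1:2, region = "MC", noisy = FALSE)
  bp <- make_band_power(vals, features = bands, channels = chans,
                        channel_names = chans$channel)
  trials <- do.call(rbind, lapply(c(10, 25, 40), trial_row))
  trials$trial_id <- 1:3
  fm <- build_feature_matrix(bp, trials)
  # constant series: every cell is the constant
  expect_true(all(fm$x == 3.25))
  expect_equal(ncol(fm$x), n_ch * 7)
  expect_equal(colnames(fm$x)[1:2], c("A1_delta_theta", "A1_alpha"))
  expect_equal(as.character(fm$y), rep(c("FORCE", "REST"), each = 3))

  # a ramp 0..15 across the force window averages to 7.5
  vals2 <- array(0, c(n_ch, 7, nfr))
  on <- 10
  i0 <- which(times == on) - 8
  vals2[1, 2, i0:(i0 + 15)] <- 0:15
  bp2 <- make_band_power(vals2, features = bands, channels = chans,
                         channel_names = chans$channel)
  fm2 <- build_feature_matrix(bp2, trial_row(on))
  expect_equal(unname(fm2$x[1, "A1_alpha"]), 7.5)

  # random series equals a loop-based window-mean oracle
  set.seed(9)
  vals3 <- array(rnorm(n_ch * 7 * nfr), c(n_ch, 7, nfr))
  bp3 <- make_band_power(vals3, features = bands, channels = chans,
                         channel_names = chans$channel)
  fm3 <- build_feature_matrix(bp3, trials)
  for (ch in 1:2) for (ft in 1:7) {
    col <- paste0(chans$channel[ch], "_", bands[ft])
    for (k in 1:3) {
      ev <- which(times == trials$onset_time_s[k])
      oracle <- mean(vals3[ch, ft, (ev - 8):(ev + 7)])
      expect_equal(unname(fm3$x[k, col]), oracle)
    }
  }
})

test_that("three-state labels keep extreme levels and drop the middle", {
  nfr <- 2000
  vals <- array(0, c(1, 7, nfr))
  bp <- make_band_power(vals, features = c(default_bands()$name, "lmp"),
                        channel_names = "A1")
  trials <- do.call(rbind, lapply(seq_along(c(20, 30, 40, 20, 40)),
                                  function(i)
    trial_row(5 + 10 * (i - 1), level = c(20, 30, 40, 20, 40)[i])))
  trials$trial_id <- seq_len(nrow(trials))
  fm <- build_feature_matrix(bp, trials, states = "three")
  expect_equal(sum(fm$y == "LIGHT"), 2)
  expect_equal(sum(fm$y == "HARD"), 2)
  expect_equal(sum(fm$y == "REST"), 5)
  bal <- balance_rest(fm, seed = 3)
  expect_equal(as.vector(table(bal$y)), c(2, 2, 2))
  bal2 <- balance_rest(fm, seed = 3)
  expect_identical(bal$x, bal2$x)            # same seed, same subsample
})

test_that("nested CV separates well-separated classes and not noise", {
  fm <- gaussian_fm(n_per_class = 20, n_features = 2, sep = 6, seed = 101)
  res <- nested_cv_svm(fm, tiny_svm_config())
  expect_gte(res$mean_accuracy, 0.95)
  expect_true(all(abs(rowSums(res$confusion) - 1) < 1e-9))

  # permuted labels: accuracy inside the permutation 95% interval
  set.seed(5)
  fm_perm <- fm
  fm_perm$y <- sample(fm$y)
  res_p <- nested_cv_svm(fm_perm, tiny_svm_config())
  chance <- permutation_chance(fm, tiny_svm_config(n_repeats = 1),
                               n_perm = 40, seed = 2)
  qs <- quantile(chance$accuracies, c(0.025, 0.975))
  expect_gte(res_p$mean_accuracy, qs[[1]])
  expect_lte(res_p$mean_accuracy, qs[[2]])
  expect_equal(chance$point, 0.5)
  expect_lt(abs(chance$mean - 0.5), 0.06)
})

test_that("outer-test labels never influence the fitted model", {
  fm <- gaussian_fm(n_per_class = 12, n_features = 3, sep = 2, seed = 7)
  set.seed(42)
  folds <- make_stratified_folds(fm$y, 3)
  cfg <- tiny_svm_config(n_repeats = 1)
  ref <- nested_cv_svm(fm, cfg, folds = folds, keep_fold_details = TRUE)
  for (k in 1:3) {
    fm2 <- fm
    idx <- which(folds == k)
    set.seed(k)
    fm2$y[idx] <- sample(fm2$y[idx])        # scramble only fold k labels
    alt <- nested_cv_svm(fm2, cfg, folds = folds,
                         keep_fold_details = TRUE)
    expect_identical(ref$fold_details[[1]]$pred[idx],
                     alt$fold_details[[1]]$pred[idx])
  }
})

test_that("duplicated trials are co-assigned to the same fold", {
  fm <- gaussian_fm(n_per_class = 10, n_features = 2, sep = 3, seed = 8)
  dup <- fm
  dup$x <- rbind(fm$x, fm$x)                 # exact duplicates
  dup$y <- factor(c(as.character(fm$y), as.character(fm$y)),
                  levels = levels(fm$y))
  dup$meta <- rbind(fm$meta, fm$meta)
  cfg <- tiny_svm_config(n_repeats = 1)
  res <- nested_cv_svm(dup, cfg, keep_fold_details = TRUE)
  folds <- res$fold_details[[1]]$folds
  n <- nrow(fm$x)
  expect_identical(folds[seq_len(n)], folds[n + seq_len(n)])
})

test_that("forward selection finds the informative feature and halts", {
  # one informative column among noise
  fm <- gaussian_fm(n_per_class = 15, n_features = 20, sep = 4,
                    informative = 3, seed = 11)
  cfg <- tiny_svm_config(n_repeats = 1)
  res <- nested_cv_svm(fm, cfg, sfs = TRUE)
  firsts <- vapply(res$selected_features[[1]],
                   function(s) s[1], character(1))
  expect_true(all(firsts == "feat3"))
  expect_gte(res$mean_accuracy, 0.9)

  # all-noise features: selection stops almost immediately
  fm0 <- gaussian_fm(n_per_class = 15, n_features = 10, sep = 0,
                     seed = 12)
  res0 <- nested_cv_svm(fm0, cfg, sfs = TRUE)
  sizes <- vapply(res0$selected_features[[1]], length, integer(1))
  expect_lte(max(sizes), 2)

  # duplicated informative feature: the lower index wins the tie, so the
  # duplicate is never picked before (or instead of) the original
  fm2 <- gaussian_fm(n_per_class = 15, n_features = 6, sep = 4,
                     informative = 4, seed = 13)
  fm2$x[, 6] <- fm2$x[, 4]
  res2 <- nested_cv_svm(fm2, cfg, sfs = TRUE)
  for (s in res2$selected_features[[1]]) {
    expect_equal(s[1], "feat4")
    if ("feat6" %in% s) expect_lt(match("feat4", s), match("feat6", s))
  }
})

test_that("single-feature screen scores every feature", {
  fm <- gaussian_fm(n_per_class = 12, n_features = 4, sep = 5,
                    informative = 2, seed = 14)
  fm$feature_info <- data.frame(column = colnames(fm$x))
  tab <- single_feature_screen(fm, tiny_svm_config(n_repeats = 2))
  expect_equal(nrow(tab), 4)
  expect_gte(tab$mean_accuracy[2], 0.9)
  expect_lt(max(tab$mean_accuracy[c(1, 3, 4)]), 0.8)
})
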