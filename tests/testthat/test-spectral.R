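test_that("STFT of a pure sinusoid matches the windowed-DFT closed form", {
  fs <- 500
  t <- (0:(fs * 10 - 1)) / fs
  # 0.5 s window -> 2 Hz native bins, so a 10 Hz tone sits exactly on a bin
  sp <- stft_power(matrix(2 * sin(2 * pi * 10 * t), 1), fs, win = 0.5)
  p <- function(hz) sp$power[1, sp$bins_hz == hz, ]
  total <- apply(sp$power[1, , ], 2, sum, na.rm = TRUE)
  # Hann closed form: energy in bins k-1, k, k+1 with 1:4:1 power ratio
  expect_gt(min((p(8) + p(10) + p(12)) / total), 0.999)
  expect_equal(mean(p(10) / p(8)), 4, tolerance = 0.02)
  expect_equal(mean(p(10) / p(12)), 4, tolerance = 0.02)
  # constant across frames within 1% (tone is stationary)
  expect_lt(diff(range(p(10))) / mean(p(10)), 0.01)
  # power scales with amplitude squared
  sp2 <- stft_power(matrix(4 * sin(2 * pi * 10 * t), 1), fs, win = 0.5)
  expect_equal(mean(sp2$power[1, sp$bins_hz == 10, ] / p(10)), 4,
               tolerance = 1e-6)
})

test_that("STFT of an all-zero signal is zero and matches per-frame FFT", {
  fs <- 200
  sp0 <- stft_power(matrix(0, 1, fs * 3), fs)
  expect_true(all(sp0$power == 0, na.rm = TRUE))

  # white noise: the 1 Hz-binned power equals an independent per-frame
  # windowed FFT computation (Parseval-style oracle, looped)
  set.seed(4)
  x <- rnorm(fs * 3)
  sp <- stft_power(matrix(x, 1), fs)
  win <- round(0.512 * fs)
  step <- round(0.05 * fs)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(win) - 1) / (win - 1)))
  nb <- fs %/% 2
  for (fr in c(1, 5, length(sp$frame_centers))) {
    seg <- x[(fr - 1) * step + seq_len(win)] * w
    X <- fft(seg)
    freqs <- (seq_len(win) - 1) * fs / win
    keep <- freqs <= fs / 2 & floor(freqs) < nb
    oracle <- tapply(Mod(X[keep])^2 / win, floor(freqs[keep]), sum)
    got <- sp$power[1, as.integer(names(oracle)) + 1, fr]
    expect_equal(unname(got), as.vector(oracle), tolerance = 1e-12)
  }
})

test_that("z-scoring uses the population SD over the normalization epoch", {
  vals <- array(c(1, 2, 3), c(1, 1, 3))
  sp <- structure(list(power = vals, bins_hz = 0,
                       frame_centers = c(0, 0.05, 0.1), frame_step = 0.05,
                       fs = 100, channel_names = "a", zscored = FALSE),
                  class = "stft_power")
  z <- zscore_bins(sp)
  expect_equal(as.vector(z$power),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  # constant track: zeros plus a warning
  sp$power <- array(7, c(1, 1, 3))
  expect_warning(z2 <- zscore_bins(sp), "zero variance")
  expect_true(all(z2$power == 0))
  # affine invariance
  set.seed(5)
  sp$power <- array(rnorm(30), c(1, 2, 15))
  za <- zscore_bins(sp)
  sp$power <- 3.7 * sp$power + 11
  zb <- zscore_bins(sp)
  expect_equal(za$power, zb$power, tolerance = 1e-9)
})

test_that("band aggregation is the unweighted mean over member bins", {
  nb <- 40
  pw <- array(0, c(1, nb, 4))
  pw[1, 7:12, ] <- c(0, 0, 0, 0, 0, 6)     # alpha bins 6..11 Hz
  sp <- structure(list(power = pw, bins_hz = 0:(nb - 1),
                       frame_centers = (0:3) * 0.05, frame_step = 0.05,
                       fs = 100, channel_names = "a", zscored = TRUE),
                  class = "stft_power")
  bands <- data.frame(name = "alpha", lo = 6, hi = 12)
  bp <- aggregate_bands(sp, bands)
  expect_equal(as.vector(bp$values), rep(1.0, 4))
  # all bins equal to c gives every band c
  sp$power[] <- 2.5
  bp2 <- aggregate_bands(sp, data.frame(name = c("a", "b"),
                                        lo = c(0, 12), hi = c(6, 30)))
  expect_true(all(bp2$values == 2.5))
  # permutation invariance over member bins + loop-based oracle
  set.seed(6)
  sp$power <- array(rnorm(nb * 4), c(1, nb, 4))
  bdef <- data.frame(name = c("x", "y"), lo = c(0, 12), hi = c(12, 30))
  bp3 <- aggregate_bands(sp, bdef)
  for (b in 1:2) {
    member <- which(sp$bins_hz >= bdef$lo[b] & sp$bins_hz < bdef$hi[b])
    oracle <- vapply(1:4, function(fr) mean(sp$power[1, member, fr]),
                     numeric(1))
    expect_equal(as.vector(bp3$values[1, b, ]), oracle)
  }
  perm <- sample(member)
  sp$power[1, member, ] <- sp$power[1, perm, ]
  bp4 <- aggregate_bands(sp, bdef)
  expect_equal(bp4$values[1, 2, ], bp3$values[1, 2, ])
  # a band with no populated bin errors
  sp$power[1, 31:40, ] <- NA
  expect_error(aggregate_bands(sp, data.frame(name = "hi", lo = 30,
                                              hi = 40)), "no populated")
})

test_that("LMP reproduces polynomials and equals local regression", {
  fs <- 500
  n <- fs * 2
  centers <- seq(0.3, 1.7, by = 0.05)
  # constant and quadratic signals are reproduced exactly (order 2)
  for (sig in list(rep(3, n), (seq_len(n) / fs)^2)) {
    lmp <- compute_lmp(matrix(sig, 1), centers, fs = fs, zscore = FALSE)
    idx <- round(centers * fs) + 1
    expect_equal(as.vector(lmp), sig[idx], tolerance = 1e-8)
  }
  # arbitrary signal: matches per-window least-squares quadratic at the
  # window centre (independent local polynomial regression oracle)
  set.seed(7)
  x <- cumsum(rnorm(n))
  lmp <- compute_lmp(matrix(x, 1), centers, fs = fs, zscore = FALSE)
  nwin <- round(0.25 * fs)
  if (nwin %% 2 == 0) nwin <- nwin + 1
  h <- (nwin - 1) / 2
  for (k in c(1, 10, length(centers))) {
    i <- round(centers[k] * fs) + 1
    d <- (-h):h
    fit <- lm(x[i + d] ~ d + I(d^2))
    expect_equal(lmp[1, k], unname(coef(fit)[1]), tolerance = 1e-6)
  }
})

test_that("feature set has seven z-scored tracks per channel", {
  sim <- small_sim()
  sf <- small_features()
  bp <- sf[[1]]$bp
  expect_equal(dim(bp$values)[2], 7)
  expect_equal(bp$features[7], "lmp")
  # z-scored bins: mean 0, SD 1 over the normalization epoch
  tb <- sf[[1]]$trials
  nw <- cbind(tb$cue_time_s - 3, tb$cue_time_s - 1)
  rec_b <- seeg_recording(
    sim$recording$samples, sim$recording$sampling_rate,
    sim$recording$channels)
  sp <- stft_power(rec_b, max_freq = 170)
  frames <- frames_in_windows(sp$frame_centers, nw)
  spz <- zscore_bins(sp, norm_frames = frames)
  m <- spz$power[3, , frames]
  mu <- rowMeans(m)
  sd1 <- sqrt(rowMeans((m - mu)^2))
  expect_lt(max(abs(mu), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(sd1 - 1), na.rm = TRUE), 1e-6)
})

test_that("task-averaged spectrogram averages event-locked epochs", {
  vals <- array(rnorm(1 * 5 * 100), c(1, 5, 100))
  sp <- structure(list(power = vals, bins_hz = 0:4,
                       frame_centers = (0:99) * 0.05, frame_step = 0.05,
                       fs = 100, channel_names = "a", zscored = TRUE),
                  class = "stft_power")
  one <- task_averaged_spectrogram(sp, 2.0, c(-0.2, 0.2))
  ep <- epoch_series(matrix(vals[1, , ], 5), sp$frame_centers, 2.0,
                     c(-0.2, 0.2))
  expect_equal(one$map[1, , ], ep[1, , ])
  # M and -M average to zero
  sp$power[1, , 57:64] <- -sp$power[1, , 37:44]
  two <- task_averaged_spectrogram(sp, c(2.0, 3.0), c(-0.2, 0.2))
  expect_equal(max(abs(two$map)), 0, tolerance = 1e-12)
  # clipping bounds the map
  three <- task_averaged_spectrogram(sp, 2.0, c(-0.2, 0.2), clip = 0.5)
  expect_lte(max(abs(three$map)), 0.5)
})

test_that("white noise has a flat PSD and 1/f noise the configured slope", {
  set.seed(8)
  fs <- 500
  # white noise: log-log slope of the Welch PSD near zero
  xw <- matrix(rnorm(fs * 60), 1)
  sp <- stft_power(xw, fs)
  psd <- rowMeans(sp$power[1, , ])
  sel <- which(!is.na(psd) & sp$bins_hz >= 1 & sp$bins_hz <= 100)
  fit <- lm(log10(psd[sel]) ~ log10(sp$bins_hz[sel] + 0.5))
  expect_lt(abs(coef(fit)[2]), 0.1)
})
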