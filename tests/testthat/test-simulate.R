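test_that("identical seeds give bit-identical sessions", {
  cfg <- sim_config(sampling_rate = 500, n_blocks = 1, seed = 33)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$force, b$force)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("band edges above Nyquist are rejected by name", {
  expect_error(sim_config(sampling_rate = 500,
                          modulation_spec = data.frame(
                            region = "MC", band = "gamma_high2",
                            depth = 1, latency_s = 0,
                            duration_s = NA_real_),
                          seed = 1) |> (\(cfg) {
                            cfg$sampling_rate <- 300
                            validate_sim_config(cfg)
                          })(),
               "Nyquist")
  expect_error(sim_config(sampling_rate = 300,
                          modulation_spec = default_modulation_spec()[0, ]),
               "sampling_rate")
})

test_that("force traces order by level and level 0 is noise only", {
  set.seed(1)
  f40 <- simulate_force_trace(40, 1, 6, t_end = 7, sensor_noise_sd = 0.2)
  f20 <- simulate_force_trace(20, 1, 6, t_end = 7, sensor_noise_sd = 0.2)
  plateau <- function(f) mean(f$force[f$time_s > 2.5 & f$time_s < 5.5])
  expect_gt(plateau(f40), plateau(f20))
  expect_gt(plateau(f20), 15)
  f0 <- simulate_force_trace(0, 1, 6, t_end = 7, sensor_noise_sd = 0.2)
  expect_lt(max(abs(f0$force)), 0.2 * 6)   # noise only
  expect_lt(abs(mean(f0$force)), 0.1)
})

test_that("background noise follows the configured 1/f slope", {
  cfg <- sim_config(sampling_rate = 500, n_blocks = 1, seed = 5,
                    modulation_spec = default_modulation_spec()[0, ],
                    noise_exponent = 1)
  sim <- simulate_recording(cfg)
  sp <- stft_power(matrix(sim$recording$samples[12, ], 1), 500)
  psd <- rowMeans(sp$power[1, , ])
  sel <- which(!is.na(psd) & sp$bins_hz >= 1 & sp$bins_hz <= 100)
  fit <- lm(log10(psd[sel]) ~ log10(sp$bins_hz[sel] + 0.5))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.3)
})

test_that("planted high-gamma ERS raises event-window power (sign test)", {
  sf <- recovery_features()
  sim <- recovery_sim()
  # pipeline's own features: gamma_high1 on an MC channel
  diffs <- c()
  for (b in seq_along(sf)) {
    bp <- sf[[b]]$bp
    tb <- sf[[b]]$trials
    ev <- epoch_bandpower(bp, tb$onset_time_s, c(-1, 0))
    ba <- epoch_bandpower(bp, tb$onset_time_s, c(-3, -1))
    ch <- which(bp$channels$region == "MC")[1]
    ft <- which(bp$features == "gamma_high1")
    diffs <- c(diffs, apply(ev[, ch, ft, ], 1, mean) -
                 apply(ba[, ch, ft, ], 1, mean))
  }
  expect_gte(length(diffs), 20)
  p <- binom.test(sum(diffs > 0), length(diffs), 0.5,
                  alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("doubling a planted depth doubles the measured change", {
  base_spec <- data.frame(region = "MC",
                          band = c("gamma_high1", "beta"),
                          depth = c(0.75, -0.3), latency_s = -1,
                          duration_s = NA_real_)
  meas <- function(mult, seed) {
    sp <- base_spec
    sp$depth <- sp$depth * mult
    cfg <- sim_config(sampling_rate = 500, n_blocks = 2, seed = seed,
                      modulation_spec = sp, depth_jitter = 0)
    sim <- simulate_recording(cfg)
    sf <- suppressWarnings(session_features(sim, norm = "baseline",
                                            car = FALSE))
    mod <- session_modulation(sf)
    sapply(split(mod$depth_norm[mod$region == "MC" &
                                  mod$band %in% sp$band],
                 mod$band[mod$region == "MC" & mod$band %in% sp$band]),
           mean)
  }
  m1 <- meas(1, 91)
  m2 <- meas(2, 91)
  for (bnd in c("gamma_high1", "beta")) {
    ratio <- m2[[bnd]] / m1[[bnd]]
    expect_gt(ratio, 1.5)
    expect_lt(ratio, 2.5)
  }
})

test_that("ground truth mirrors the modulation spec with correct signs", {
  sim <- small_sim()
  gt <- sim$ground_truth$modulation
  spec <- default_modulation_spec()
  expect_setequal(unique(paste(gt$region, gt$band)),
                  paste(spec$region, spec$band))
  sg <- sign(spec$depth[match(paste(gt$region, gt$band),
                              paste(spec$region, spec$band))])
  expect_true(all(sign(gt$planted_depth) == sg))
  expect_true(all(sign(gt$realized_depth) == sg))
  # one entry per (trial, planted channel x band)
  n_mc <- sum(sim$recording$channels$region == "MC")
  n_ic <- sum(sim$recording$channels$region == "IC")
  expect_equal(nrow(gt),
               nrow(sim$trials) * (4 * n_mc + 1 * n_ic))
})

test_that("imagined trials scale planted depth by imagined_scale", {
  cfg <- sim_config(sampling_rate = 500, n_blocks = 1,
                    imagined_blocks = 1, imagined_scale = 0.5, seed = 44)
  sim <- simulate_recording(cfg)
  gt <- sim$ground_truth$modulation
  ex_ids <- sim$trials$trial_id[sim$trials$executed]
  im_ids <- sim$trials$trial_id[!sim$trials$executed]
  r_ex <- mean(abs(gt$planted_depth[gt$trial_id %in% ex_ids]))
  r_im <- mean(abs(gt$planted_depth[gt$trial_id %in% im_ids]))
  expect_equal(r_im / r_ex, 0.5, tolerance = 0.1)
  # imagined trials have no force output
  im <- sim$trials[!sim$trials$executed, ]
  sel <- sim$force$time_s >= min(im$cue_time_s) &
    sim$force$time_s <= max(im$offset_time_s)
  expect_lt(max(abs(sim$force$force[sel])),
            6 * cfg$sensor_noise_sd)
})

test_that("region noise floors suppress high-frequency planted modulation", {
  spec <- data.frame(region = c("IC", "IC"),
                     band = c("alpha", "gamma_high1"),
                     depth = c(-0.5, 1), latency_s = -1,
                     duration_s = NA_real_)
  cfg <- sim_config(sampling_rate = 500, n_blocks = 1, seed = 55,
                    modulation_spec = spec)
  sim <- simulate_recording(cfg)
  gt <- sim$ground_truth$modulation
  # gamma_high1 starts at 70 Hz >= the 50 Hz IC floor: dropped
  expect_false("gamma_high1" %in% gt$band[gt$region == "IC"])
  expect_true("alpha" %in% gt$band[gt$region == "IC"])
})
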