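#' Default channel layout for simulated SEEG
#'
#' Three depth-electrode shafts with four contacts each: a motor shaft
#' (motor cortex, premotor, white matter), a sensory shaft (primary sensory,
#' supplementary motor, white matter) and an insular shaft (insular cortex,
#' white matter).
#'
#' @return data.frame usable as the `channels` slot of a recording
#' @export
default_channel_table <- function() {
  data.frame(
    channel = c("A1", "A2", "A3", "A4",
                "B1", "B2", "B3", "B4",
                "C1", "C2", "C3", "C4"),
    shaft_id = rep(c("A", "B", "C"), each = 4),
    contact_index = rep(1:4, 3),
    region = c("MC", "MC", "PM", "PM",
               "S1", "S1", "SM", "SM",
               "IC", "IC", "WM", "WM"),
    noisy = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Default planted modulation structure
#'
#' Event-locked band-power changes placed on motor and insular channels:
#' beta and alpha desynchronization (ERD) plus broadband high-gamma
#' synchronization (ERS) on motor cortex, and a weaker alpha ERD in the
#' insula. Depths are in units of the baseline SD of the band-power track.
#' Latency is relative to force onset; modulation starts at the cue
#' (about 1 s before force onset, as motor preparation) and holds until
#' force offset (`duration_s = NA`).
#'
#' @return data.frame with columns `region`, `band`, `depth`, `latency_s`,
#'   `duration_s`
#' @export
default_modulation_spec <- function() {
  data.frame(
    region = c("MC", "MC", "MC", "MC", "IC"),
    band = c("beta", "gamma_high1", "gamma_high2", "alpha", "alpha"),
    depth = c(-1.5, 1.5, 1.0, -1.0, -0.8),
    latency_s = -1.0,
    duration_s = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Describes a grasp force-matching session: blocks of `5 s target / 5 s
#' rest` trials at 20/30/40 percent of maximum voluntary contraction (MVC),
#' five trials per level per block, recorded as multichannel 1/f noise with
#' band-limited carriers whose envelopes are scaled in event-locked windows
#' to plant event-related (de)synchronization of known depth.
#'
#' @param channels channel metadata table (see [default_channel_table()])
#' @param sampling_rate neural sampling rate, Hz
#' @param n_blocks number of executed blocks; grasp configurations from
#'   `grasps` are assigned cyclically
#' @param imagined_blocks number of imagined (no force output) blocks
#'   appended after the executed blocks
#' @param trials_per_level_per_block trials of each force level per block
#' @param force_levels force targets in percent MVC
#' @param target_duration,rest_duration seconds of target presentation and
#'   of rest between trials
#' @param grasps grasp configuration labels cycled over blocks
#' @param noise_exponent slope of the 1/f^a background noise
#' @param noise_floor_per_region named Hz cutoffs; planted modulation in
#'   bands starting at or above the cutoff is dropped for that region
#'   (emulates the region-dependent power cutoff seen on insular and
#'   white-matter contacts)
#' @param modulation_spec planted modulation table
#'   (see [default_modulation_spec()])
#' @param imagined_scale multiplier in `[0, 1]` applied to planted depths on
#'   imagined trials
#' @param depth_jitter per-trial relative jitter of the planted depth
#'   (uniform on `depth * (1 +/- depth_jitter)`)
#' @param carrier_snr variance of each band carrier relative to the
#'   background variance in that band
#' @param reaction_mean,reaction_jitter mean and half-range (s) of the
#'   cue-to-force-onset latency
#' @param ramp_s force rise time, seconds
#' @param force_rate force-sensor sampling rate, Hz (its own clock)
#' @param sensor_noise_sd force-sensor noise SD, percent MVC
#' @param line_60hz add a stationary 60 Hz mains sinusoid
#' @param offset_ers_burst add a second high-gamma burst at force offset
#' @param seed integer seed; identical seeds give bit-identical output
#' @return object of class `sim_config`
#' @export
sim_config <- function(channels = default_channel_table(),
                       sampling_rate = 2000,
                       n_blocks = 2,
                       imagined_blocks = 0,
                       trials_per_level_per_block = 5,
                       force_levels = c(20, 30, 40),
                       target_duration = 5,
                       rest_duration = 5,
                       grasps = c("pinch", "power"),
                       noise_exponent = 1,
                       noise_floor_per_region = c(IC = 50, WM = 50),
                       modulation_spec = default_modulation_spec(),
                       imagined_scale = 0.5,
                       depth_jitter = 0.15,
                       carrier_snr = 4,
                       reaction_mean = 1.0,
                       reaction_jitter = 0.15,
                       ramp_s = 0.5,
                       force_rate = 100,
                       sensor_noise_sd = 0.5,
                       line_60hz = FALSE,
                       offset_ers_burst = FALSE,
                       seed = 1) {
  cfg <- list(channels = channels, sampling_rate = sampling_rate,
              n_blocks = n_blocks, imagined_blocks = imagined_blocks,
              trials_per_level_per_block = trials_per_level_per_block,
              force_levels = force_levels,
              target_duration = target_duration,
              rest_duration = rest_duration, grasps = grasps,
              noise_exponent = noise_exponent,
              noise_floor_per_region = noise_floor_per_region,
              modulation_spec = modulation_spec,
              imagined_scale = imagined_scale, depth_jitter = depth_jitter,
              carrier_snr = carrier_snr, reaction_mean = reaction_mean,
              reaction_jitter = reaction_jitter, ramp_s = ramp_s,
              force_rate = force_rate, sensor_noise_sd = sensor_noise_sd,
              line_60hz = line_60hz, offset_ers_burst = offset_ers_burst,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bands <- default_bands()
  ms <- cfg$modulation_spec
  if (nrow(ms) > 0) {
    unknown <- setdiff(ms$band, bands$name)
    if (length(unknown))
      stop("unknown band(s) in modulation_spec: ",
           paste(unknown, collapse = ", "))
    hi <- bands$hi[match(ms$band, bands$name)]
    bad <- hi > cfg$sampling_rate / 2
    if (any(bad))
      stop("band edge above Nyquist (", cfg$sampling_rate / 2, " Hz) for: ",
           paste(unique(ms$band[bad]), collapse = ", "))
    stopifnot(all(is.finite(ms$depth)))
  }
  if (cfg$sampling_rate <= 2 * 170)
    stop("sampling_rate must exceed twice the highest band edge (170 Hz)")
  stopifnot(cfg$target_duration > 0, cfg$rest_duration > 0,
            cfg$imagined_scale >= 0, cfg$imagined_scale <= 1,
            cfg$n_blocks + cfg$imagined_blocks >= 1,
            all(cfg$force_levels > 0))
  invisible(cfg)
}

# 1/f^a Gaussian noise via FFT amplitude shaping, normalized to SD 1
pink_noise <- function(n, exponent, fs) {
  x <- stats::rnorm(n)
  if (exponent == 0) return(x)
  X <- stats::fft(x)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n          # symmetric frequency axis
  amp <- c(0, f[-1]^(-exponent / 2))    # zero out DC
  y <- Re(stats::fft(X * amp, inverse = TRUE)) / n
  y / stats::sd(y)
}

band_filter <- function(lo, hi, fs) {
  nyq <- fs / 2
  if (lo <= 0) signal::butter(4, hi / nyq, type = "low")
  else signal::butter(4, c(lo, hi) / nyq, type = "pass")
}

# per-frame power in each 1 Hz interval of [lo, hi) (same Hann/STFT/floor
# binning as the analysis path) at the given 0-based frame starts
band_bin_tracks <- function(x, fs, lo, hi, starts, win_samp) {
  idx <- outer(seq_len(win_samp), starts, "+")
  w <- hann_window(win_samp)
  seg <- matrix(x[idx], nrow = win_samp) * w
  S <- stats::mvfft(seg)
  freqs <- (seq_len(win_samp) - 1) * fs / win_samp
  keep <- which(freqs >= lo & freqs < hi & freqs <= fs / 2)
  P <- Mod(S[keep, , drop = FALSE])^2 / win_samp
  rowsum(P, floor(freqs[keep]))
}

# sum over the band (used for spectral-content checks)
band_power_track <- function(x, fs, lo, hi, starts, win_samp) {
  colSums(band_bin_tracks(x, fs, lo, hi, starts, win_samp))
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

raised_cosine <- function(u) 0.5 * (1 - cos(pi * pmin(pmax(u, 0), 1)))

# multiplicative envelope: 1 outside [t_on, t_off], plateau `gain` inside,
# 100 ms raised-cosine ramps at the edges
apply_envelope <- function(env, t, t_on, t_off, gain, ramp = 0.1) {
  sel <- which(t >= t_on & t < t_off + ramp)
  if (!length(sel)) return(env)
  ts <- t[sel]
  up <- raised_cosine((ts - t_on) / ramp)
  down <- 1 - raised_cosine((ts - t_off) / ramp)
  shape <- pmin(up, down)
  env[sel] <- env[sel] * (1 + (gain - 1) * shape)
  env
}

#' Simulate a force-sensor trace for one trial
#'
#' Trapezoid-plus-jitter profile: raised-cosine rise over `ramp_s` to the
#' target with a transient overshoot that settles, a hold until force
#' offset, and a release back to zero; zero plus sensor noise elsewhere.
#'
#' @param level target force in percent MVC (0 gives a noise-only trace)
#' @param onset_time,offset_time force onset and offset, seconds
#' @param t_start,t_end trace extent, seconds
#' @param fs sensor sampling rate, Hz
#' @param ramp_s rise time, seconds
#' @param sensor_noise_sd sensor noise SD, percent MVC
#' @param overshoot relative overshoot of the initial rise
#' @return data.frame with columns `time_s`, `force` (percent MVC)
#' @export
simulate_force_trace <- function(level, onset_time, offset_time,
                                 t_start = 0, t_end = offset_time + 2,
                                 fs = 100, ramp_s = 0.5,
                                 sensor_noise_sd = 0.5, overshoot = 0.08) {
  t <- seq(t_start, t_end, by = 1 / fs)
  f <- numeric(length(t))
  if (level > 0) {
    peak <- level * (1 + overshoot)
    rise <- t >= onset_time & t < onset_time + ramp_s
    f[rise] <- peak * (t[rise] - onset_time) / ramp_s
    hold <- t >= onset_time + ramp_s & t < offset_time
    f[hold] <- level +
      (peak - level) * exp(-(t[hold] - onset_time - ramp_s) / 0.4)
    rel <- t >= offset_time & t < offset_time + 0.3
    if (any(rel)) {
      end_val <- if (any(hold)) f[max(which(hold))] else peak
      f[rel] <- end_val * (1 - raised_cosine((t[rel] - offset_time) / 0.3))
    }
  }
  f <- f + stats::rnorm(length(t), sd = sensor_noise_sd)
  data.frame(time_s = t, force = f)
}

build_trial_table <- function(cfg) {
  n_levels <- length(cfg$force_levels)
  tpb <- cfg$trials_per_level_per_block * n_levels
  cycle <- cfg$target_duration + cfg$rest_duration
  block_dur <- cfg$rest_duration + tpb * cycle   # lead-in rest, then trials
  total_blocks <- cfg$n_blocks + cfg$imagined_blocks
  trials <- NULL
  blocks <- data.frame(block = seq_len(total_blocks),
                       grasp = rep_len(cfg$grasps, total_blocks),
                       executed = rep(c(TRUE, FALSE),
                                      c(cfg$n_blocks, cfg$imagined_blocks)),
                       start_s = (seq_len(total_blocks) - 1) * block_dur,
                       end_s = seq_len(total_blocks) * block_dur)
  for (b in seq_len(total_blocks)) {
    levels_b <- sample(rep(cfg$force_levels, cfg$trials_per_level_per_block))
    cue <- blocks$start_s[b] + cfg$rest_duration +
      (seq_len(tpb) - 1) * cycle
    executed <- blocks$executed[b]
    latency <- cfg$reaction_mean +
      stats::runif(tpb, -cfg$reaction_jitter, cfg$reaction_jitter)
    trials <- rbind(trials, data.frame(
      block = b, grasp = blocks$grasp[b], level_pct_mvc = levels_b,
      cue_time_s = cue,
      onset_time_s = if (executed) cue + latency else NA_real_,
      offset_time_s = cue + cfg$target_duration,
      executed = executed))
  }
  trials$trial_id <- seq_len(nrow(trials))
  trials <- trials[c("trial_id", "block", "grasp", "level_pct_mvc",
                     "cue_time_s", "onset_time_s", "offset_time_s",
                     "executed")]
  list(trials = trials, blocks = blocks,
       total_duration = blocks$end_s[total_blocks])
}

#' Simulate an SEEG grasp-force session
#'
#' Generates a continuous multichannel recording (1/f background noise plus
#' band-limited noise carriers), a trial/event table, a force-sensor trace
#' on its own clock, and a ground-truth record of the modulation actually
#' planted. Modulation is multiplicative envelope scaling of a band-passed
#' noise carrier, so band power moves without introducing line spectra. The
#' envelope gain for a requested depth `d` (in baseline-SD units of the
#' band-power track) is calibrated per channel and band against the
#' simulated baseline: `gain = sqrt(1 + d * SD_baseline / P_carrier)`.
#'
#' @param config a [sim_config()]
#' @return object of class `seeg_sim`: list with `recording`
#'   ([seeg_recording]), `trials`, `blocks`, `force` (data.frame `time_s`,
#'   `force`), `ground_truth` (list `onsets`, `modulation`), `config`
#' @export
simulate_recording <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  fs <- config$sampling_rate
  layout <- build_trial_table(config)
  trials <- layout$trials
  n_samp <- round(layout$total_duration * fs)
  chans <- config$channels
  n_ch <- nrow(chans)

  # --- force trace on its own 100 Hz (default) clock -----------------------
  tf <- seq(0, layout$total_duration, by = 1 / config$force_rate)
  force <- stats::rnorm(length(tf), sd = config$sensor_noise_sd)
  for (i in which(trials$executed)) {
    tr <- trials[i, ]
    peak_over <- max(0, stats::rnorm(1, 0.08, 0.03))
    prof <- simulate_force_trace(tr$level_pct_mvc, tr$onset_time_s,
                                 tr$offset_time_s,
                                 t_start = tr$cue_time_s,
                                 t_end = tr$offset_time_s + 0.5,
                                 fs = config$force_rate,
                                 sensor_noise_sd = 0,
                                 overshoot = peak_over)
    sel <- which(tf >= tr$cue_time_s - 1e-9 &
                   tf <= tr$offset_time_s + 0.5 + 1e-9)
    n <- min(length(sel), nrow(prof))
    force[sel[seq_len(n)]] <- force[sel[seq_len(n)]] + prof$force[seq_len(n)]
  }

  # --- modulation windows per trial ---------------------------------------
  # imagined trials have no force onset; modulation is centred on the cue
  # plus the configured mean reaction latency, scaled by imagined_scale
  ref_onset <- ifelse(trials$executed, trials$onset_time_s,
                      trials$cue_time_s + config$reaction_mean)
  ref_offset <- trials$offset_time_s

  # --- per-channel signals -------------------------------------------------
  bands <- default_bands()
  ms <- config$modulation_spec
  samples <- matrix(0, n_ch, n_samp)
  t_neural <- (seq_len(n_samp) - 1) / fs
  gt_mod <- NULL
  win_samp <- round(0.512 * fs)

  # calibration frames: rest periods away from any modulation window
  grid <- frame_grid(n_samp, fs, 0.512, 0.050)
  in_mod <- rep(FALSE, length(grid$centers))
  for (i in seq_len(nrow(trials))) {
    in_mod <- in_mod | (grid$centers > ref_onset[i] - 2 &
                          grid$centers < ref_offset[i] + 1)
  }
  calib_starts <- grid$starts[!in_mod]
  if (length(calib_starts) > 300)
    calib_starts <- calib_starts[round(seq(1, length(calib_starts),
                                           length.out = 300))]

  for (ch in seq_len(n_ch)) {
    bg <- pink_noise(n_samp, config$noise_exponent, fs)
    sig <- bg
    reg <- chans$region[ch]
    floor_hz <- config$noise_floor_per_region[reg]
    spec_ch <- ms[ms$region == reg, , drop = FALSE]
    if (nrow(spec_ch) && !is.na(floor_hz)) {
      lo_band <- bands$lo[match(spec_ch$band, bands$name)]
      spec_ch <- spec_ch[lo_band < floor_hz, , drop = FALSE]
    }
    for (j in seq_len(nrow(spec_ch))) {
      sp <- spec_ch[j, ]
      bd <- bands[bands$name == sp$band, ]
      filt <- band_filter(bd$lo, bd$hi, fs)
      bg_band_sd <- stats::sd(signal::filtfilt(filt, bg))
      car <- signal::filtfilt(filt, stats::rnorm(n_samp))
      car <- car / stats::sd(car) * sqrt(config$carrier_snr) * bg_band_sd
      # calibrate in the analysis pipeline's own units: the band feature
      # is the mean of per-1 Hz-bin z-scores, so express the planted power
      # change through each bin's baseline mean/SD
      base_bins <- band_bin_tracks(bg + car, fs, bd$lo, bd$hi,
                                   calib_starts, win_samp)
      car_bins <- rowMeans(band_bin_tracks(car, fs, bd$lo, bd$hi,
                                           calib_starts, win_samp))
      mu_bin <- rowMeans(base_bins)
      sd_bin <- apply(base_bins, 1, stats::sd)
      feat_track <- colMeans((base_bins - mu_bin) / sd_bin)
      s_feat <- stats::sd(feat_track)
      gain_per_unit <- mean(car_bins / sd_bin)  # d(feature)/d(g^2 - 1)
      env <- rep(1, n_samp)
      for (i in seq_len(nrow(trials))) {
        d <- sp$depth *
          (1 + config$depth_jitter * stats::runif(1, -1, 1))
        if (!trials$executed[i]) d <- d * config$imagined_scale
        t_on <- ref_onset[i] + sp$latency_s
        t_off <- if (is.na(sp$duration_s)) ref_offset[i] else
          min(t_on + sp$duration_s, ref_offset[i])
        g2 <- max(0, 1 + d * s_feat / gain_per_unit)
        realized <- (g2 - 1) * gain_per_unit / s_feat
        env <- apply_envelope(env, t_neural, t_on, t_off, sqrt(g2))
        if (config$offset_ers_burst && sp$depth > 0) {
          env <- apply_envelope(env, t_neural, t_off + 0.1, t_off + 0.5,
                                sqrt(g2))
        }
        gt_mod <- rbind(gt_mod, data.frame(
          trial_id = trials$trial_id[i], channel = chans$channel[ch],
          region = reg, band = sp$band, planted_depth = d,
          realized_depth = realized, gain = sqrt(g2)))
      }
      sig <- sig + car * env
    }
    if (config$line_60hz) sig <- sig + 0.5 * sin(2 * pi * 60 * t_neural)
    samples[ch, ] <- sig
  }

  rec <- seeg_recording(samples, fs, chans)
  gt <- list(onsets = data.frame(trial_id = trials$trial_id,
                                 onset_time_s = trials$onset_time_s),
             modulation = gt_mod %||% data.frame())
  structure(list(recording = rec, trials = trials, blocks = layout$blocks,
                 force = data.frame(time_s = tf, force = force),
                 ground_truth = gt, config = config),
            class = "seeg_sim")
}

#' @export
print.seeg_sim <- function(x, ...) {
  cat(sprintf("<seeg_sim> %d trials in %d block(s), %d channels, %.0f s\n",
              nrow(x$trials), nrow(x$blocks), nrow(x$recording$samples),
              ncol(x$recording$samples) / x$recording$sampling_rate))
  if (nrow(x$ground_truth$modulation) > 0) {
    m <- unique(x$ground_truth$modulation[c("region", "band")])
    cat("  planted modulation:",
        paste(m$region, m$band, sep = ":", collapse = ", "), "\n")
  } else cat("  no planted modulation\n")
  invisible(x)
}
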