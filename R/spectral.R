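#' Short-time Fourier band power in 1 Hz bins
#'
#' Slides a Hann-tapered window of `win` seconds (default 512 ms) in steps
#' of `step` seconds (default 50 ms) and computes the magnitude-squared
#' spectrum per frame. FFT bins are pooled into 1 Hz intervals `[b, b+1)` by
#' the interval containing each bin's centre frequency; at 512 ms the native
#' resolution is ~2 Hz, so some 1 Hz intervals are empty (all-`NA`) and are
#' skipped downstream. Set `zero_pad = TRUE` to pad each frame to one
#' second of samples, which makes every 1 Hz interval exactly one FFT bin.
#' Frame timestamps are window centres.
#'
#' @param x a [seeg_recording] or a channels x time numeric matrix
#' @param fs sampling rate in Hz (taken from the recording if omitted)
#' @param win,step window length and frame step, seconds
#' @param zero_pad pad frames to 1 s for true 1 Hz resolution
#' @param max_freq keep only 1 Hz intervals below this frequency (Hz);
#'   default keeps everything up to Nyquist
#' @return object of class `stft_power`: list with `power` (channels x
#'   1 Hz bins x frames; empty intervals `NA`), `bins_hz` (interval lower
#'   edges), `frame_centers`, `frame_step`, `fs`, `channel_names`
#' @export
stft_power <- function(x, fs = NULL, win = 0.512, step = 0.050,
                       zero_pad = FALSE, max_freq = NULL) {
  if (inherits(x, "seeg_recording")) {
    fs <- x$sampling_rate
    x <- x$samples
  }
  x <- as.matrix(x)
  stopifnot(!is.null(fs), fs > 0)
  grid <- frame_grid(ncol(x), fs, win, step)
  n_fft <- if (zero_pad) max(grid$win, as.integer(ceiling(fs))) else grid$win
  w <- hann_window(grid$win)
  freqs <- (seq_len(n_fft) - 1) * fs / n_fft
  nb <- as.integer(floor(fs / 2))
  keep <- which(freqs <= fs / 2 & floor(freqs) < nb)
  bin_of <- as.integer(floor(freqs[keep]))
  n_ch <- nrow(x)
  n_fr <- length(grid$starts)
  idx <- outer(seq_len(grid$win), grid$starts, "+")
  power <- array(NA_real_, c(n_ch, nb, n_fr))
  for (ch in seq_len(n_ch)) {
    seg <- matrix(x[ch, ][idx], nrow = grid$win) * w
    if (n_fft > grid$win)
      seg <- rbind(seg, matrix(0, n_fft - grid$win, n_fr))
    S <- stats::mvfft(seg)
    P <- Mod(S[keep, , drop = FALSE])^2 / n_fft
    agg <- rowsum(P, bin_of)               # sums power within each interval
    power[ch, as.integer(rownames(agg)) + 1L, ] <- agg
  }
  if (!is.null(max_freq)) {
    sel <- 0:(nb - 1) < max_freq
    power <- power[, sel, , drop = FALSE]
    nb <- sum(sel)
  }
  structure(list(power = power, bins_hz = 0:(nb - 1),
                 frame_centers = grid$centers, frame_step = grid$step_s,
                 fs = fs, channel_names = rownames(x),
                 zscored = FALSE),
            class = "stft_power")
}

#' Z-score each 1 Hz power bin over a normalization epoch
#'
#' Per channel and 1 Hz bin, converts power to `(x - mean) / SD` with the
#' mean and population SD computed over `norm_frames` (default: every
#' frame, i.e. the whole block). Bins with zero variance produce an
#' all-zero track with a warning. With `log_power = TRUE` power is
#' log-transformed first (zero power becomes `NA`), the convention used for
#' reporting task-averaged spectrograms.
#'
#' @param sp an [stft_power()] result
#' @param norm_frames integer frame indices of the normalization epoch
#' @param log_power log-transform power before z-scoring
#' @return an `stft_power` object with z-scored `power`
#' @export
zscore_bins <- function(sp, norm_frames = NULL, log_power = FALSE) {
  stopifnot(inherits(sp, "stft_power"))
  n_fr <- dim(sp$power)[3]
  norm_frames <- norm_frames %||% seq_len(n_fr)
  if (length(norm_frames) < 2)
    stop("normalization epoch must contain at least 2 frames")
  pw <- sp$power
  if (log_power) {
    pw <- log(pw)
    pw[!is.finite(pw)] <- NA_real_
  }
  n_zero <- 0L
  for (ch in seq_len(dim(pw)[1])) {
    m <- pw[ch, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    mu <- rowMeans(m[, norm_frames, drop = FALSE])
    s <- sqrt(rowMeans((m[, norm_frames, drop = FALSE] - mu)^2))
    z <- (m - mu) / s
    flat <- which(s == 0 & !is.na(s))
    if (length(flat)) {
      z[flat, ] <- 0
      n_zero <- n_zero + length(flat)
    }
    pw[ch, , ] <- z
  }
  if (n_zero > 0)
    warning(n_zero, " channel x bin track(s) had zero variance; ",
            "z-scores set to 0")
  sp$power <- pw
  sp$zscored <- TRUE
  sp
}

#' Average z-scored 1 Hz bins into band features
#'
#' Each band feature is the unweighted mean of the member 1 Hz-bin z-scores
#' (bins whose lower edge falls in `[lo, hi)`); empty 1 Hz intervals are
#' excluded from the mean. A band covered by no populated bin is an error.
#'
#' @param sp a z-scored [stft_power()] result
#' @param bands band definition table (see [default_bands()])
#' @param channels optional channel metadata data.frame carried through
#' @return object of class `band_power`: `values` (channels x bands x
#'   frames), `features`, `frame_centers`, `frame_step`, `channels`
#' @export
aggregate_bands <- function(sp, bands = default_bands(), channels = NULL) {
  stopifnot(inherits(sp, "stft_power"))
  n_ch <- dim(sp$power)[1]
  n_fr <- dim(sp$power)[3]
  vals <- array(NA_real_, c(n_ch, nrow(bands), n_fr))
  for (b in seq_len(nrow(bands))) {
    member <- which(sp$bins_hz >= bands$lo[b] & sp$bins_hz < bands$hi[b])
    member <- member[!is.na(sp$power[1, member, 1])]
    if (length(member) == 0)
      stop("band ", bands$name[b], " [", bands$lo[b], ", ", bands$hi[b],
           ") Hz is covered by no populated 1 Hz bin")
    for (ch in seq_len(n_ch)) {
      vals[ch, b, ] <- colMeans(
        matrix(sp$power[ch, member, ], nrow = length(member)))
    }
  }
  structure(list(values = vals, features = bands$name,
                 frame_centers = sp$frame_centers,
                 frame_step = sp$frame_step,
                 channels = channels,
                 channel_names = sp$channel_names),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("<band_power> %d channels x %d features x %d frames (%g s step)\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              x$frame_step))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Local motor potential (LMP)
#'
#' The low-frequency time-domain feature: the raw trace smoothed with a
#' 2nd-order Savitzky-Golay filter over a 250 ms window, sampled at the
#' 50 ms frame centres so it shares the band features' time base, and
#' (optionally) z-scored like the band powers.
#'
#' @param rec a [seeg_recording] or channels x time matrix
#' @param fs sampling rate, Hz (from the recording if omitted)
#' @param frame_centers frame centre times in seconds
#' @param win smoothing window, seconds (rounded to an odd sample count)
#' @param order polynomial order of the filter
#' @param zscore z-score over the normalization epoch
#' @param norm_frames frame indices of the normalization epoch
#' @return channels x frames matrix
#' @export
compute_lmp <- function(rec, frame_centers, fs = NULL, win = 0.250,
                        order = 2, zscore = TRUE, norm_frames = NULL) {
  if (inherits(rec, "seeg_recording")) {
    fs <- rec$sampling_rate
    rec <- rec$samples
  }
  x <- as.matrix(rec)
  n <- round(win * fs)
  if (n %% 2 == 0) n <- n + 1
  if (n > ncol(x)) stop("smoothing window longer than the recording")
  samp_idx <- pmin(pmax(round(frame_centers * fs) + 1, 1), ncol(x))
  out <- matrix(NA_real_, nrow(x), length(frame_centers))
  for (ch in seq_len(nrow(x))) {
    sm <- signal::sgolayfilt(x[ch, ], p = order, n = n)
    out[ch, ] <- sm[samp_idx]
  }
  if (zscore) {
    norm_frames <- norm_frames %||% seq_len(ncol(out))
    mu <- rowMeans(out[, norm_frames, drop = FALSE])
    s <- apply(out[, norm_frames, drop = FALSE], 1, pop_sd)
    s[s == 0] <- 1
    out <- (out - mu) / s
  }
  rownames(out) <- rownames(x)
  out
}

#' Full per-channel feature set: six band powers plus LMP
#'
#' Runs the STFT, z-scores each 1 Hz bin over the normalization epoch,
#' averages bins into the six canonical bands, and appends the z-scored
#' LMP as a seventh feature, giving 7 features per channel on a common
#' 50 ms frame grid.
#'
#' @param rec a (typically re-referenced) [seeg_recording]
#' @param bands band definitions
#' @param win,step STFT window and step, seconds
#' @param zero_pad see [stft_power()]
#' @param norm_windows optional matrix of `[t0, t1)` second windows defining
#'   the normalization epoch (e.g. rest periods); default is the whole
#'   recording
#' @param include_lmp append the LMP feature
#' @param lmp_win LMP smoothing window, seconds
#' @param log_power log-transform power before z-scoring
#' @return a `band_power` object with `length(bands$name) + include_lmp`
#'   features per channel
#' @export
band_power_features <- function(rec, bands = default_bands(),
                                win = 0.512, step = 0.050,
                                zero_pad = FALSE, norm_windows = NULL,
                                include_lmp = TRUE, lmp_win = 0.250,
                                log_power = FALSE) {
  stopifnot(inherits(rec, "seeg_recording"))
  sp <- stft_power(rec, win = win, step = step, zero_pad = zero_pad,
                   max_freq = max(bands$hi))
  norm_frames <- if (is.null(norm_windows)) NULL else
    frames_in_windows(sp$frame_centers, norm_windows)
  if (!is.null(norm_frames) && length(norm_frames) < 2)
    stop("normalization windows contain fewer than 2 frames")
  spz <- zscore_bins(sp, norm_frames = norm_frames, log_power = log_power)
  bp <- aggregate_bands(spz, bands, channels = rec$channels)
  if (include_lmp) {
    lmp <- compute_lmp(rec, sp$frame_centers, win = lmp_win,
                       zscore = TRUE, norm_frames = norm_frames)
    vals <- array(NA_real_, dim(bp$values) + c(0, 1, 0))
    vals[, seq_len(dim(bp$values)[2]), ] <- bp$values
    vals[, dim(vals)[2], ] <- lmp
    bp$values <- vals
    bp$features <- c(bp$features, "lmp")
  }
  bp
}

#' Epoch a band-power series around events
#'
#' @param bp a `band_power` object
#' @param events event times, seconds
#' @param window `[t0, t1)` seconds relative to each event
#' @return array trials x channels x features x frames with attributes
#'   `kept` and `rel_times`
#' @export
epoch_bandpower <- function(bp, events, window) {
  ef <- epoch_frames(bp$frame_centers, events, window)
  nt <- length(ef$kept)
  nf <- ncol(ef$index)
  d <- dim(bp$values)
  out <- array(NA_real_, c(nt, d[1], d[2], nf))
  for (i in seq_len(nt))
    out[i, , , ] <- bp$values[, , ef$index[i, ], drop = FALSE]
  attr(out, "kept") <- ef$kept
  attr(out, "rel_times") <- (round(window[1] / bp$frame_step) +
                               seq_len(nf) - 1) * bp$frame_step
  out
}

#' Task-averaged spectrogram
#'
#' Mean over trials of the event-locked z-scored 1 Hz spectrogram, the
#' report used to compare modulation time courses across brain regions.
#' Values can be clipped (conventionally at +/- 0.5) for display parity.
#'
#' @param sp a z-scored [stft_power()] result (use `log_power = TRUE` in
#'   [zscore_bins()] for the log-power convention)
#' @param events event times, seconds (e.g. force onsets)
#' @param window `[t0, t1)` seconds relative to each event
#' @param clip optional symmetric clipping bound
#' @return list with `map` (channels x bins x frames), `bins_hz`,
#'   `rel_times`, `n_trials`
#' @export
task_averaged_spectrogram <- function(sp, events, window, clip = NULL) {
  stopifnot(inherits(sp, "stft_power"))
  ef <- epoch_frames(sp$frame_centers, events, window)
  if (length(ef$kept) == 0) stop("no events with complete epochs")
  d <- dim(sp$power)
  nf <- ncol(ef$index)
  acc <- array(0, c(d[1], d[2], nf))
  for (i in seq_len(nrow(ef$index)))
    acc <- acc + sp$power[, , ef$index[i, ], drop = FALSE]
  map <- acc / nrow(ef$index)
  if (!is.null(clip)) map <- pmin(pmax(map, -abs(clip)), abs(clip))
  list(map = map, bins_hz = sp$bins_hz,
       rel_times = (round(window[1] / sp$frame_step) + seq_len(nf) - 1) *
         sp$frame_step,
       n_trials = nrow(ef$index))
}

#' Rest versus force power spectral density by channel
#'
#' Welch-style averaged periodograms: the raw PSD is the mean short-time
#' spectrum over all frames falling in the rest windows (1 s into each rest
#' period) or in the peri-onset force windows (-400 to +400 ms around force
#' onset), and the normalized change is the force-rest difference in units
#' of the rest-frame SD per bin.
#'
#' @param rec a (re-referenced) [seeg_recording]
#' @param trials trial table with detected onsets
#' @param force_window seconds around force onset
#' @param rest_window seconds after force offset defining the rest segment
#' @param win,step STFT window and step, seconds
#' @return list with `freq_hz`, `psd_rest`, `psd_force` (channels x bins)
#'   and `change_z`
#' @export
region_psd <- function(rec, trials, force_window = c(-0.4, 0.4),
                       rest_window = c(0.6, 1.4), win = 0.512,
                       step = 0.050) {
  sp <- stft_power(rec, win = win, step = step)
  ex <- trials[trials$executed & !is.na(trials$onset_time_s), ]
  if (nrow(ex) == 0) stop("no executed trials with onsets")
  fw <- cbind(ex$onset_time_s + force_window[1],
              ex$onset_time_s + force_window[2])
  rw <- cbind(ex$offset_time_s + rest_window[1],
              ex$offset_time_s + rest_window[2])
  f_frames <- frames_in_windows(sp$frame_centers, fw)
  r_frames <- frames_in_windows(sp$frame_centers, rw)
  if (length(f_frames) < 2 || length(r_frames) < 2)
    stop("too few frames in the rest or force windows")
  n_ch <- dim(sp$power)[1]
  psd_r <- psd_f <- chg <- matrix(NA_real_, n_ch, length(sp$bins_hz))
  for (ch in seq_len(n_ch)) {
    m <- matrix(sp$power[ch, , ], nrow = length(sp$bins_hz))
    mr <- rowMeans(m[, r_frames, drop = FALSE])
    sr <- apply(m[, r_frames, drop = FALSE], 1, stats::sd)
    mf <- rowMeans(m[, f_frames, drop = FALSE])
    psd_r[ch, ] <- mr
    psd_f[ch, ] <- mf
    chg[ch, ] <- (mf - mr) / ifelse(sr > 0, sr, NA_real_)
  }
  rownames(psd_r) <- rownames(psd_f) <- rownames(chg) <- sp$channel_names
  list(freq_hz = sp$bins_hz, psd_rest = psd_r, psd_force = psd_f,
       change_z = chg)
}
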