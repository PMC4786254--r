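#' Common average reference by shaft and region
#'
#' Subtracts, sample-wise, the mean of each channel group from every channel
#' in the group. Groups are contacts on the same electrode shaft passing
#' through the same anatomical region — the standard way to suppress shared
#' ambient noise on SEEG while keeping the reference local to the tissue the
#' contacts sample. Channels flagged noisy are excluded from the group
#' average but are themselves re-referenced. A group whose channels are all
#' noisy is passed through unreferenced with a warning.
#'
#' @param rec a [seeg_recording]
#' @return a re-referenced [seeg_recording] of the same shape
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "seeg_recording"))
  out <- rec$samples
  key <- paste(rec$channels$shaft_id, rec$channels$region, sep = "/")
  for (g in unique(key)) {
    rows <- which(key == g)
    good <- rows[!rec$channels$noisy[rows]]
    if (length(good) == 0) {
      warning("group ", g, " has no non-noisy channels; passed through ",
              "unreferenced")
      next
    }
    if (length(good) == 1 && length(rows) == 1)
      warning("group ", g, " has a single channel; self-referencing ",
              "zeroes it out")
    ref <- colMeans(rec$samples[good, , drop = FALSE])
    out[rows, ] <- sweep(rec$samples[rows, , drop = FALSE], 2, ref)
  }
  seeg_recording(out, rec$sampling_rate, rec$channels)
}

#' Detect force onset within a cue window
#'
#' Onset is the first time inside the cue window at which the force exceeds
#' 10 percent of the trial's target level and stays above that threshold for
#' at least 200 ms. The persistence requirement makes the rule robust to the
#' overshoot/undershoot jitter of real force matching.
#'
#' @param force data.frame with columns `time_s`, `force` (percent MVC)
#' @param level target force, percent MVC
#' @param window length-2 numeric, the cue window `[t0, t1)` in seconds
#' @param threshold_frac fraction of the target used as threshold
#' @param hold_s required persistence above threshold, seconds
#' @return onset time in seconds, or `NA` (with a warning) if no sustained
#'   crossing occurs
#' @export
detect_force_onset <- function(force, level, window,
                               threshold_frac = 0.1, hold_s = 0.2) {
  stopifnot(level > 0, length(window) == 2)
  sel <- force$time_s >= window[1] - 1e-9 & force$time_s < window[2] - 1e-9
  t <- force$time_s[sel]
  f <- force$force[sel]
  if (length(t) == 0) {
    warning("no force samples inside the cue window")
    return(NA_real_)
  }
  dt <- stats::median(diff(t))
  need <- max(1L, as.integer(ceiling(hold_s / dt)))
  above <- f > threshold_frac * level
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= need)
  if (length(ok) == 0) {
    warning("no sustained force onset detected in cue window")
    return(NA_real_)
  }
  t[starts[ok[1]]]
}

#' Detect onsets for every executed trial
#'
#' Applies [detect_force_onset()] over the trial table, searching each
#' trial's cue-to-offset window; detected onsets replace `onset_time_s`.
#' Executed trials with no detectable onset get `NA` and are counted in the
#' `n_undetected` attribute.
#'
#' @param trials trial table
#' @param force force trace data.frame (`time_s`, `force`)
#' @param target_duration target presentation length, seconds
#' @return trial table with detected `onset_time_s`
#' @export
detect_trial_onsets <- function(trials, force, target_duration = 5) {
  out <- trials
  n_miss <- 0L
  for (i in seq_len(nrow(trials))) {
    if (!trials$executed[i]) {
      out$onset_time_s[i] <- NA_real_
      next
    }
    on <- suppressWarnings(detect_force_onset(
      force, trials$level_pct_mvc[i],
      c(trials$cue_time_s[i], trials$cue_time_s[i] + target_duration)))
    if (is.na(on)) n_miss <- n_miss + 1L
    out$onset_time_s[i] <- on
  }
  if (n_miss > 0)
    warning(n_miss, " executed trial(s) had no detectable force onset")
  attr(out, "n_undetected") <- n_miss
  out
}

#' Assign surrogate onsets to imagined trials
#'
#' Imagined trials have no force output, so analysis windows are centred
#' using the mean cue-to-onset latency of the executed trials, computed per
#' grasp configuration (falling back to the overall mean for a grasp with no
#' executed trials).
#'
#' @param trials trial table with detected executed onsets
#' @return trial table with `onset_time_s` filled for imagined trials
#' @export
assign_imagined_onsets <- function(trials) {
  ex <- trials$executed & !is.na(trials$onset_time_s)
  if (!any(ex)) stop("no executed trials with onsets to estimate latency")
  lat <- trials$onset_time_s[ex] - trials$cue_time_s[ex]
  overall <- mean(lat)
  by_grasp <- tapply(lat, trials$grasp[ex], mean)
  out <- trials
  im <- which(!trials$executed)
  for (i in im) {
    g <- as.character(trials$grasp[i])
    l <- if (g %in% names(by_grasp)) by_grasp[[g]] else overall
    out$onset_time_s[i] <- trials$cue_time_s[i] + l
  }
  out
}
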