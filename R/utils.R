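`%||%` <- function(a, b) if (is.null(a)) b else a

# population SD (divisor n); band-power z-scores use the normalization
# epoch as the full population, not a sample from it
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Analysis frame grid for a signal
#'
#' Computes the frame start samples (0-based) and centre times for a sliding
#' window of `win_s` seconds advanced by `step_s` seconds.
#'
#' @param n_samples number of samples in the signal
#' @param fs sampling rate in Hz
#' @param win_s window length in seconds
#' @param step_s frame step in seconds
#' @return list with `win`, `step` (samples), `starts` (0-based sample
#'   offsets), `centers` (seconds) and `step_s`
#' @keywords internal
frame_grid <- function(n_samples, fs, win_s, step_s) {
  win <- round(win_s * fs)
  step <- round(step_s * fs)
  if (win < 2) stop("analysis window must span at least 2 samples")
  if (win > n_samples) stop("recording is shorter than one analysis window")
  starts <- seq(0L, n_samples - win, by = step)
  list(win = win, step = step, starts = starts,
       centers = (starts + win / 2) / fs, step_s = step / fs)
}

# index of the nearest grid point at or before t (0 if t precedes the grid);
# tolerance absorbs sub-nanosecond float error in second-valued event times
floor_index <- function(times, t) findInterval(t + 1e-9, times)

# indices of frames whose centre times fall in any half-open [t0, t1) window
frames_in_windows <- function(times, windows) {
  windows <- matrix(windows, ncol = 2)
  sel <- rep(FALSE, length(times))
  for (i in seq_len(nrow(windows))) {
    sel <- sel | (times >= windows[i, 1] - 1e-9 & times < windows[i, 2] - 1e-9)
  }
  which(sel)
}

#' Map events to frame-index windows
#'
#' Events are snapped to the nearest grid point at or before the event time;
#' the window `[t0, t1)` (seconds, relative to the event) is converted to a
#' fixed number of frames `round((t1 - t0) / step)` starting
#' `round(t0 / step)` frames from the event frame. Events whose window falls
#' outside the grid are dropped with a warning.
#'
#' @param times frame centre times (seconds), equally spaced
#' @param events event times in seconds
#' @param window length-2 numeric, `[t0, t1)` relative to each event
#' @return list: `index` (kept-events x frames matrix of frame indices),
#'   `kept` (indices into `events`), `n_dropped`
#' @export
epoch_frames <- function(times, events, window) {
  stopifnot(length(window) == 2, window[2] >= window[1])
  step <- stats::median(diff(times))
  nf <- as.integer(round((window[2] - window[1]) / step))
  ev <- floor_index(times, events)
  start <- ev + as.integer(round(window[1] / step))
  ok <- !is.na(events) & ev >= 1L & start >= 1L &
    (start + max(nf - 1L, 0L)) <= length(times)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warning(sprintf("%d event(s) dropped: epoch window outside recording",
                    n_dropped))
  }
  idx <- matrix(NA_integer_, nrow = sum(ok), ncol = nf)
  if (nf > 0 && any(ok)) {
    idx <- t(vapply(start[ok], function(s) seq.int(s, length.out = nf),
                    integer(nf)))
    if (nf == 1L) idx <- matrix(idx, ncol = 1L)
  }
  list(index = idx, kept = which(ok), n_dropped = n_dropped)
}

#' Epoch a multichannel series around events
#'
#' @param values channels x time matrix
#' @param times time of each column in seconds
#' @param events event times in seconds
#' @param window `[t0, t1)` in seconds relative to each event
#' @return array trials x channels x frames, with attributes `kept` and
#'   `rel_times`
#' @export
epoch_series <- function(values, times, events, window) {
  ef <- epoch_frames(times, events, window)
  nt <- length(ef$kept)
  nc <- nrow(values)
  nf <- ncol(ef$index)
  out <- array(NA_real_, c(nt, nc, nf))
  for (i in seq_len(nt)) out[i, , ] <- values[, ef$index[i, ], drop = FALSE]
  step <- stats::median(diff(times))
  attr(out, "kept") <- ef$kept
  attr(out, "rel_times") <- if (nf > 0)
    (round(window[1] / step) + seq_len(nf) - 1) * step else numeric(0)
  out
}

# canonical md5 of an R object for run manifests
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), f)
  unname(tools::md5sum(f))
}
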