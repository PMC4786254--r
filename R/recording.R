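#' SEEG recording container
#'
#' Bundles a channels x time voltage matrix with its sampling rate and
#' per-channel metadata (electrode shaft, contact index along the shaft,
#' anatomical region label, noisy flag). Depth-electrode (SEEG) shafts pass
#' through several structures, so region is a per-contact property.
#'
#' @param samples numeric matrix, channels x time
#' @param sampling_rate sampling rate in Hz
#' @param channels data.frame with columns `channel`, `shaft_id`,
#'   `contact_index`, `region`, `noisy`
#' @return object of class `seeg_recording`
#' @export
seeg_recording <- function(samples, sampling_rate, channels) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), sampling_rate > 0)
  req <- c("channel", "shaft_id", "contact_index", "region", "noisy")
  if (!all(req %in% names(channels)))
    stop("channels must have columns: ", paste(req, collapse = ", "))
  if (nrow(channels) != nrow(samples))
    stop("channel metadata rows (", nrow(channels),
         ") do not match signal channels (", nrow(samples), ")")
  key <- paste(channels$shaft_id, channels$contact_index)
  if (anyDuplicated(key))
    stop("(shaft_id, contact_index) pairs must be unique")
  rownames(samples) <- channels$channel
  structure(list(samples = samples,
                 sampling_rate = sampling_rate,
                 channels = as.data.frame(channels)),
            class = "seeg_recording")
}

#' @export
print.seeg_recording <- function(x, ...) {
  dur <- ncol(x$samples) / x$sampling_rate
  cat(sprintf("<seeg_recording> %d channels, %.1f s at %g Hz\n",
              nrow(x$samples), dur, x$sampling_rate))
  tab <- table(x$channels$region)
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  if (any(x$channels$noisy))
    cat("  noisy channels:",
        paste(x$channels$channel[x$channels$noisy], collapse = ", "), "\n")
  invisible(x)
}

#' Default frequency-band definitions
#'
#' The six band-power features: delta/theta 0-6 Hz, alpha 6-12 Hz,
#' beta 12-30 Hz, gamma 30-50 Hz, and two high-gamma bands 70-110 and
#' 130-170 Hz. The gaps at 50-70 and 110-130 Hz avoid 60 Hz mains noise and
#' its harmonics. Bands are half-open `[lo, hi)` over 1 Hz intervals.
#'
#' @return data.frame with columns `name`, `lo`, `hi` (Hz)
#' @export
default_bands <- function() {
  data.frame(
    name = c("delta_theta", "alpha", "beta", "gamma",
             "gamma_high1", "gamma_high2"),
    lo = c(0, 6, 12, 30, 70, 130),
    hi = c(6, 12, 30, 50, 110, 170),
    stringsAsFactors = FALSE
  )
}
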