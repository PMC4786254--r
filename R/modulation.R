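#' ERD/ERS modulation depth and significance per channel and band
#'
#' For each channel x feature, finds the frame of maximum absolute
#' deviation of the trial-averaged z-score from the baseline mean inside
#' the response window (-1 to 0 s before force onset by default), reads the
#' per-trial values at that frame, and compares them against per-trial
#' baseline means (-3 to -1 s before onset) with a Welch two-sample t-test.
#' Modulation depth is the mean response at the peak frame minus the mean
#' baseline, in z-score units; positive depth is event-related
#' synchronization (ERS), negative is desynchronization (ERD). Significance
#' uses the conservative threshold p < 0.002.
#'
#' Choosing the peak frame on the trial-averaged trace (rather than per
#' trial) avoids the selection bias that per-trial maxima would introduce
#' into the t statistic; set `peak_per_trial = TRUE` for the per-trial
#' variant. For imagined trials, which lack a force onset, use
#' `align = "cue"` with `response_window = c(0, 2)` (the first two seconds
#' after target presentation).
#'
#' @param bp a `band_power` object (see [band_power_features()]), or a
#'   list of them (one per recording block, with `trials` a matching list
#'   of block trial tables in block-relative time); trials are pooled
#'   across blocks before the t-test
#' @param trials trial table; rows with `NA` alignment times are dropped
#' @param response_window,baseline_window seconds relative to the alignment
#'   event
#' @param align align windows on `"onset"` (force onset) or `"cue"`
#' @param p_threshold significance threshold
#' @param peak_per_trial take each trial's own extreme frame instead of the
#'   group-peak frame
#' @return data.frame of class `modulation_result`: one row per channel x
#'   feature with `depth` (raw change in mean bin z-score), `depth_norm`
#'   (the same change expressed per pooled-baseline-frame SD of the band
#'   feature, the unit in which the synthetic generator plants depths;
#'   invariant to the choice of z-normalization epoch), `t_stat`,
#'   `p_value`, `significant`, `direction`, `peak_time_s`
#' @export
modulation_depth <- function(bp, trials,
                             response_window = c(-1, 0),
                             baseline_window = c(-3, -1),
                             align = c("onset", "cue"),
                             p_threshold = 0.002,
                             peak_per_trial = FALSE) {
  align <- match.arg(align)
  if (inherits(bp, "band_power")) {
    bp <- list(bp)
    trials <- list(trials)
  }
  resp_blocks <- base_blocks <- vector("list", length(bp))
  for (b in seq_along(bp)) {
    tb <- trials[[b]]
    events <- if (align == "onset") tb$onset_time_s else tb$cue_time_s
    events <- events[!is.na(events)]
    if (length(events) == 0) next
    r <- epoch_bandpower(bp[[b]], events, response_window)
    s <- epoch_bandpower(bp[[b]], events, baseline_window)
    keep <- intersect(attr(r, "kept"), attr(s, "kept"))
    resp_blocks[[b]] <- r[match(keep, attr(r, "kept")), , , ,
                          drop = FALSE]
    base_blocks[[b]] <- s[match(keep, attr(s, "kept")), , , ,
                          drop = FALSE]
    attr(resp_blocks[[b]], "rel_times") <- attr(r, "rel_times")
  }
  resp_blocks <- Filter(Negate(is.null), resp_blocks)
  base_blocks <- Filter(Negate(is.null), base_blocks)
  if (length(resp_blocks) == 0) stop("no trials with alignment times")
  rel_t <- attr(resp_blocks[[1]], "rel_times")
  stack1 <- function(lst) {
    d <- dim(lst[[1]])
    out <- array(NA_real_, c(sum(vapply(lst, function(a) dim(a)[1],
                                        integer(1))), d[2], d[3], d[4]))
    at <- 0
    for (a in lst) {
      if (dim(a)[1] > 0) out[at + seq_len(dim(a)[1]), , , ] <- a
      at <- at + dim(a)[1]
    }
    out
  }
  resp <- stack1(resp_blocks)
  base <- stack1(base_blocks)
  if (dim(resp)[4] < 2 || dim(base)[4] < 2)
    stop("response and baseline windows must each contain >= 2 frames")
  n_trials <- dim(resp)[1]
  if (n_trials < 2) stop("fewer than 2 trials with complete epochs")
  bp1 <- bp[[1]]

  n_ch <- dim(resp)[2]
  n_feat <- dim(resp)[3]
  out <- vector("list", n_ch * n_feat)
  k <- 0
  for (ch in seq_len(n_ch)) {
    for (ft in seq_len(n_feat)) {
      r <- matrix(resp[, ch, ft, ], nrow = n_trials)  # trials x frames
      b <- matrix(base[, ch, ft, ], nrow = n_trials)
      b_trial <- rowMeans(b)          # one baseline value per trial
      b_mean <- mean(b_trial)
      if (peak_per_trial) {
        r_trial <- r[cbind(seq_len(nrow(r)),
                           max.col(abs(r - b_mean), ties.method = "first"))]
        peak_t <- NA_real_
      } else {
        dev <- colMeans(r) - b_mean
        j <- which.max(abs(dev))
        r_trial <- r[, j]
        peak_t <- rel_t[j]
      }
      depth <- mean(r_trial) - b_mean
      sigma_b <- pop_sd(as.vector(b))   # pooled baseline-frame SD
      # essentially-constant groups break t.test(); perfectly separated
      # constant samples are infinitely significant, identical ones null
      tt <- tryCatch(stats::t.test(r_trial, b_trial),
                     error = function(e) {
                       if (isTRUE(all.equal(mean(r_trial), b_mean)))
                         list(statistic = 0, p.value = 1)
                       else
                         list(statistic = sign(mean(r_trial) - b_mean) * Inf,
                              p.value = 0)
                     })
      k <- k + 1
      out[[k]] <- data.frame(
        channel = bp1$channel_names[ch] %||% as.character(ch),
        region = if (!is.null(bp1$channels)) bp1$channels$region[ch]
                 else NA_character_,
        band = bp1$features[ft],
        depth = depth,
        depth_norm = if (sigma_b > 0) depth / sigma_b else NA_real_,
        peak_time_s = peak_t,
        t_stat = unname(tt$statistic),
        p_value = unname(tt$p.value),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$significant <- !is.na(res$p_value) & res$p_value < p_threshold
  res$direction <- ifelse(res$depth >= 0, "ERS", "ERD")
  attr(res, "n_trials") <- n_trials
  attr(res, "p_threshold") <- p_threshold
  class(res) <- c("modulation_result", "data.frame")
  res
}

#' @export
print.modulation_result <- function(x, ...) {
  sig <- sum(x$significant)
  cat(sprintf("<modulation_result> %d channel x band tests, %d trials\n",
              nrow(x), attr(x, "n_trials")))
  cat(sprintf("  significant at p < %g: %d\n", attr(x, "p_threshold"), sig))
  if (sig > 0) {
    s <- x[x$significant, ]
    s <- s[order(-abs(s$depth)), ]
    print.data.frame(utils::head(
      s[c("channel", "region", "band", "depth", "t_stat", "p_value",
          "direction")], 10), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Summarize modulation depth over significant channels
#'
#' Mean and SD of the absolute modulation depth across statistically
#' significant channels, grouped by region and band (the boxplot-style
#' summary reported per participant and grasp). Groups with no significant
#' channel are omitted rather than reported as zero.
#'
#' @param res a `modulation_result`
#' @param by grouping columns
#' @param sd_type `"sample"` (n-1 divisor, the default) or `"population"`
#' @param use_abs summarize `|depth|` (default) or signed depth
#' @return data.frame with `mean_depth`, `sd_depth`, `n_channels` per group
#' @export
modulation_summary <- function(res, by = c("region", "band"),
                               sd_type = c("sample", "population"),
                               use_abs = TRUE) {
  sd_type <- match.arg(sd_type)
  sig <- res[res$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(matrix(nrow = 0, ncol = length(by) + 3,
                             dimnames = list(NULL, c(by, "mean_depth",
                                                     "sd_depth",
                                                     "n_channels")))))
  }
  d <- if (use_abs) abs(sig$depth) else sig$depth
  key <- interaction(sig[by], drop = TRUE, sep = "\r")
  agg <- lapply(split(d, key), function(v) {
    s <- if (length(v) < 2) 0 else
      if (sd_type == "sample") stats::sd(v) else pop_sd(v)
    c(mean = mean(v), sd = s, n = length(v))
  })
  keys <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- by
  m <- do.call(rbind, agg)
  out$mean_depth <- m[, "mean"]
  out$sd_depth <- m[, "sd"]
  out$n_channels <- as.integer(m[, "n"])
  rownames(out) <- NULL
  out
}
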