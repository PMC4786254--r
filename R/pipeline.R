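#' Per-block band-power features for a whole session
#'
#' Slices the continuous recording into its blocks, applies the
#' shaft/region common average reference, extracts the seven features per
#' channel within each block, and returns block-relative trial tables
#' alongside. Working block-by-block keeps the z-score normalization epoch
#' within one block and bounds memory for long sessions.
#'
#' @param sim a `seeg_sim` (or any list with `recording`, `trials`,
#'   `blocks`)
#' @param norm `"block"` (z-score over the whole block) or `"baseline"`
#'   (z-score over the 3-to-1 s pre-cue rest windows, which expresses
#'   features in baseline-SD units)
#' @param zero_pad see [stft_power()]
#' @param include_lmp append the LMP feature
#' @param car apply the common average reference; disable when channels
#'   carry no shared noise (e.g. independent synthetic channels being
#'   compared against planted ground truth)
#' @return object of class `session_features`: list of per-block lists
#'   with `bp` (a `band_power`) and `trials` (block-relative times)
#' @export
session_features <- function(sim, norm = c("block", "baseline"),
                             zero_pad = FALSE, include_lmp = TRUE,
                             car = TRUE) {
  norm <- match.arg(norm)
  fs <- sim$recording$sampling_rate
  out <- vector("list", nrow(sim$blocks))
  for (b in seq_len(nrow(sim$blocks))) {
    blk <- sim$blocks[b, ]
    i0 <- round(blk$start_s * fs) + 1
    i1 <- min(round(blk$end_s * fs), ncol(sim$recording$samples))
    rec_b <- seeg_recording(sim$recording$samples[, i0:i1, drop = FALSE],
                            fs, sim$recording$channels)
    if (car) rec_b <- common_average_reference(rec_b)
    tb <- sim$trials[sim$trials$block == blk$block, , drop = FALSE]
    for (cl in c("cue_time_s", "onset_time_s", "offset_time_s"))
      tb[[cl]] <- tb[[cl]] - blk$start_s
    nw <- if (norm == "baseline")
      cbind(tb$cue_time_s - 3, tb$cue_time_s - 1) else NULL
    bp <- band_power_features(rec_b, zero_pad = zero_pad,
                              norm_windows = nw,
                              include_lmp = include_lmp)
    out[[b]] <- list(bp = bp, trials = tb, block = blk$block)
  }
  structure(out, class = "session_features")
}

#' @export
print.session_features <- function(x, ...) {
  cat(sprintf("<session_features> %d block(s)\n", length(x)))
  print(x[[1]]$bp)
  invisible(x)
}

#' Combine per-block feature matrices into one
#'
#' @param fms list of `feature_matrix` objects with identical columns
#' @return a single `feature_matrix`
#' @export
combine_feature_matrices <- function(fms) {
  stopifnot(length(fms) >= 1)
  cn <- colnames(fms[[1]]$x)
  for (f in fms) stopifnot(identical(colnames(f$x), cn))
  structure(list(x = do.call(rbind, lapply(fms, `[[`, "x")),
                 y = factor(unlist(lapply(fms, function(f)
                   as.character(f$y))), levels = levels(fms[[1]]$y)),
                 meta = do.call(rbind, lapply(fms, `[[`, "meta")),
                 feature_info = fms[[1]]$feature_info),
            class = "feature_matrix",
            n_excluded = sum(vapply(fms, function(f)
              attr(f, "n_excluded") %||% 0L, numeric(1))))
}

#' Session-level feature matrix
#'
#' Builds the trial x feature matrix over all blocks of the requested
#' trial type (see [build_feature_matrix()]).
#'
#' @param sf a [session_features()] result
#' @param states `"two"` or `"three"`
#' @param executed executed or imagined trials
#' @param ... passed to [build_feature_matrix()]
#' @return a `feature_matrix`
#' @export
session_feature_matrix <- function(sf, states = "two", executed = TRUE,
                                   ...) {
  blocks <- Filter(function(b) any(b$trials$executed == executed &
                                     !is.na(b$trials$onset_time_s)), sf)
  if (length(blocks) == 0) stop("no blocks with usable trials")
  combine_feature_matrices(lapply(blocks, function(b)
    build_feature_matrix(b$bp, b$trials, states = states,
                         executed = executed, ...)))
}

#' Session-level modulation statistics
#'
#' Pools trials over blocks and runs [modulation_depth()].
#'
#' @param sf a [session_features()] result
#' @param executed analyse executed (`TRUE`) or imagined (`FALSE`) trials;
#'   imagined trials use the cue-aligned 0-2 s response window preset
#' @param ... overrides passed to [modulation_depth()]
#' @return a `modulation_result`
#' @export
session_modulation <- function(sf, executed = TRUE, ...) {
  bps <- lapply(sf, `[[`, "bp")
  tabs <- lapply(sf, function(b)
    b$trials[b$trials$executed == executed, , drop = FALSE])
  if (executed) {
    modulation_depth(bps, tabs, ...)
  } else {
    modulation_depth(bps, tabs, response_window = c(0, 2),
                     align = "cue", ...)
  }
}

#' Run the full force-decoding pipeline on a session
#'
#' Detects force onsets from the force trace, assigns surrogate onsets to
#' imagined trials, extracts per-block features, computes ERD/ERS
#' modulation statistics and their region x band summary, classifies force
#' versus rest (and rest/light/hard) with the nested-CV SVM, tests
#' accuracies against chance with exact binomial tests, and controls the
#' FDR over all classification tests. If `out_dir` is given, writes TSV
#' result tables and a JSON manifest keyed by the config hash.
#'
#' @param sim a `seeg_sim` (from [simulate_recording()] or [read_sim()])
#' @param config an [svm_config()]
#' @param out_dir optional output directory for TSV/JSON artifacts
#' @param norm normalization epoch passed to [session_features()]
#' @param states character vector of classification problems to run
#' @param sfs use sequential forward selection in the classifiers
#' @return list with `modulation`, `modulation_summary`, `classification`
#'   (one `svm_cv_result` per state set), `significance` (binomial + FDR
#'   table), `features` (the `session_features`)
#' @export
run_pipeline <- function(sim, config = svm_config(), out_dir = NULL,
                         norm = "block", states = c("two", "three"),
                         sfs = FALSE) {
  target_dur <- sim$config$target_duration %||% 5
  trials <- detect_trial_onsets(sim$trials, sim$force, target_dur)
  if (any(!trials$executed)) trials <- assign_imagined_onsets(trials)
  sim$trials <- trials
  sf <- session_features(sim, norm = norm)

  mod <- session_modulation(sf)
  mod_sum <- modulation_summary(mod)

  results <- list()
  sig_rows <- NULL
  for (st in states) {
    fm <- balance_rest(session_feature_matrix(sf, states = st),
                       seed = config$seed)
    res <- nested_cv_svm(fm, config, sfs = sfs)
    results[[st]] <- res
    refs <- if (st == "two") 0.5 else c(1 / 3, 0.5)
    for (ref in refs) {
      sig_rows <- rbind(sig_rows, data.frame(
        problem = st, chance_ref = ref,
        accuracy = res$mean_accuracy, n = res$n_trials))
    }
  }
  k <- round(sig_rows$accuracy * sig_rows$n)
  p <- mapply(binomial_above_chance, k, sig_rows$n, sig_rows$chance_ref)
  fdr <- bh_fdr(p)
  sig <- cbind(sig_rows, k = k, p_binomial = p,
               p_adjusted = fdr$p_adjusted, reject_fdr = fdr$reject)

  out <- list(modulation = mod, modulation_summary = mod_sum,
              classification = results, significance = sig,
              features = sf)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_modulation_tsv(mod, file.path(out_dir, "modulation.tsv"))
    utils::write.table(mod_sum, file.path(out_dir,
                                          "modulation_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sig, file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (st in names(results)) {
      utils::write.table(as.data.frame.matrix(results[[st]]$confusion),
                         file.path(out_dir,
                                   paste0("confusion_", st, "state.tsv")),
                         sep = "\t", quote = FALSE)
    }
    cfg <- sim$config
    class(cfg) <- NULL
    cfg$channels <- NULL
    manifest <- list(package = "seegforce",
                     version =
                       as.character(utils::packageVersion("seegforce")),
                     config_hash = config_hash(cfg),
                     svm_seed = config$seed)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
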