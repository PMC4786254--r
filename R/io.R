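#' Write a simulated session to a directory of plain-text files
#'
#' The on-disk container is columnar and lossless: `signals.tsv` (one
#' column per channel, full double precision), `channels.tsv` metadata
#' sidecar, `trials.csv`, `force.csv`, `ground_truth.json`, `config.json`
#' and a `manifest.json` carrying the config hash, seed and package
#' version so outputs can be traced to the run that produced them. All
#' timestamps are seconds from recording start, 0-based.
#'
#' @param sim a `seeg_sim`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "seeg_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- t(sim$recording$samples)
  con <- file(file.path(dir, "signals.tsv"), "w")
  writeLines(paste(sim$recording$channels$channel, collapse = "\t"), con)
  utils::write.table(format(sig, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  utils::write.table(sim$recording$channels,
                     file.path(dir, "channels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(sim$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(time_s = sim$force$time_s,
                              force = format(sim$force$force,
                                             digits = 17, trim = TRUE)),
                   file.path(dir, "force.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(sim$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       digits = NA, dataframe = "columns")
  cfg <- sim$config
  class(cfg) <- NULL
  cfg$channels <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(package = "seegforce",
                   version = as.character(utils::packageVersion("seegforce")),
                   config_hash = config_hash(cfg),
                   seed = sim$config$seed,
                   sampling_rate = sim$config$sampling_rate,
                   n_channels = nrow(sim$recording$channels),
                   n_trials = nrow(sim$trials))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_sim()]
#'
#' @param dir directory containing the container files
#' @return a `seeg_sim` list (the `config` slot holds the deserialized
#'   parameter list)
#' @export
read_sim <- function(dir) {
  need <- c("signals.tsv", "channels.tsv", "trials.csv", "force.csv",
            "manifest.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing session files in ", dir, ": ",
         paste(missing, collapse = ", "))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  chans <- utils::read.delim(file.path(dir, "channels.tsv"),
                             stringsAsFactors = FALSE)
  sig <- utils::read.delim(file.path(dir, "signals.tsv"),
                           check.names = FALSE)
  rec <- seeg_recording(t(as.matrix(sig)), manifest$sampling_rate, chans)
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  force <- utils::read.csv(file.path(dir, "force.csv"))
  gt <- if (file.exists(file.path(dir, "ground_truth.json")))
    jsonlite::read_json(file.path(dir, "ground_truth.json"),
                        simplifyVector = TRUE) else NULL
  cfg <- if (file.exists(file.path(dir, "config.json")))
    jsonlite::read_json(file.path(dir, "config.json"),
                        simplifyVector = TRUE) else list()
  cfg$channels <- chans
  rest <- cfg$rest_duration %||% 5
  blocks <- do.call(rbind, lapply(split(trials, trials$block), function(tb)
    data.frame(block = tb$block[1], grasp = tb$grasp[1],
               executed = tb$executed[1],
               start_s = min(tb$cue_time_s) - rest,
               end_s = max(tb$offset_time_s) + rest)))
  rownames(blocks) <- NULL
  structure(list(recording = rec, trials = trials, blocks = blocks,
                 force = force, ground_truth = gt, config = cfg),
            class = "seeg_sim")
}

#' Write a modulation result table as TSV
#'
#' @param res a `modulation_result`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_modulation_tsv <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
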