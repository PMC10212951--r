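#' Trial-aligned multi-channel spike dataset
#'
#' The universal input of the pipeline: spike times per (trial, channel) plus
#' per-trial condition labels.  Times are in ms, aligned so that t = 0 is
#' stimulus onset; negative times belong to the pre-stimulus baseline.
#'
#' @param spikes data.frame with columns `trial_id`, `channel_id`, `time_ms`.
#' @param trials data.frame with columns `trial_id`, `stimulus_id`,
#'   `category`, `ramp_ms`, `intensity`, `plateau_ms`.
#' @param meta list with at least `n_channels`, `t_min_ms`, `t_max_ms`.
#' @param ground_truth optional generator ground truth (kept alongside).
#' @param config optional generating [synth_config()].
#' @return an object of class `spike_dataset`.
#' @export
spike_dataset <- function(spikes, trials, meta,
                          ground_truth = NULL, config = NULL) {
  need_s <- c("trial_id", "channel_id", "time_ms")
  need_t <- c("trial_id", "stimulus_id", "category", "ramp_ms", "intensity",
              "plateau_ms")
  miss <- setdiff(need_s, names(spikes))
  if (length(miss))
    stop("spikes is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(need_t, names(trials))
  if (length(miss))
    stop("trials is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(spikes$time_ms) || !all(is.finite(spikes$time_ms)))
    stop("spikes$time_ms contains non-finite values (first bad row: ",
         which(!is.finite(spikes$time_ms))[1], ")", call. = FALSE)
  if (!all(spikes$trial_id %in% trials$trial_id))
    stop("spikes reference trial_id values absent from trials", call. = FALSE)
  if (is.null(meta$n_channels))
    stop("meta$n_channels is required", call. = FALSE)
  structure(list(spikes = spikes, trials = trials, meta = meta,
                 ground_truth = ground_truth, config = config),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat("spike_dataset:", nrow(x$trials), "trials,", x$meta$n_channels,
      "channels,", nrow(x$spikes), "spikes\n")
  cat("  window [", x$meta$t_min_ms, ",", x$meta$t_max_ms, "] ms;",
      length(unique(x$trials$stimulus_id)), "stimuli;",
      "categories:", paste(unique(x$trials$category), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a spike dataset as plain-text files
#'
#' The on-disk layout is `spikes.csv` (trial_id, channel_id, time_ms),
#' `trials.csv` (trial_id, stimulus_id, category, ramp_ms, intensity,
#' plateau_ms), `meta.json`, and, when present, `ground_truth.json`.
#' Round-tripping preserves spike times to sub-microsecond precision and all
#' labels.
#'
#' @param dataset a [spike_dataset()].
#' @param path directory to write into (created if needed).
#' @return `write_spike_dataset` returns `path` invisibly;
#'   `read_spike_dataset` returns a `spike_dataset`.
#' @export
write_spike_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spike_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$spikes, file.path(path, "spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  jsonlite::write_json(dataset$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(dataset$ground_truth))
    jsonlite::write_json(dataset$ground_truth,
                         file.path(path, "ground_truth.json"),
                         digits = NA)
  invisible(path)
}

#' @rdname write_spike_dataset
#' @export
read_spike_dataset <- function(path) {
  fs <- file.path(path, "spikes.csv")
  ft <- file.path(path, "trials.csv")
  fm <- file.path(path, "meta.json")
  for (f in c(fs, ft, fm))
    if (!file.exists(f))
      stop("dataset at '", path, "' is missing ", basename(f), call. = FALSE)
  spikes <- utils::read.csv(fs)
  trials <- utils::read.csv(ft)
  meta <- jsonlite::read_json(fm, simplifyVector = TRUE)
  gt <- NULL
  fg <- file.path(path, "ground_truth.json")
  if (file.exists(fg)) {
    gt <- jsonlite::read_json(fg, simplifyVector = TRUE)
    for (nm in c("latency_offsets_ms", "sustained_dev_hz"))
      if (!is.null(gt[[nm]])) gt[[nm]] <- as.matrix(gt[[nm]])
  }
  spike_dataset(spikes, trials, meta, ground_truth = gt)
}

# Subset a dataset to the trials satisfying a predicate on the trials table.
#' Subset a spike dataset by condition
#'
#' @param dataset a [spike_dataset()].
#' @param keep logical vector over rows of `dataset$trials`, or an expression
#'   of trial columns evaluated within the trials table.
#' @return the restricted `spike_dataset`.
#' @examples
#' # subset_trials(d, ramp_ms == 500 & intensity == 0.3)
#' @export
subset_trials <- function(dataset, keep) {
  keep_expr <- substitute(keep)
  keep <- eval(keep_expr, dataset$trials, parent.frame())
  stopifnot(is.logical(keep), length(keep) == nrow(dataset$trials))
  trials <- dataset$trials[keep & !is.na(keep), , drop = FALSE]
  spikes <- dataset$spikes[dataset$spikes$trial_id %in% trials$trial_id, ,
                           drop = FALSE]
  out <- dataset
  out$trials <- trials
  out$spikes <- spikes
  out
}
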