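#' End-to-end analysis pipeline on synthetic data
#'
#' Chains the full analysis: generate one synthetic dataset per stimulus
#' category (with decreasing prior match), extract latency sequences and
#' their span/center parameterization, run the rank-order and naive-Bayes
#' decoders, compute the time-resolved rate-decoding curve and its decay
#' slope, and the trajectory discriminability index.  Every intermediate
#' artifact is written under `out_dir` (CSV/JSON), together with summary
#' figures (rasters, accuracy curves, discriminability time courses).
#'
#' @param out_dir output directory (created; pass `NULL` to skip writing).
#' @param categories named numeric vector of prior-match levels per
#'   category.
#' @param config_args list of overrides passed to [synth_config()]
#'   (channels, trials, ramps, ...).
#' @param seed global seed; category k uses `seed + k` for generation and
#'   `seed` for fold assignment.
#' @param folds cross-validation folds.
#' @param decode_condition list with `ramp_ms` and `intensity` selecting the
#'   condition cell used for the per-category decoders.
#' @param figures write PDF figures (default `TRUE` when `out_dir` given).
#' @return (invisibly) the report: a nested list with per-category
#'   `sequence_fits`, `decoding` (rank / nb_latency / nb_rate results),
#'   `time_resolved` series and `decay_slope`, and `discriminability`.
#' @export
run_pipeline <- function(out_dir = NULL,
                         categories = c(natural = 1, morphed = 0.6,
                                        scrambled = 0.2),
                         config_args = list(), seed = 1L, folds = 10,
                         decode_condition = list(ramp_ms = NULL,
                                                 intensity = NULL),
                         figures = !is.null(out_dir)) {
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = seed, categories = list())
  for (k in seq_along(categories)) {
    cat_name <- names(categories)[k]
    args <- utils::modifyList(
      list(prior_match = unname(categories[k]), category = cat_name,
           seed = seed + k), config_args)
    cfg <- do.call(synth_config, args)
    ds <- generate_dataset(cfg)
    ramp_sel <- decode_condition$ramp_ms %||% max(cfg$ramp_durations_ms)
    int_sel <- decode_condition$intensity %||% max(cfg$intensities)
    ds_dec <- subset_trials(ds, ramp_ms == ramp_sel & intensity == int_sel)

    rt <- compute_rates(ds_dec, 30, 1)
    lt <- latency_table(rt)
    mlat <- mean_latencies(lt, ds_dec$trials)
    fits <- lapply(mlat, function(v)
      tryCatch(unclass(fit_sequence(v))[c("slope", "span_ms", "center_ms",
                                          "r_fit", "n_used")],
               error = function(e) list(error = conditionMessage(e))))

    decoding <- list(
      rank = crossval_accuracy(ds_dec, "rank", folds = folds, seed = seed),
      nb_latency = crossval_accuracy(ds_dec, "nb_latency", folds = folds,
                                     seed = seed),
      nb_rate = crossval_accuracy(ds_dec, "nb_rate", folds = folds,
                                  seed = seed)
    )
    series <- time_resolved_rate_decoding(ds_dec, folds = folds, seed = seed)
    slope <- tryCatch(decay_slope(series, max(series$time_ms)),
                      error = function(e) list(error = conditionMessage(e)))
    rt100 <- compute_rates(ds_dec, 100, 100)
    disc <- discriminability_index(rt100)

    report$categories[[cat_name]] <- list(
      prior_match = unname(categories[k]),
      condition = list(ramp_ms = ramp_sel, intensity = int_sel),
      sequence_fits = fits,
      decoding = lapply(decoding, function(d)
        list(accuracy_pct = d$accuracy_pct,
             chance_level_pct = d$chance_level_pct,
             fold_accuracies = d$fold_accuracies)),
      decay_slope = slope,
      discriminability = disc
    )

    if (!is.null(out_dir)) {
      sub <- file.path(out_dir, cat_name)
      write_spike_dataset(ds, file.path(sub, "dataset"))
      utils::write.csv(lt, file.path(sub, "latencies.csv"), row.names = FALSE)
      jsonlite::write_json(fits, file.path(sub, "sequence_fits.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      utils::write.csv(series, file.path(sub, "decoding_timecourse.csv"),
                       row.names = FALSE)
      utils::write.csv(disc, file.path(sub, "discriminability.csv"),
                       row.names = FALSE)
      if (figures) pipeline_figures(sub, ds_dec, rt, series, disc)
    }
  }
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Static summary figures for one category (base graphics, PDF).
pipeline_figures <- function(dir_, ds, rt, series, disc) {
  grDevices::pdf(file.path(dir_, "figures.pdf"), width = 8, height = 6)
  on.exit(grDevices::dev.off())
  # raster of the first trial per stimulus, channels ordered by peak latency
  stim <- sort(unique(ds$trials$stimulus_id))
  graphics::par(mfrow = c(length(stim), 1), mar = c(3, 4, 2, 1))
  psth <- apply(rt$values, c(2, 3), mean)
  ord <- order(apply(psth, 1, function(r)
    peak_latency(r, rt$bin_centers_ms, k = 0)))
  for (s in stim) {
    tr <- ds$trials$trial_id[ds$trials$stimulus_id == s][1]
    spk <- ds$spikes[ds$spikes$trial_id == tr, ]
    graphics::plot(spk$time_ms, match(spk$channel_id, ord), pch = "|",
                   cex = 0.5, xlab = "time (ms)", ylab = "channel (sorted)",
                   main = paste("stimulus", s))
    graphics::abline(v = 0, col = "red")
  }
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  graphics::plot(series$time_ms, series$accuracy_pct, type = "b",
                 xlab = "time (ms)", ylab = "accuracy (%)",
                 main = "time-resolved rate decoding")
  graphics::abline(h = attr(series, "chance_level_pct"), lty = 2)
  graphics::plot(disc$time_ms, disc$index, type = "l",
                 xlab = "time (ms)", ylab = "discriminability index",
                 main = "trajectory discriminability")
  invisible(NULL)
}
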