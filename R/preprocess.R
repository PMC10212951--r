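#' Robust noise level of a filtered trace
#'
#' Median-based estimator of the background noise SD of a spiking-band
#' signal: `sigma = median(|x|) / 0.6745`.  Because spikes occupy a small
#' fraction of samples, the median of absolute amplitudes is nearly
#' unaffected by them, unlike the sample SD.
#'
#' @param x numeric vector of filtered samples (arbitrary units).
#' @return non-negative scalar noise SD estimate.
#' @export
estimate_noise_sigma <- function(x) {
  if (length(x) == 0) stop("empty trace", call. = FALSE)
  if (any(!is.finite(x))) stop("trace contains non-finite samples", call. = FALSE)
  stats::median(abs(x)) / 0.6745
}

#' Zero-phase band-pass filter for broadband traces
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass, by default
#' 500-3000 Hz, isolating the spiking frequency band before threshold
#' detection.
#'
#' @param x numeric vector of raw samples.
#' @param sampling_rate_hz sampling rate.
#' @param band two-element passband in Hz.
#' @return filtered samples, same length as `x`.
#' @export
bandpass_filter <- function(x, sampling_rate_hz, band = c(500, 3000)) {
  stopifnot(sampling_rate_hz > 0, length(band) == 2, band[1] < band[2],
            band[2] < sampling_rate_hz / 2)
  bt <- signal::butter(4, band / (sampling_rate_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bt, x))
}

#' Threshold-crossing spike detection
#'
#' Detects multi-unit events as negative-going crossings of `-k * sigma`,
#' where `sigma` is the robust noise estimate of [estimate_noise_sigma()].
#' After each detection a refractory lockout suppresses further crossings so
#' a single waveform yields a single event.  Times are reported in ms at
#' sample resolution (time of the first sub-threshold sample).
#'
#' @param x filtered samples.
#' @param sampling_rate_hz sampling rate.
#' @param k threshold multiplier (> 0), default 4.
#' @param sigma noise SD; estimated from `x` when `NULL`.
#' @param lockout_ms refractory lockout after each event (ms).
#' @return numeric vector of event times in ms.
#' @export
detect_spikes <- function(x, sampling_rate_hz, k = 4, sigma = NULL,
                          lockout_ms = 1) {
  if (k <= 0) stop("threshold multiplier k must be positive", call. = FALSE)
  stopifnot(sampling_rate_hz > 0, lockout_ms >= 0)
  if (length(x) < 2) return(numeric(0))
  if (is.null(sigma)) sigma <- estimate_noise_sigma(x)
  thr <- -k * sigma
  below <- x < thr
  cross <- which(below[-1] & !below[-length(x)]) + 1L
  if (sigma == 0) cross <- which(below)  # degenerate flat-noise case
  if (!length(cross)) return(numeric(0))
  lock <- max(1L, as.integer(round(lockout_ms * sampling_rate_hz / 1000)))
  keep <- logical(length(cross))
  last <- -Inf
  for (i in seq_along(cross)) {
    if (cross[i] - last >= lock) {
      keep[i] <- TRUE
      last <- cross[i]
    }
  }
  (cross[keep] - 1) / sampling_rate_hz * 1000
}

#' Sliding-window firing-rate tensor
#'
#' Converts a [spike_dataset()] into a trials x channels x bins array of
#' firing rates (spikes/s).  Each bin counts spikes in the half-open window
#' `[center - window/2, center + window/2)` and divides by the window length.
#' Bin centers advance in steps of `step_ms`; windows that would extend
#' outside the recorded trial are dropped rather than zero-padded.  The two
#' canonical settings are 30/1 ms (latency estimation, light single-trial
#' smoothing) and 100/100 ms (rate decoding, long integration windows).
#'
#' @param dataset a [spike_dataset()].
#' @param window_ms window length (> 0).
#' @param step_ms step between bin centers (> 0).
#' @return a `rate_tensor`: list with `values` (array trials x channels x
#'   bins), `bin_centers_ms`, `window_ms`, `step_ms`, and the `trials` table.
#' @export
compute_rates <- function(dataset, window_ms, step_ms) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (window_ms <= 0 || step_ms <= 0)
    stop("window_ms and step_ms must be positive", call. = FALSE)
  t0 <- dataset$meta$t_min_ms
  t1 <- dataset$meta$t_max_ms
  if (is.null(t0) || is.null(t1) || t1 <= t0)
    stop("dataset has a zero-length or undefined trial window", call. = FALSE)
  half <- window_ms / 2
  centers <- seq(t0 + half, t1 - half, by = step_ms)
  if (!length(centers))
    stop("trial shorter than one window", call. = FALSE)
  nc <- dataset$meta$n_channels
  trial_ids <- dataset$trials$trial_id
  nt <- length(trial_ids)
  vals <- array(0, dim = c(nt, nc, length(centers)))
  spk <- dataset$spikes
  spk_trial <- match(spk$trial_id, trial_ids)
  edges <- c(centers - half, centers + half)
  for (ti in seq_len(nt)) {
    in_tr <- which(spk_trial == ti)
    if (!length(in_tr)) next
    ch <- spk$channel_id[in_tr]
    tm <- spk$time_ms[in_tr]
    for (c_id in unique(ch)) {
      st <- sort(tm[ch == c_id])
      # count in [lo, hi): #(x < hi) - #(x < lo)
      cnt <- findInterval(edges, st, left.open = TRUE)
      n_b <- length(centers)
      vals[ti, c_id, ] <- (cnt[(n_b + 1):(2 * n_b)] - cnt[1:n_b]) /
        (window_ms / 1000)
    }
  }
  structure(list(values = vals, bin_centers_ms = centers,
                 window_ms = window_ms, step_ms = step_ms,
                 trials = dataset$trials),
            class = "rate_tensor")
}

#' @export
print.rate_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("rate_tensor:", d[1], "trials x", d[2], "channels x", d[3], "bins;",
      "window", x$window_ms, "ms, step", x$step_ms, "ms\n")
  invisible(x)
}
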