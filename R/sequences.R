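#' Peak response latency of a single rate profile
#'
#' Time of the global maximum of a firing-rate trace within the response
#' window, with a responsiveness gate: the latency is `NA` unless the peak
#' exceeds the pre-stimulus baseline mean by `k` baseline SDs.  Ties are
#' broken toward the earliest bin.  Profiles are expected from
#' [compute_rates()] with a short window (30 ms) moved in small steps (1 ms),
#' which lightly smooths single-trial rate estimates.
#'
#' @param rate numeric rate trace (one channel, one trial or trial mean).
#' @param centers_ms bin centers belonging to `rate`.
#' @param response_window two times (ms) delimiting where to search;
#'   default from stimulus onset (0) to the end of the trace.
#' @param k responsiveness gate in baseline SDs (default 3).
#' @param baseline_sd_floor absolute floor for the baseline SD used by the
#'   gate, guarding degenerate all-zero baselines.
#' @return peak time in ms, or `NA_real_` if the channel is unresponsive.
#' @export
peak_latency <- function(rate, centers_ms,
                         response_window = c(0, max(centers_ms)),
                         k = 3, baseline_sd_floor = 1e-9) {
  stopifnot(length(rate) == length(centers_ms))
  win <- centers_ms >= response_window[1] & centers_ms <= response_window[2]
  if (!any(win)) stop("response window lies outside the trace", call. = FALSE)
  base <- centers_ms < 0
  gate <- if (any(base)) {
    s <- stats::sd(rate[base])
    if (!is.finite(s) || s < baseline_sd_floor) s <- baseline_sd_floor
    mean(rate[base]) + k * s
  } else -Inf
  r <- rate[win]
  pk <- max(r)
  if (pk <= gate || pk <= 0) return(NA_real_)
  centers_ms[win][which.max(r)]   # which.max -> earliest tie
}

#' Onset response latency of a single rate profile
#'
#' First time after stimulus onset at which the rate exceeds the baseline
#' mean + `k` baseline SDs and stays above that threshold for at least
#' `m_consecutive` consecutive bins.  Returns `NA` when the rate never
#' fulfils the criterion.  A degenerate baseline (SD 0) is handled with an
#' absolute threshold floor.
#'
#' @inheritParams peak_latency
#' @param m_consecutive minimal number of consecutive supra-threshold bins
#'   (default 10, i.e. 10 ms at a 1 ms step).
#' @return onset time in ms, or `NA_real_`.
#' @export
onset_latency <- function(rate, centers_ms,
                          response_window = c(0, max(centers_ms)),
                          k = 3, m_consecutive = 10,
                          baseline_sd_floor = 1e-9) {
  stopifnot(length(rate) == length(centers_ms))
  base <- centers_ms < 0
  if (!any(base)) stop("no pre-stimulus baseline bins in trace", call. = FALSE)
  s <- stats::sd(rate[base])
  if (!is.finite(s) || s < baseline_sd_floor) s <- baseline_sd_floor
  thr <- mean(rate[base]) + k * s
  win <- which(centers_ms >= response_window[1] &
                 centers_ms <= response_window[2])
  above <- rate[win] > thr
  if (!any(above)) return(NA_real_)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= m_consecutive)
  if (!length(ok)) return(NA_real_)
  centers_ms[win[starts[ok[1]]]]
}

#' Per-trial, per-channel latency table
#'
#' Applies [peak_latency()] and [onset_latency()] to every (trial, channel)
#' slice of a rate tensor.
#'
#' @param rt a `rate_tensor` from [compute_rates()] (30/1 ms recommended).
#' @param response_window search window, ms.
#' @param k responsiveness gate (baseline SDs).
#' @param onset_m consecutive-bin requirement for the onset criterion.
#' @return data.frame with columns `trial_id`, `channel_id`, `peak_ms`,
#'   `onset_ms`.
#' @export
latency_table <- function(rt, response_window = NULL, k = 3, onset_m = 10) {
  stopifnot(inherits(rt, "rate_tensor"))
  cen <- rt$bin_centers_ms
  if (is.null(response_window)) response_window <- c(0, max(cen))
  d <- dim(rt$values)
  out <- expand.grid(channel_id = seq_len(d[2]),
                     trial_id = rt$trials$trial_id,
                     KEEP.OUT.ATTRS = FALSE)[, c(2, 1)]
  pk <- on <- numeric(nrow(out))
  i <- 0L
  for (ti in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      i <- i + 1L
      r <- rt$values[ti, ch, ]
      pk[i] <- peak_latency(r, cen, response_window, k)
      on[i] <- if (is.na(pk[i])) NA_real_ else
        onset_latency(r, cen, response_window, k, onset_m)
    }
  }
  out$peak_ms <- pk
  out$onset_ms <- pmin(on, pk, na.rm = FALSE)
  out
}

#' Fit a line to rank-sorted latencies (sequence span and center)
#'
#' Parameterizes a response sequence: latencies are sorted ascending, a
#' least-squares line is fitted to sorted latency versus rank index, and the
#' sequence is summarized by the span (difference between the fitted values
#' at the first and last rank) and the center time (fitted value at the
#' middle rank).
#'
#' @param latencies named or plain numeric vector of per-channel mean
#'   latencies (ms); `NA` entries (unresponsive channels) are dropped.
#' @return a `sequence_fit`: list with `channel_order`, `slope`
#'   (ms/channel-rank), `intercept`, `span_ms`, `center_ms`, `r_fit`,
#'   `n_used`, `excluded`.
#' @export
fit_sequence <- function(latencies) {
  lat <- latencies
  if (is.null(names(lat))) names(lat) <- seq_along(lat)
  ok <- !is.na(lat)
  if (sum(ok) < 3)
    stop("fit_sequence needs >= 3 defined latencies", call. = FALSE)
  lat_ok <- lat[ok]
  ord <- order(lat_ok)
  y <- lat_ok[ord]
  n <- length(y)
  x <- seq_len(n) - 1
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- unname(fit$coefficients)
  r_fit <- if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  structure(list(channel_order = names(lat_ok)[ord],
                 slope = b[2], intercept = b[1],
                 span_ms = b[2] * (n - 1),
                 center_ms = b[1] + b[2] * (n - 1) / 2,
                 r_fit = r_fit, n_used = n,
                 excluded = names(lat)[!ok]),
            class = "sequence_fit")
}

#' @export
print.sequence_fit <- function(x, ...) {
  cat(sprintf("sequence_fit: span %.1f ms, center %.1f ms (%d channels, r = %.3f)\n",
              x$span_ms, x$center_ms, x$n_used,
              ifelse(is.na(x$r_fit), NaN, x$r_fit)))
  invisible(x)
}

#' Per-channel trial-mean latencies by condition
#'
#' Averages the [latency_table()] within each condition cell.
#'
#' @param lt latency table.
#' @param trials trials table of the dataset.
#' @param feature `"peak"` or `"onset"`.
#' @param by condition columns to group by.
#' @param fun summary function across trials (default mean).
#' @return a list of named latency vectors, one per condition, names built
#'   from the `by` columns.
#' @export
mean_latencies <- function(lt, trials, feature = c("peak", "onset"),
                           by = c("stimulus_id", "ramp_ms", "intensity"),
                           fun = mean) {
  feature <- match.arg(feature)
  col <- paste0(feature, "_ms")
  m <- merge(lt, trials[, c("trial_id", by)], by = "trial_id")
  key <- interaction(m[by], drop = TRUE, sep = "|")
  out <- lapply(split(m, key), function(g) {
    v <- tapply(g[[col]], g$channel_id, function(x) {
      x <- x[!is.na(x)]
      if (length(x)) fun(x) else NA_real_
    })
    stats::setNames(as.numeric(v), names(v))
  })
  out
}

#' Rank-order correlation between two condition sequences
#'
#' Spearman correlation between the per-channel latencies obtained under two
#' conditions (e.g. slow vs fast ramp for the same stimulus), over the
#' channels responsive in both.  High correlation means the sequence order is
#' preserved across conditions.
#'
#' @param lat_a,lat_b per-channel latency vectors (same channel set, `NA`
#'   for unresponsive channels).
#' @param method p-value method: Student-t approximation or permutation.
#' @param n_perm permutations when `method = "permutation"`.
#' @return list with `rho`, `p_value`, `n_shared`.
#' @export
sequence_order_correlation <- function(lat_a, lat_b,
                                       method = c("t", "permutation"),
                                       n_perm = 1000) {
  method <- match.arg(method)
  if (length(lat_a) != length(lat_b))
    stop("latency vectors differ in length", call. = FALSE)
  ok <- !is.na(lat_a) & !is.na(lat_b)
  n <- sum(ok)
  if (n < 5)
    stop("fewer than 5 shared responsive channels", call. = FALSE)
  a <- lat_a[ok]; b <- lat_b[ok]
  rho <- spearman_rho(a, b)
  p <- if (is.na(rho)) {
    NA_real_
  } else if (method == "t") {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    null <- replicate(n_perm, spearman_rho(a, sample(b)))
    (1 + sum(abs(null) >= abs(rho), na.rm = TRUE)) / (n_perm + 1)
  }
  list(rho = rho, p_value = p, n_shared = n)
}
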