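# closed-form Spearman for permutations without ties
rho_closed_form <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

test_that("spearman_rho matches closed form on all permutations of n = 6", {
  x <- 1:6
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  expect_equal(nrow(perms), 720)
  for (i in seq_len(nrow(perms))) {
    y <- perms[i, ]
    expect_equal(spearman_rho(x, y), rho_closed_form(x, y),
                 tolerance = 1e-12)
  }
})

test_that("spearman_rho handles ties exactly like the reference midrank method", {
  set.seed(10)
  for (i in 1:1000) {
    n <- sample(5:30, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- sample(1:8, n, replace = TRUE)
    mine <- spearman_rho(x, y)
    ref <- suppressWarnings(stats::cor(x, y, method = "spearman"))
    if (is.na(ref)) expect_true(is.na(mine))
    else expect_equal(mine, ref, tolerance = 1e-12)
  }
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8, tolerance = 1e-12)
  expect_equal(spearman_rho(1:7, 1:7), 1)
  expect_equal(spearman_rho(1:7, 7:1), -1)
  expect_error(spearman_rho(1:3, 1:4), "length")
})

test_that("naive Bayes posteriors match the closed-form Gaussian ratio", {
  x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 2), 10))
  y <- rep(1:2, each = 10)
  m <- nb_fit(x, y)
  # overwrite with the canonical parameters for the closed-form check
  m$mu <- matrix(c(0, 2, 0, 2), 2)[, 1, drop = FALSE]
  m$var <- matrix(1, 2, 1)
  m$prior <- c(0.5, 0.5)
  p1 <- nb_predict(m, 1)$posterior
  expect_equal(unname(p1), c(0.5, 0.5), tolerance = 1e-9)
  p2 <- nb_predict(m, 0.5)$posterior
  expect_equal(unname(p2[1]), 1 / (1 + exp(-1)), tolerance = 1e-9)
  # widely separated classes
  m$mu <- matrix(c(0, 10), 2)
  p3 <- nb_predict(m, 0)
  expect_identical(p3$class, 1L)
  expect_gt(p3$posterior[1], 0.99)
  # identical class distributions -> indifferent posterior
  m$mu <- matrix(c(1, 1), 2)
  expect_equal(unname(nb_predict(m, 3)$posterior), c(0.5, 0.5))
})

test_that("naive Bayes agrees with an independent reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(11)
  x <- matrix(rnorm(60 * 4, rep(c(0, 1, 3), each = 20)), 60, 4)
  y <- rep(1:3, each = 20)
  mine <- nb_fit(x, y)
  ref <- e1071::naiveBayes(x, factor(y))
  for (i in sample(60, 10)) {
    p_ref <- stats::predict(ref, x[i, , drop = FALSE], type = "raw")
    p_me <- nb_predict(mine, x[i, ])$posterior
    expect_equal(unname(p_me), as.numeric(p_ref), tolerance = 1e-6)
  }
})

test_that("posterior sums to one and responds monotonically to evidence", {
  set.seed(12)
  x <- matrix(rnorm(40, rep(c(0, 4), each = 10)), 20, 2)
  y <- rep(1:2, each = 10)
  m <- nb_fit(x, y)
  for (v in seq(-2, 6, by = 1)) {
    p <- nb_predict(m, c(v, v))$posterior
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  post2 <- vapply(seq(-2, 6, 0.5),
                  function(v) nb_predict(m, c(v, v))$posterior[2], numeric(1))
  expect_true(all(diff(post2) > -1e-9))
})

test_that("zero feature variance is floored, not fatal", {
  x <- cbind(rep(c(0, 1), each = 5), rnorm(10))
  y <- rep(1:2, each = 5)
  m <- nb_fit(x, y, var_floor = 1e-9)
  expect_true(all(m$var >= 1e-9))
  expect_identical(nb_predict(m, c(0, 0))$class, 1L)
})

test_that("rank templates recover ground-truth orders and reject bad input", {
  d <- generate_dataset(clean_config(seed = 14))
  lat <- rankseq:::latency_features(d, "peak")
  tpl <- build_rank_templates(lat, d$trials$stimulus_id)
  for (s in 1:3) {
    expect_equal(spearman_rho(tpl$mean_latency[s, ],
                              d$ground_truth$latency_offsets_ms[s, tpl$channels]),
                 1)
  }
  expect_error(build_rank_templates(lat, seq_len(nrow(lat))), "2 training")
  # classifying a template's own mean latencies returns its stimulus
  for (s in 1:3) {
    full <- rep(NA_real_, ncol(lat))
    full[tpl$channels] <- tpl$mean_latency[s, ]
    expect_identical(rank_decode(full, tpl), s)
  }
  expect_error(rank_decode(rep(NA_real_, ncol(lat)), tpl), "defined")
})

test_that("templates from disjoint trial halves agree at low jitter", {
  set.seed(15)
  # latency matrices built directly from ground-truth offsets + noise
  offs <- t(vapply(1:3, function(s) sample(seq(0, 120, length.out = 24)),
                   numeric(24)))
  rhos <- replicate(20, {
    lat <- do.call(rbind, lapply(rep(1:3, each = 10), function(s)
      offs[s, ] + rnorm(24, 0, 8)))
    y <- rep(1:3, each = 10)
    half <- rep(c(TRUE, FALSE), 15)
    t1 <- build_rank_templates(lat[half, ], y[half])
    t2 <- build_rank_templates(lat[!half, ], y[!half])
    mean(vapply(1:3, function(s)
      spearman_rho(t1$ranks[s, ], t2$ranks[s, ]), numeric(1)))
  })
  expect_gt(mean(rhos), 0.95)
})

test_that("cross-validation is deterministic, stratified, and consistent", {
  d <- generate_dataset(clean_config(seed = 16, n_trials = 12))
  r1 <- crossval_accuracy(d, "rank", folds = 6, seed = 5)
  r2 <- crossval_accuracy(d, "rank", folds = 6, seed = 5)
  expect_identical(r1$accuracy_pct, r2$accuracy_pct)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_equal(sum(r1$confusion), nrow(d$trials))
  expect_equal(as.numeric(rowSums(r1$confusion)),
               as.numeric(table(d$trials$stimulus_id)))
  expect_equal(r1$chance_level_pct, 100 / 3)
  expect_error(crossval_accuracy(d, "rank", folds = 13), "folds")
})

test_that("label-shuffled decoding stays near chance (spot check)", {
  d <- generate_dataset(noisy_config(seed = 17))
  lat <- rankseq:::latency_features(d, "peak", response_window = c(0, 700))
  n <- nrow(d$trials)
  band <- stats::qbinom(c(0.005, 0.995), n, 1/3) / n * 100
  set.seed(18)
  inside <- replicate(10, {
    y <- sample(d$trials$stimulus_id)
    acc <- rankseq:::decode_features(lat, y, "nb_latency", folds = 10,
                                     seed = 1)$accuracy_pct
    acc >= band[1] && acc <= band[2]
  })
  expect_gte(sum(inside), 9)
})

test_that("fastest-channels curve reaches the full-set accuracy at k = n", {
  d <- generate_dataset(clean_config(seed = 19, n_trials = 12))
  curve <- fastest_channels_curve(d, k_values = c(4, 16), folds = 6, seed = 2)
  full <- crossval_accuracy(d, "nb_latency", folds = 6, seed = 2)
  expect_equal(curve$accuracy_pct[curve$k == 16], full$accuracy_pct)
  expect_true(all(diff(curve$mean_latency_ms) > 0))
  expect_warning(fastest_channels_curve(d, k_values = 99, folds = 6, seed = 2),
                 "clipped")
})

test_that("rate-equivalent features equal a brute-force recount", {
  d <- generate_dataset(noisy_config(seed = 20))
  lat <- rankseq:::latency_features(d, "peak")
  glat <- colMeans(lat, na.rm = TRUE)
  counts <- rankseq:::latency_cutoff_counts(d, glat)
  # brute-force recount for random (trial, channel) pairs
  set.seed(21)
  ids <- d$trials$trial_id
  for (i in 1:100) {
    ti <- sample(length(ids), 1)
    ch <- sample(16, 1)
    manual <- sum(d$spikes$trial_id == ids[ti] & d$spikes$channel_id == ch &
                    d$spikes$time_ms >= 0 & d$spikes$time_ms < glat[ch])
    expect_identical(counts[ti, ch], as.numeric(manual))
  }
  curve <- rate_equivalent_curve(d, k_values = 16, folds = 10, seed = 3)
  expect_equal(nrow(curve), 1)
})

test_that("latency beats early-cutoff rates for the fastest channels", {
  # stimuli share firing-rate profiles and differ only in which channel
  # fires when; with few channels the early spike counts are noisy while
  # peak times remain well estimated
  set.seed(22)
  diffs <- replicate(20, {
    sd_ <- sample(1e6, 1)
    d <- generate_dataset(synth_config(
      n_channels = 16, n_stimuli = 3, n_trials_per_condition = 12,
      ramp_durations_ms = 500, intensities = 0.3, base_latency_ms = 120,
      base_span_ms = 120, latency_jitter_ms = 15, peak_rate_hz = 150,
      baseline_rate_hz = 10, sustained_rate_hz = 0, trial_duration_ms = 900,
      baseline_ms = 200, seed = sd_))
    a_lat <- fastest_channels_curve(d, k_values = 2, folds = 6,
                                    seed = 1)$accuracy_pct
    a_rate <- rate_equivalent_curve(d, k_values = 2, folds = 6,
                                    seed = 1)$accuracy_pct
    a_lat - a_rate
  })
  expect_gt(mean(diffs), 0)
})

test_that("time-resolved decoding peaks in the transient and decays", {
  d <- generate_dataset(synth_config(
    n_channels = 16, n_stimuli = 3, n_trials_per_condition = 20,
    ramp_durations_ms = 0, intensities = 0.3, base_latency_ms = 150,
    base_span_ms = 80, latency_jitter_ms = 10, peak_rate_hz = 120,
    baseline_rate_hz = 3, sustained_rate_hz = 15, persistence_tau_ms = 300,
    trial_duration_ms = 1000, baseline_ms = 300, seed = 23))
  ser <- time_resolved_rate_decoding(d, folds = 10, seed = 1)
  chance <- attr(ser, "chance_level_pct")
  pre <- ser$accuracy_pct[ser$time_ms < 0]
  expect_true(all(abs(pre - chance) < 25))
  pk <- ser$time_ms[which.max(ser$accuracy_pct)]
  expect_true(pk >= 100 && pk <= 400)
  late <- mean(ser$accuracy_pct[ser$time_ms > 700])
  expect_lt(late, max(ser$accuracy_pct))
})

test_that("decay slope is exact on constructed accuracy curves", {
  flat <- data.frame(time_ms = seq(50, 950, 100), accuracy_pct = 70)
  expect_equal(decay_slope(flat, 1000)$slope_pct_per_s, 0)
  falling <- data.frame(time_ms = seq(50, 950, 100),
                        accuracy_pct = seq(100, 10, by = -10))
  expect_equal(decay_slope(falling, 1000)$slope_pct_per_s, -100)
  expect_error(decay_slope(falling[1:2, ], 1000), "3 bins")
  # slope fitted only from the peak onward
  humped <- data.frame(time_ms = seq(50, 950, 100),
                       accuracy_pct = c(40, 60, 90, 80, 70, 60, 50, 40, 30, 20))
  ds_ <- decay_slope(humped, 1000)
  expect_equal(ds_$interval_ms[1], 250)
  expect_equal(ds_$slope_pct_per_s, -100)
})

test_that("persistence extends late decodability and flattens the decay", {
  set.seed(24)
  res <- vapply(1:6, function(i) {
    sd_ <- sample(1e6, 1)
    mk <- function(pm) generate_dataset(synth_config(
      n_channels = 24, n_stimuli = 3, n_trials_per_condition = 20,
      ramp_durations_ms = 0, intensities = 0.3, base_latency_ms = 120,
      base_span_ms = 60, latency_jitter_ms = 20, peak_rate_hz = 100,
      baseline_rate_hz = 3, sustained_rate_hz = 20, persistence_tau_ms = 300,
      prior_match = pm, trial_duration_ms = 1000, baseline_ms = 300,
      category = "x", seed = sd_))
    s_hi <- time_resolved_rate_decoding(mk(1.0), folds = 10, seed = i)
    s_lo <- time_resolved_rate_decoding(mk(0.2), folds = 10, seed = i)
    late <- function(s) mean(s$accuracy_pct[s$time_ms >= 450 & s$time_ms <= 850])
    # slopes compared over the early descending phase, before the
    # low-persistence curve reaches the chance floor
    sl <- function(s) decay_slope(s, 500)$slope_pct_per_s
    c(late(s_hi) - late(s_lo), sl(s_hi) - sl(s_lo))
  }, numeric(2))
  expect_gt(mean(res[1, ]), 0)          # more late information
  expect_gt(mean(res[2, ]), 0)          # less negative slope
})
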