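#' Spearman rank-order correlation
#'
#' Similarity measure used for sequence-template matching: midranks are
#' assigned to both vectors (ties get the average of the tied ranks) and the
#' Pearson correlation of the rank vectors is computed explicitly.  Returns
#' `NA` when either rank vector has zero variance.
#'
#' @param x,y numeric vectors of equal length >= 2; `NA`s are not accepted
#'   (exclude undefined channels before calling).
#' @return rho in \[-1, 1\], or `NA_real_`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y differ in length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / sqrt(sx * sy)
}

#' Rank-order templates from trial-averaged latencies
#'
#' For each stimulus, the per-channel trial-mean latencies of the training
#' trials are converted to a midrank vector over the shared responsive
#' channels (channels whose trial-mean latency is defined for every
#' stimulus).
#'
#' @param lat matrix trials x channels of single-trial latencies (ms).
#' @param labels stimulus label per trial.
#' @return a `rank_templates` object: list with `ranks` (stimuli x channels
#'   midrank matrix), `mean_latency` (stimuli x channels), `channels`.
#' @export
build_rank_templates <- function(lat, labels) {
  stopifnot(is.matrix(lat), nrow(lat) == length(labels))
  labs <- sort(unique(labels))
  if (any(table(labels) < 2))
    stop("need >= 2 training trials per stimulus", call. = FALSE)
  mlat <- t(vapply(labs, function(l) {
    colMeans(lat[labels == l, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(lat))))
  mlat[!is.finite(mlat)] <- NA
  shared <- which(colSums(is.na(mlat)) == 0)
  if (!length(shared))
    stop("no channel is responsive for every stimulus", call. = FALSE)
  ranks <- t(apply(mlat[, shared, drop = FALSE], 1, rank,
                   ties.method = "average"))
  structure(list(ranks = ranks, mean_latency = mlat[, shared, drop = FALSE],
                 channels = shared, labels = labs),
            class = "rank_templates")
}

#' Classify one trial by rank-template matching
#'
#' Compares the rank order of a single trial's latencies with every stimulus
#' template via [spearman_rho()] and returns the label of the most similar
#' template.  Ties are broken deterministically toward the smallest label;
#' if every correlation is undefined the decoder abstains (`NA`).
#'
#' @param trial_lat per-channel latency vector for one trial (full channel
#'   set; `NA` for unresponsive channels).
#' @param templates a [build_rank_templates()] object.
#' @param min_defined minimal number of defined latencies on template
#'   channels (default 5).
#' @return predicted label (same type as the template labels) or `NA`.
#' @export
rank_decode <- function(trial_lat, templates, min_defined = 5) {
  v <- trial_lat[templates$channels]
  ok <- !is.na(v)
  if (sum(ok) < min_defined)
    stop("trial has fewer than ", min_defined,
         " defined latencies on template channels", call. = FALSE)
  rhos <- apply(templates$ranks[, ok, drop = FALSE], 1, function(tpl) {
    spearman_rho(v[ok], tpl)
  })
  if (all(is.na(rhos))) return(templates$labels[NA_integer_])
  templates$labels[which.max(rhos)]  # which.max: earliest (smallest label)
}

#' Gaussian naive Bayes classifier
#'
#' Class-conditional independent Gaussians per feature with a variance floor
#' and maximum-likelihood priors.  Features that are `NA` in a test vector
#' are skipped (their likelihood factor omitted), so trials with a few
#' unresponsive channels remain classifiable.
#'
#' @param x matrix trials x features.
#' @param y class label per trial.
#' @param var_floor minimal class-conditional variance (default 1e-9).
#' @return a `gaussian_nb` model (means, variances, priors per class).
#' @export
nb_fit <- function(x, y, var_floor = 1e-9) {
  stopifnot(is.matrix(x), nrow(x) == length(y), var_floor > 0)
  labs <- sort(unique(y))
  if (length(labs) < 2) stop("need >= 2 classes", call. = FALSE)
  if (any(table(y) < 2)) stop("need >= 2 trials per class", call. = FALSE)
  mu <- t(vapply(labs, function(l)
    colMeans(x[y == l, , drop = FALSE], na.rm = TRUE), numeric(ncol(x))))
  v <- t(vapply(labs, function(l)
    apply(x[y == l, , drop = FALSE], 2, stats::var, na.rm = TRUE),
    numeric(ncol(x))))
  v[!is.finite(v) | v < var_floor] <- var_floor
  mu[!is.finite(mu)] <- NA
  pri <- as.numeric(table(factor(y, levels = labs))) / length(y)
  structure(list(mu = mu, var = v, prior = pri, labels = labs),
            class = "gaussian_nb")
}

#' @rdname nb_fit
#' @param model a fitted `gaussian_nb`.
#' @param x_new feature vector (length = n features; `NA` allowed).
#' @return `nb_predict` returns a list with `class` and `posterior`
#'   (named, sums to 1).
#' @export
nb_predict <- function(model, x_new) {
  stopifnot(inherits(model, "gaussian_nb"),
            length(x_new) == ncol(model$mu))
  ll <- vapply(seq_along(model$labels), function(ci) {
    ok <- !is.na(x_new) & !is.na(model$mu[ci, ])
    if (!any(ok)) return(-Inf)
    sum(stats::dnorm(x_new[ok], model$mu[ci, ok],
                     sqrt(model$var[ci, ok]), log = TRUE))
  }, numeric(1)) + log(model$prior)
  m <- max(ll)
  post <- exp(ll - m)
  post <- post / sum(post)
  names(post) <- model$labels
  list(class = model$labels[which.max(post)], posterior = post)
}

# Stratified fold assignment: per class, shuffled indices dealt round-robin.
stratified_folds <- function(y, folds, seed) {
  if (any(table(y) < folds))
    stop("every class needs at least `folds` trials for stratified ",
         folds, "-fold cross-validation", call. = FALSE)
  set.seed(seed)
  fold <- integer(length(y))
  for (l in unique(y)) {
    idx <- sample(which(y == l))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# Internal: latency feature matrix (trials x channels) for a dataset.
latency_features <- function(dataset, feature = "peak", window_ms = 30,
                             step_ms = 1, k = 3, response_window = NULL) {
  rt <- compute_rates(dataset, window_ms, step_ms)
  lt <- latency_table(rt, response_window = response_window, k = k)
  col <- paste0(feature, "_ms")
  nc <- dataset$meta$n_channels
  ids <- dataset$trials$trial_id
  m <- matrix(NA_real_, length(ids), nc)
  m[cbind(match(lt$trial_id, ids), lt$channel_id)] <- lt[[col]]
  m
}

# Internal: per-channel spike counts in [0, cutoff_ch) per trial.
latency_cutoff_counts <- function(dataset, cutoffs_ms) {
  ids <- dataset$trials$trial_id
  nc <- dataset$meta$n_channels
  spk <- dataset$spikes
  counts <- matrix(0, length(ids), nc)
  for (ch in seq_len(nc)) {
    sel <- spk$channel_id == ch & spk$time_ms >= 0 &
      spk$time_ms < cutoffs_ms[ch]
    if (any(sel))
      counts[, ch] <- as.numeric(table(factor(spk$trial_id[sel],
                                              levels = ids)))
  }
  counts
}

# Internal: mean-rate feature matrix over a response window.
rate_features <- function(dataset, response_window = c(0, 300)) {
  spk <- dataset$spikes
  keep <- spk$time_ms >= response_window[1] & spk$time_ms < response_window[2]
  spk <- spk[keep, , drop = FALSE]
  ids <- dataset$trials$trial_id
  nc <- dataset$meta$n_channels
  m <- matrix(0, length(ids), nc)
  if (nrow(spk)) {
    tab <- table(factor(spk$trial_id, levels = ids),
                 factor(spk$channel_id, levels = seq_len(nc)))
    m <- unclass(tab) / diff(response_window) * 1000
  }
  m
}

#' Cross-validated decoding of stimulus identity
#'
#' Stratified k-fold cross-validation of one of three population decoders:
#' `"rank"` (rank-template matching of latency vectors), `"nb_latency"`
#' (Gaussian naive Bayes on latency vectors), `"nb_rate"` (Gaussian naive
#' Bayes on mean firing rates in a response window).  Templates and models
#' are fitted on the training folds only; abstentions count as errors.
#'
#' @param dataset a [spike_dataset()] (typically restricted to one ramp /
#'   intensity condition with [subset_trials()]).
#' @param decoder `"rank"`, `"nb_latency"`, or `"nb_rate"`.
#' @param feature latency feature, `"peak"` or `"onset"`.
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param window_ms,step_ms rate-estimation windows for latency features.
#' @param response_window for `"nb_rate"`, the rate-integration window; for
#'   latency decoders, the epoch searched for the peak/onset (default: the
#'   whole post-onset trace).
#' @param features optional precomputed trials x features matrix, bypassing
#'   feature extraction (used for label-permutation nulls).
#' @param labels optional label vector overriding `trials$stimulus_id`.
#' @return a `decoding_result`: `accuracy_pct`, `fold_accuracies`,
#'   `confusion` (true x predicted), `chance_level_pct`, `decoder`.
#' @export
crossval_accuracy <- function(dataset, decoder = c("rank", "nb_latency", "nb_rate"),
                              feature = c("peak", "onset"), folds = 10,
                              seed = 1L, window_ms = 30, step_ms = 1,
                              response_window = NULL,
                              features = NULL, labels = NULL) {
  decoder <- match.arg(decoder)
  feature <- match.arg(feature)
  y <- if (is.null(labels)) dataset$trials$stimulus_id else labels
  x <- if (!is.null(features)) features
  else if (decoder == "nb_rate")
    rate_features(dataset, response_window %||% c(0, 300))
  else latency_features(dataset, feature, window_ms, step_ms,
                        response_window = response_window)
  decode_features(x, y, decoder, folds, seed)
}

# Core CV loop on a precomputed feature matrix.
decode_features <- function(x, y, decoder, folds = 10, seed = 1L) {
  fold <- stratified_folds(y, folds, seed)
  labs <- sort(unique(y))
  pred <- y
  pred[] <- NA
  for (f in seq_len(folds)) {
    tr <- fold != f
    te <- which(!tr)
    if (decoder == "rank") {
      tpl <- build_rank_templates(x[tr, , drop = FALSE], y[tr])
      for (i in te)
        pred[i] <- tryCatch(rank_decode(x[i, ], tpl),
                            error = function(e) NA)  # too few defined -> abstain
    } else {
      mdl <- nb_fit(x[tr, , drop = FALSE], y[tr])
      for (i in te) pred[i] <- nb_predict(mdl, x[i, ])$class
    }
  }
  correct <- !is.na(pred) & pred == y
  fold_acc <- vapply(seq_len(folds), function(f)
    100 * mean(correct[fold == f]), numeric(1))
  conf <- table(true = factor(y, labs), predicted = factor(pred, labs))
  structure(list(accuracy_pct = 100 * mean(correct),
                 fold_accuracies = fold_acc,
                 confusion = conf,
                 chance_level_pct = 100 / length(labs),
                 n_trials = length(y),
                 decoder = decoder),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result [%s]: %.2f%% (chance %.2f%%, %d trials, %d folds)\n",
              x$decoder, x$accuracy_pct, x$chance_level_pct, x$n_trials,
              length(x$fold_accuracies)))
  invisible(x)
}

#' Decoding accuracy as a function of the number of fastest channels
#'
#' Channels are ordered by their global mean latency (over all trials and
#' stimuli); for each `k` the naive-Bayes latency decoder is restricted to
#' the `k` fastest channels.  Reported alongside is the mean latency of the
#' included channels, i.e. the time by which their responses have occurred.
#'
#' @inheritParams crossval_accuracy
#' @param k_values numbers of fastest channels to include (clipped with a
#'   warning when exceeding the channel count).
#' @return data.frame with `k`, `accuracy_pct`, `mean_latency_ms`.
#' @export
fastest_channels_curve <- function(dataset, feature = c("peak", "onset"),
                                   k_values = NULL, folds = 10, seed = 1L,
                                   window_ms = 30, step_ms = 1) {
  feature <- match.arg(feature)
  lat <- latency_features(dataset, feature, window_ms, step_ms)
  nc <- ncol(lat)
  if (is.null(k_values)) k_values <- seq_len(nc)
  if (any(k_values > nc)) {
    warning("k > n_channels clipped to ", nc)
    k_values <- pmin(k_values, nc)
  }
  glat <- colMeans(lat, na.rm = TRUE)
  ord <- order(glat)
  y <- dataset$trials$stimulus_id
  out <- lapply(unique(k_values), function(k) {
    ch <- ord[seq_len(k)]
    res <- decode_features(lat[, ch, drop = FALSE], y, "nb_latency",
                           folds, seed)
    data.frame(k = k, accuracy_pct = res$accuracy_pct,
               mean_latency_ms = mean(glat[ch]))
  })
  do.call(rbind, out)
}

#' Rate-based counterpart of the fastest-channels curve
#'
#' Identical channel ordering and latency cutoffs as
#' [fastest_channels_curve()], but the decoder input is the firing rate of
#' each included channel summed between stimulus onset and that channel's
#' global mean latency, making the two curves directly comparable.
#'
#' @inheritParams fastest_channels_curve
#' @return data.frame with `k`, `accuracy_pct`, `mean_latency_ms`.
#' @export
rate_equivalent_curve <- function(dataset, feature = c("peak", "onset"),
                                  k_values = NULL, folds = 10, seed = 1L,
                                  window_ms = 30, step_ms = 1) {
  feature <- match.arg(feature)
  lat <- latency_features(dataset, feature, window_ms, step_ms)
  nc <- ncol(lat)
  if (is.null(k_values)) k_values <- seq_len(nc)
  if (any(k_values > nc)) {
    warning("k > n_channels clipped to ", nc)
    k_values <- pmin(k_values, nc)
  }
  glat <- colMeans(lat, na.rm = TRUE)
  ord <- order(glat)
  y <- dataset$trials$stimulus_id
  counts <- latency_cutoff_counts(dataset, glat)
  out <- lapply(unique(k_values), function(k) {
    ch <- ord[seq_len(k)]
    res <- decode_features(counts[, ch, drop = FALSE], y, "nb_rate",
                           folds, seed)
    data.frame(k = k, accuracy_pct = res$accuracy_pct,
               mean_latency_ms = mean(glat[ch]))
  })
  do.call(rbind, out)
}

#' Time-resolved rate-vector decoding
#'
#' Trains an independent cross-validated naive-Bayes decoder on the
#' population rate vector of every time bin (default 100 ms windows moved in
#' 100 ms steps) and returns the accuracy time course.
#'
#' @inheritParams crossval_accuracy
#' @param window_ms,step_ms rate window and step (default 100/100 ms).
#' @return an `accuracy_series`: data.frame with `time_ms` (bin centers) and
#'   `accuracy_pct`, with `chance_level_pct` attribute.
#' @export
time_resolved_rate_decoding <- function(dataset, window_ms = 100,
                                        step_ms = 100, folds = 10, seed = 1L) {
  rt <- compute_rates(dataset, window_ms, step_ms)
  y <- dataset$trials$stimulus_id
  acc <- vapply(seq_along(rt$bin_centers_ms), function(b) {
    decode_features(rt$values[, , b, drop = TRUE], y, "nb_rate",
                    folds, seed)$accuracy_pct
  }, numeric(1))
  out <- data.frame(time_ms = rt$bin_centers_ms, accuracy_pct = acc)
  attr(out, "chance_level_pct") <- 100 / length(unique(y))
  class(out) <- c("accuracy_series", "data.frame")
  out
}

#' Decay slope of a decoding-accuracy time course
#'
#' Least-squares slope of accuracy versus time over the descending phase of
#' the curve, operationalized as the interval from the accuracy peak (first
#' bin attaining the maximum) to the end of the plateau period.
#'
#' @param series an `accuracy_series` (or data.frame with `time_ms`,
#'   `accuracy_pct`).
#' @param plateau_end_ms end of the descending interval (ms).
#' @return list with `slope_pct_per_s`, `interval_ms`, `n_bins`.
#' @export
decay_slope <- function(series, plateau_end_ms) {
  s <- series[series$time_ms <= plateau_end_ms, , drop = FALSE]
  if (!nrow(s)) stop("no bins before plateau_end_ms", call. = FALSE)
  pk <- which.max(s$accuracy_pct)
  d <- s[pk:nrow(s), , drop = FALSE]
  if (nrow(d) < 3)
    stop("fewer than 3 bins in the descending phase", call. = FALSE)
  b <- stats::lm.fit(cbind(1, d$time_ms / 1000), d$accuracy_pct)$coefficients
  list(slope_pct_per_s = unname(b[2]),
       interval_ms = c(d$time_ms[1], d$time_ms[nrow(d)]),
       n_bins = nrow(d))
}
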