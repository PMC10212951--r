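#' Configuration for the synthetic multi-unit-activity generator
#'
#' Builds and validates the parameter set that defines a simulated ramped
#' visual stimulation experiment: a multi-channel recording in which each
#' stimulus evokes a stimulus-specific sequence of transient firing-rate peaks
#' across channels, followed by slowly decaying sustained activity.
#'
#' The generator emulates the regime of awake-monkey MUA recordings during
#' ramped stimulus onset: trials aligned to stimulus onset (t = 0), a
#' pre-stimulus baseline, ramp phases of 0 (step onset) / fast / slow, and a
#' plateau.  Sequences dilate sub-proportionally with ramp duration: the span
#' multiplier for ramp duration `R` relative to step onset is
#' `(1 + R/R_max)^e` with `e = dilation_exponent * log(2)/log(4/3)`, so that
#' doubling the ramp duration (from `R_max/2` to `R_max`) multiplies the span
#' by exactly `2^dilation_exponent`.  The default exponents reproduce span and
#' latency ratios of 1.56 and 1.3 between the slow and fast ramp.
#'
#' `prior_match` models how well a stimulus category conforms to the priors
#' assumed stored in cortical connectivity (1 = natural-like, 0 =
#' scrambled-like): trial-to-trial latency jitter SD is scaled by
#' `(1.5 - prior_match)` and the persistence time constant of the
#' stimulus-specific sustained-rate deviation by `(0.5 + prior_match)`.
#'
#' @param n_channels number of recording channels (>= n_stimuli).
#' @param n_stimuli number of distinct stimuli (>= 2).
#' @param n_trials_per_condition trials per (stimulus, ramp, intensity) cell.
#' @param ramp_durations_ms ramp durations in ms; 0 means step onset.
#' @param intensities maximal stimulus intensities (alpha fractions in (0,1]).
#' @param base_latency_ms earliest mean transient latency in the step-onset
#'   condition (ms).
#' @param base_span_ms latency span of the sequence in the step-onset
#'   condition (ms).
#' @param dilation_exponent span dilation exponent in (0,1]; doubling the
#'   ramp duration multiplies the sequence span by `2^dilation_exponent`.
#' @param latency_dilation_exponent like `dilation_exponent` but applied to
#'   the sequence onset latency.
#' @param latency_jitter_ms SD of trial-to-trial latency noise (ms) before
#'   the `prior_match` scaling.
#' @param peak_rate_hz amplitude of the transient rate bump at full intensity.
#' @param baseline_rate_hz spontaneous rate.
#' @param sustained_rate_hz mean sustained rate during the plateau.
#' @param persistence_tau_ms decay time constant of the stimulus-specific
#'   sustained-rate deviation before the `prior_match` scaling.
#' @param prior_match category parameter in \[0,1\], see Details.
#' @param trial_duration_ms post-onset recording duration (ms).
#' @param baseline_ms pre-stimulus baseline duration (ms).
#' @param transient_sd_ms SD of the Gaussian transient bump (ms).
#' @param category label stored with every trial (e.g. "natural").
#' @param seed integer seed; identical configs generate identical datasets.
#' @return an object of class `synth_config`.
#' @seealso [generate_dataset()]
#' @export
synth_config <- function(n_channels = 64,
                         n_stimuli = 3,
                         n_trials_per_condition = 20,
                         ramp_durations_ms = c(0, 500, 1000),
                         intensities = c(0.1, 0.3),
                         base_latency_ms = 150,
                         base_span_ms = 120,
                         dilation_exponent = log2(1.56),
                         latency_dilation_exponent = log2(1.3),
                         latency_jitter_ms = 10,
                         peak_rate_hz = 50,
                         baseline_rate_hz = 5,
                         sustained_rate_hz = 10,
                         persistence_tau_ms = 400,
                         prior_match = 1,
                         trial_duration_ms = 1800,
                         baseline_ms = 500,
                         transient_sd_ms = 15,
                         category = "natural",
                         seed = 1L) {
  cfg <- list(
    n_channels = as.integer(n_channels),
    n_stimuli = as.integer(n_stimuli),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    ramp_durations_ms = as.numeric(ramp_durations_ms),
    intensities = as.numeric(intensities),
    base_latency_ms = base_latency_ms,
    base_span_ms = base_span_ms,
    dilation_exponent = dilation_exponent,
    latency_dilation_exponent = latency_dilation_exponent,
    latency_jitter_ms = latency_jitter_ms,
    peak_rate_hz = peak_rate_hz,
    baseline_rate_hz = baseline_rate_hz,
    sustained_rate_hz = sustained_rate_hz,
    persistence_tau_ms = persistence_tau_ms,
    prior_match = prior_match,
    trial_duration_ms = trial_duration_ms,
    baseline_ms = baseline_ms,
    transient_sd_ms = transient_sd_ms,
    category = as.character(category),
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  num <- cfg[!(names(cfg) %in% "category")]
  if (!all(vapply(num, function(x) all(is.finite(x)), logical(1))))
    stop("synth_config: all numeric fields must be finite", call. = FALSE)
  durs <- c(cfg$ramp_durations_ms, cfg$base_latency_ms, cfg$base_span_ms,
            cfg$latency_jitter_ms, cfg$persistence_tau_ms,
            cfg$trial_duration_ms, cfg$baseline_ms, cfg$transient_sd_ms)
  rates <- c(cfg$peak_rate_hz, cfg$baseline_rate_hz, cfg$sustained_rate_hz)
  if (any(durs < 0) || any(rates < 0))
    stop("synth_config: durations and rates must be non-negative", call. = FALSE)
  if (cfg$prior_match < 0 || cfg$prior_match > 1)
    stop("synth_config: prior_match must lie in [0, 1]", call. = FALSE)
  if (cfg$dilation_exponent <= 0 || cfg$dilation_exponent > 1 ||
      cfg$latency_dilation_exponent <= 0 || cfg$latency_dilation_exponent > 1)
    stop("synth_config: dilation exponents must lie in (0, 1]", call. = FALSE)
  if (cfg$n_stimuli < 2 || cfg$n_channels < cfg$n_stimuli)
    stop("synth_config: need n_channels >= n_stimuli >= 2", call. = FALSE)
  if (any(cfg$intensities <= 0) || any(cfg$intensities > 1))
    stop("synth_config: intensities must lie in (0, 1]", call. = FALSE)
  if (cfg$transient_sd_ms <= 0)
    stop("synth_config: transient_sd_ms must be positive", call. = FALSE)
  invisible(cfg)
}

#' Sub-proportional ramp dilation multiplier
#'
#' Span (or latency) multiplier applied to a condition with ramp duration
#' `ramp_ms`, relative to the step-onset condition, given the maximal ramp
#' duration `r_max`.  The multiplier is `(1 + ramp/r_max)^e` with
#' `e = exponent * log(2)/log(4/3)`, normalized so that the multiplier is 1
#' at ramp 0 and the ratio between ramps `r_max` and `r_max/2` is
#' exactly `2^exponent`.
#'
#' @param ramp_ms ramp duration(s), ms.
#' @param r_max maximal ramp duration of the experiment, ms.
#' @param exponent dilation exponent in (0,1].
#' @return numeric multiplier(s) >= 1.
#' @export
ramp_multiplier <- function(ramp_ms, r_max, exponent) {
  if (r_max <= 0) return(rep(1, length(ramp_ms)))
  e <- exponent * log(2) / log(4 / 3)
  (1 + ramp_ms / r_max)^e
}

#' Deterministic per-channel rate profile of the generator
#'
#' Evaluates the noise-free (zero-jitter) firing-rate intensity function
#' lambda(t) for one channel and stimulus under a given condition, on an
#' arbitrary time grid.  This is the function whose inhomogeneous-Poisson
#' realizations [generate_dataset()] draws, and serves as the analytic
#' reference for expected spike counts.
#'
#' @param t_ms time points (ms, t = 0 stimulus onset).
#' @param config a [synth_config()].
#' @param offset_ms the channel's ground-truth latency offset (ms).
#' @param sustained_dev_hz the channel's stimulus-specific sustained deviation.
#' @param ramp_ms ramp duration of the condition.
#' @param intensity stimulus intensity of the condition.
#' @param jitter_ms optional additive latency displacement for this trial.
#' @return rate in spikes/s at each `t_ms`.
#' @export
synth_rate_profile <- function(t_ms, config, offset_ms, sustained_dev_hz,
                               ramp_ms, intensity, jitter_ms = 0) {
  r_max <- max(config$ramp_durations_ms)
  m_span <- ramp_multiplier(ramp_ms, r_max, config$dilation_exponent)
  m_lat <- ramp_multiplier(ramp_ms, r_max, config$latency_dilation_exponent)
  amp <- intensity / max(config$intensities)
  center <- config$base_latency_ms * m_lat + offset_ms * m_span +
    (1 - amp) * 30 + jitter_ms
  bump <- amp * config$peak_rate_hz *
    exp(-(t_ms - center)^2 / (2 * config$transient_sd_ms^2))
  post <- t_ms >= center
  sust <- numeric(length(t_ms))
  tau <- config$persistence_tau_ms * (0.5 + config$prior_match)
  if (any(post)) {
    dt <- t_ms[post] - center
    sust[post] <- amp * (config$sustained_rate_hz +
                           sustained_dev_hz * exp(-dt / tau))
  }
  rate <- config$baseline_rate_hz + bump + sust
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("synthetic rate profile is negative or non-finite; check config",
         call. = FALSE)
  rate
}

#' Generate a synthetic trial-aligned spike dataset
#'
#' Draws an inhomogeneous-Poisson spike dataset under the response model of
#' [synth_config()]: every channel's rate is baseline + a Gaussian transient
#' bump at a stimulus- and channel-specific latency (dilated sub-proportionally
#' with ramp duration, jittered trial-to-trial) + a sustained component whose
#' stimulus-specific deviation decays with the persistence time constant.
#' Ground-truth latency offsets per stimulus are random permutations of
#' equally spaced offsets spanning exactly `base_span_ms`, so the sorted
#' latencies of the step-onset condition lie on an exact line.
#'
#' Spikes are drawn with 1 ms resolution: the rate is evaluated piecewise
#' constant on a 1 ms grid, counts per bin are Poisson, and spike times are
#' uniform within their bin (exact for the piecewise-constant intensity).
#'
#' @param config a [synth_config()].
#' @return a `spike_dataset` (see [spike_dataset()]) with an attached
#'   `ground_truth` element: `latency_offsets_ms` and `sustained_dev_hz`
#'   (`n_stimuli x n_channels` matrices) and the per-ramp span/latency
#'   multipliers.
#' @examples
#' d <- generate_dataset(synth_config(n_channels = 8, n_trials_per_condition = 2,
#'                                    ramp_durations_ms = c(0, 500),
#'                                    intensities = 0.3, trial_duration_ms = 800,
#'                                    baseline_ms = 200))
#' head(d$spikes)
#' @export
generate_dataset <- function(config) {
  validate_synth_config(unclass(config))
  set.seed(config$seed)
  ns <- config$n_stimuli
  nc <- config$n_channels
  offsets <- t(vapply(seq_len(ns), function(s) {
    sample(seq(0, config$base_span_ms, length.out = nc))
  }, numeric(nc)))
  sdev <- matrix(stats::runif(ns * nc, -0.8, 0.8) * config$sustained_rate_hz,
                 nrow = ns)
  jit_sd <- config$latency_jitter_ms * (1.5 - config$prior_match)

  conds <- expand.grid(stimulus_id = seq_len(ns),
                       ramp_ms = config$ramp_durations_ms,
                       intensity = config$intensities,
                       KEEP.OUT.ATTRS = FALSE)
  ntr <- config$n_trials_per_condition
  n_trials <- nrow(conds) * ntr
  grid <- seq(-config$baseline_ms, config$trial_duration_ms - 1, by = 1)

  trials <- data.frame(
    trial_id = seq_len(n_trials),
    stimulus_id = rep(conds$stimulus_id, each = ntr),
    category = config$category,
    ramp_ms = rep(conds$ramp_ms, each = ntr),
    intensity = rep(conds$intensity, each = ntr),
    plateau_ms = config$trial_duration_ms - rep(conds$ramp_ms, each = ntr)
  )

  spk <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    s <- trials$stimulus_id[tr]
    jit <- if (jit_sd > 0) stats::rnorm(nc, 0, jit_sd) else numeric(nc)
    per_ch <- vector("list", nc)
    for (ch in seq_len(nc)) {
      lam <- synth_rate_profile(grid, config, offsets[s, ch], sdev[s, ch],
                                trials$ramp_ms[tr], trials$intensity[tr],
                                jit[ch])
      counts <- stats::rpois(length(grid), lam * 1e-3)
      tot <- sum(counts)
      if (tot > 0) {
        t_spk <- rep(grid, counts) + stats::runif(tot)
        per_ch[[ch]] <- data.frame(trial_id = tr, channel_id = ch,
                                   time_ms = sort(t_spk))
      }
    }
    spk[[tr]] <- do.call(rbind, per_ch)
  }
  spikes <- do.call(rbind, spk)
  if (is.null(spikes))
    spikes <- data.frame(trial_id = integer(), channel_id = integer(),
                         time_ms = numeric())
  rownames(spikes) <- NULL

  r_max <- max(config$ramp_durations_ms)
  gt <- list(
    latency_offsets_ms = offsets,
    sustained_dev_hz = sdev,
    span_multiplier = stats::setNames(
      ramp_multiplier(config$ramp_durations_ms, r_max, config$dilation_exponent),
      config$ramp_durations_ms),
    latency_multiplier = stats::setNames(
      ramp_multiplier(config$ramp_durations_ms, r_max,
                      config$latency_dilation_exponent),
      config$ramp_durations_ms)
  )
  spike_dataset(spikes, trials,
                meta = list(n_channels = nc,
                            t_min_ms = -config$baseline_ms,
                            t_max_ms = config$trial_duration_ms,
                            alignment = "t=0 = stimulus onset",
                            units = "ms",
                            seed = config$seed),
                ground_truth = gt, config = config)
}

# 7x7 glyph bitmaps for the digit stimuli (rows are strings of 0/1).
.digit_glyphs <- list(
  "0" = c("0111110", "1100011", "1100011", "1100011", "1100011", "1100011", "0111110"),
  "1" = c("0001100", "0011100", "0001100", "0001100", "0001100", "0001100", "0111111"),
  "2" = c("0111110", "1100011", "0000011", "0001110", "0111000", "1100000", "1111111"),
  "3" = c("0111110", "1100011", "0000011", "0011110", "0000011", "1100011", "0111110"),
  "4" = c("0000110", "0001110", "0011010", "0110010", "1111111", "0000010", "0000010"),
  "5" = c("1111111", "1100000", "1111110", "0000011", "0000011", "1100011", "0111110"),
  "6" = c("0011110", "0110000", "1100000", "1111110", "1100011", "1100011", "0111110"),
  "7" = c("1111111", "0000011", "0000110", "0001100", "0011000", "0011000", "0011000"),
  "8" = c("0111110", "1100011", "1100011", "0111110", "1100011", "1100011", "0111110"),
  "9" = c("0111110", "1100011", "1100011", "0111111", "0000011", "0000110", "0111100")
)

#' Deterministic digit-like stimulus image
#'
#' Renders a binary digit glyph on a `size x size` grid.  Glyphs are defined
#' on a 7x7 canvas and resampled (nearest neighbor) for other sizes, so the
#' same label always yields the same image.
#'
#' @param label one of `"0" ... "9"`.
#' @param size grid side length, >= 5.
#' @return a `stimulus_image`: list with `pixels` (`size x size` matrix in
#'   \{0,1\}) and `label`.
#' @export
make_digit_image <- function(label, size = 7) {
  label <- as.character(label)
  if (!label %in% names(.digit_glyphs))
    stop("unknown glyph label '", label, "'; available: ",
         paste(names(.digit_glyphs), collapse = ", "), call. = FALSE)
  if (size < 5) stop("size must be >= 5", call. = FALSE)
  g <- .digit_glyphs[[label]]
  base <- do.call(rbind, lapply(g, function(row) {
    as.integer(strsplit(row, "")[[1]])
  }))
  idx <- pmin(7L, pmax(1L, round((seq_len(size) - 0.5) / size * 7 + 0.5)))
  px <- base[idx, idx, drop = FALSE]
  structure(list(pixels = px, label = label), class = "stimulus_image")
}

#' Phase-scramble an image
#'
#' Adds uniform random noise to the Fourier phase spectrum of a 2-D image
#' while preserving the amplitude spectrum exactly.  The phase perturbation
#' is antisymmetrized so Hermitian symmetry holds and the inverse transform
#' is real; the DC component (and any self-conjugate frequency) is left
#' untouched.  The result is clipped to \[0, 1\].
#'
#' @param image a `stimulus_image` or a numeric matrix with values in \[0,1\].
#' @param noise_level fraction in \[0,1\] of the full +/- pi phase
#'   perturbation.
#' @param seed integer seed for the phase noise.
#' @param clip clip the output to \[0,1\] (default); set `FALSE` to obtain the
#'   raw inverse transform, whose amplitude spectrum equals the input's.
#' @return an object of the same kind as the input (matrix in, matrix out).
#' @export
phase_scramble <- function(image, noise_level, seed = 1L, clip = TRUE) {
  is_img <- inherits(image, "stimulus_image")
  px <- if (is_img) image$pixels else image
  if (!is.matrix(px) || !is.numeric(px))
    stop("phase_scramble requires a 2-D numeric matrix", call. = FALSE)
  if (noise_level < 0 || noise_level > 1)
    stop("noise_level must lie in [0, 1]", call. = FALSE)
  n <- nrow(px); m <- ncol(px)
  set.seed(seed)
  theta <- matrix(stats::runif(n * m, -pi, pi) * noise_level, n, m)
  # antisymmetrize: phi(-k) = -phi(k); conjugate index of (i,j) (1-based)
  ci <- c(1L, rev(seq_len(n)[-1]))
  cj <- c(1L, rev(seq_len(m)[-1]))
  # difference of two +/- pi*noise_level draws: antisymmetric by
  # construction, and at noise_level 1 the expected output-input spectral
  # correlation per frequency, E[cos(phi)], is exactly 0
  phi <- theta - theta[ci, cj, drop = FALSE]
  f <- stats::fft(px)
  out <- Re(stats::fft(f * exp(1i * phi), inverse = TRUE)) / (n * m)
  if (clip) {
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  if (is_img)
    structure(list(pixels = out, label = paste0(image$label, "-scrambled")),
              class = "stimulus_image")
  else out
}
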