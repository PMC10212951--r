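# Shared fixtures: small generator configs and a memoized trained network.

# Strong-response, zero-jitter config: latencies are recovered almost
# noiselessly, so orderings and decoders behave deterministically.
clean_config <- function(n_channels = 16, n_stimuli = 3, n_trials = 20,
                         ramps = 500, seed = 1L, ...) {
  args <- list(n_channels = n_channels, n_stimuli = n_stimuli,
               n_trials_per_condition = n_trials,
               ramp_durations_ms = ramps, intensities = 0.3,
               base_latency_ms = 120, base_span_ms = 120,
               latency_jitter_ms = 0, peak_rate_hz = 250,
               baseline_rate_hz = 0, sustained_rate_hz = 0,
               trial_duration_ms = 900, baseline_ms = 200, seed = seed)
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# Moderate-noise config for decoder null tests.
noisy_config <- function(seed = 1L, ...) {
  synth_config(n_channels = 16, n_stimuli = 3, n_trials_per_condition = 20,
               ramp_durations_ms = 500, intensities = 0.3,
               base_latency_ms = 120, base_span_ms = 60,
               latency_jitter_ms = 40, peak_rate_hz = 100,
               baseline_rate_hz = 3, sustained_rate_hz = 10,
               trial_duration_ms = 900, baseline_ms = 300, seed = seed, ...)
}

# Category-ordering study conditions (paired across prior-match levels).
category_config <- function(prior_match, seed, category) {
  synth_config(n_channels = 32, n_stimuli = 3, n_trials_per_condition = 30,
               ramp_durations_ms = 500, intensities = 0.3,
               base_latency_ms = 120, base_span_ms = 60,
               latency_jitter_ms = 120, peak_rate_hz = 120,
               baseline_rate_hz = 3, sustained_rate_hz = 20,
               persistence_tau_ms = 300, prior_match = prior_match,
               trial_duration_ms = 1000, baseline_ms = 300,
               category = category, seed = seed)
}

# One fully trained reference network (expensive; trained once per session).
.snn_cache <- new.env(parent = emptyenv())
trained_reference_net <- function() {
  if (is.null(.snn_cache$net)) {
    net <- build_network(seed = 1)
    tr <- train_network(net, make_digit_image("0"), n_trials = 200,
                        seed = 100)
    .snn_cache$untrained <- net
    .snn_cache$net <- tr$net
    .snn_cache$weight_change <- tr$weight_change
  }
  list(untrained = .snn_cache$untrained, trained = .snn_cache$net,
       weight_change = .snn_cache$weight_change)
}
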