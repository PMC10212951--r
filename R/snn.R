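#' Build a recurrent Izhikevich spiking network
#'
#' Constructs a randomly connected recurrent network of regular-spiking (RS,
#' excitatory) and fast-spiking (FS, inhibitory) Izhikevich neurons with a
#' 4:1 E/I ratio.  Per-neuron heterogeneity follows the standard recipe: for
#' RS cells `(a,b) = (0.02, 0.2)` and `(c,d) = (-65, 8) + (15, -6) r^2`; for
#' FS cells `(a,b) = (0.02, 0.25) + (0.08, -0.05) r^2` and `(c,d) = (-65, 2)`,
#' with `r ~ U[0,1]` drawn once per neuron.  Connectivity is Bernoulli with
#' probability `p_connect` (no self-connections), initial weights uniform on
#' \[0,1\].  A subset of excitatory neurons receives the external image
#' input (one pixel per neuron).
#'
#' @param seed integer seed (connectivity, weights, heterogeneity).
#' @param n_exc,n_inh numbers of excitatory / inhibitory neurons (default
#'   200 / 50, i.e. N = 250 at 4:1).
#' @param p_connect connection probability (default 0.4).
#' @param n_input number of excitatory input neurons (default 49, a 7x7
#'   pixel grid).
#' @param dt_ms integration step, 0.5 or 1 ms (default 0.5).
#' @param delay_ms uniform synaptic transmission delay (default 1 ms).
#' @param input_gain current injected per unit pixel intensity at full ramp.
#' @param noise_amp_exc,noise_amp_inh SD of the per-step Gaussian background
#'   current, calibrated for a spontaneous rate of roughly 1-3 Hz.
#' @param exc_gain,inh_gain scaling of recurrent excitatory / inhibitory
#'   synaptic currents.
#' @param stdp list of plasticity constants: `tau_ms` (trace time constant
#'   for potentiation and depression), `lr` (learning rate), `w_max`,
#'   `w_min` (lower bound kept strictly positive so weights stay in
#'   `(0, w_max]`).
#' @return an `izh_network` object.
#' @export
build_network <- function(seed = 1L, n_exc = 200, n_inh = 50,
                          p_connect = 0.4, n_input = 49,
                          dt_ms = 0.5, delay_ms = 1,
                          input_gain = 20, noise_amp_exc = 5,
                          noise_amp_inh = 2, exc_gain = 0.3, inh_gain = 1,
                          stdp = list(tau_ms = 20, lr = 0.02,
                                      w_max = 2, w_min = 1e-6)) {
  if (n_exc != 4 * n_inh)
    stop("excitatory:inhibitory ratio must be 4:1", call. = FALSE)
  if (n_input > n_exc)
    stop("input subset must fit within the excitatory population",
         call. = FALSE)
  if (!dt_ms %in% c(0.5, 1))
    stop("dt_ms must be 0.5 or 1", call. = FALSE)
  set.seed(seed)
  n <- n_exc + n_inh
  exc <- c(rep(TRUE, n_exc), rep(FALSE, n_inh))
  r <- stats::runif(n)
  a <- ifelse(exc, 0.02, 0.02 + 0.08 * r^2)
  b <- ifelse(exc, 0.2, 0.25 - 0.05 * r^2)
  cc <- ifelse(exc, -65 + 15 * r^2, -65)
  d <- ifelse(exc, 8 - 6 * r^2, 2)
  mask <- matrix(stats::runif(n * n) < p_connect, n, n)
  diag(mask) <- FALSE
  w <- matrix(stats::runif(n * n), n, n) * mask
  input_idx <- sort(sample(which(exc), n_input))
  structure(list(
    n = n, n_exc = n_exc, n_inh = n_inh, exc = exc,
    params = list(a = a, b = b, c = cc, d = d, r = r),
    mask = mask, w = w,
    plastic_mask = mask & outer(exc, exc, `&`),  # E->E synapses
    input_idx = input_idx,
    dt_ms = dt_ms, delay_steps = max(1L, as.integer(round(delay_ms / dt_ms))),
    input_gain = input_gain,
    noise_amp_exc = noise_amp_exc, noise_amp_inh = noise_amp_inh,
    exc_gain = exc_gain, inh_gain = inh_gain,
    stdp = stdp, seed = seed
  ), class = "izh_network")
}

#' @export
print.izh_network <- function(x, ...) {
  cat("izh_network:", x$n_exc, "RS +", x$n_inh, "FS neurons,",
      sprintf("density %.3f,", mean(x$mask)),
      length(x$input_idx), "input neurons, dt =", x$dt_ms, "ms\n")
  invisible(x)
}

#' One forward-Euler step of the Izhikevich dynamics
#'
#' Advances membrane potential `v` and recovery variable `u` by `dt` under
#' input current `I`:
#' `v' = 0.04 v^2 + 5 v + 140 - u + I`, `u' = a (b v - u)`.
#' Following the reference stepping convention, a 1 ms step integrates `v`
#' in two 0.5 ms half-steps (with `u` updated once); a 0.5 ms step uses a
#' single half-step.  Neurons with `v >= 30` are reported as spiking and
#' reset (`v <- c`, `u <- u + d`).  The spike test is applied to the state
#' *entering* the step, matching the reference implementation in which
#' resets happen before integration.
#'
#' @param v,u state vectors.
#' @param I input current per neuron.
#' @param a,b,c,d Izhikevich parameter vectors.
#' @param dt_ms 0.5 or 1.
#' @return list with `v`, `u`, `fired` (logical).
#' @export
izhikevich_step <- function(v, u, I, a, b, c, d, dt_ms = 0.5) {
  if (any(!is.finite(v)) || any(!is.finite(u)))
    stop("non-finite membrane state (v range ",
         paste(signif(range(v), 3), collapse = ".."), ")", call. = FALSE)
  fired <- v >= 30
  if (any(fired)) {
    v[fired] <- c[fired]
    u[fired] <- u[fired] + d[fired]
  }
  n_half <- if (dt_ms == 1) 2L else 1L
  for (i in seq_len(n_half))
    v <- v + 0.5 * (0.04 * v^2 + 5 * v + 140 - u + I)
  u <- u + dt_ms * a * (b * v - u)
  list(v = v, u = u, fired = fired)
}

#' Multiplicative STDP update from exponential spike traces
#'
#' All-to-all trace-based spike-timing-dependent plasticity with
#' multiplicative soft bounds, applied to E-to-E synapses only: when a
#' postsynaptic neuron fires, each of its existing excitatory afferents is
#' potentiated by `lr * (w_max - w) * x_pre`; when a presynaptic excitatory
#' neuron fires, each of its existing excitatory efferents is depressed by
#' `lr * w * x_post`.  `x_pre`/`x_post` are exponential traces (time
#' constant `tau_ms`) incremented by 1 at each spike of their neuron.
#' Weights are confined to `(w_min, w_max]` with `w_min > 0`; at
#' `w = w_max` the potentiation increment vanishes (soft-bound fixed
#' point).
#'
#' @param w weight matrix (pre x post).
#' @param plastic_mask logical matrix of plastic (E-to-E, existing)
#'   synapses.
#' @param fired logical vector of neurons spiking this step.
#' @param exc logical vector marking excitatory neurons.
#' @param x_pre,x_post trace vectors (before this step's increment).
#' @param stdp list with `lr`, `w_max`, `w_min`.
#' @return updated weight matrix.
#' @export
stdp_update <- function(w, plastic_mask, fired, exc, x_pre, x_post, stdp) {
  fe <- which(fired & exc)
  if (!length(fe)) return(w)
  eidx <- which(exc)
  # potentiation: pre trace onto synapses of just-fired posts
  sub <- w[eidx, fe, drop = FALSE]
  msk <- plastic_mask[eidx, fe, drop = FALSE]
  sub <- sub + stdp$lr * (stdp$w_max - sub) * x_pre[eidx] * msk
  w[eidx, fe] <- sub
  # depression: post trace onto synapses of just-fired pres
  sub <- w[fe, eidx, drop = FALSE]
  msk <- plastic_mask[fe, eidx, drop = FALSE]
  dep <- stdp$lr * sub *
    matrix(x_post[eidx], nrow = length(fe), ncol = length(eidx), byrow = TRUE)
  sub <- sub - dep * msk
  w[fe, eidx] <- sub
  # hard clip as a safety net; increments are bounded by construction
  pm <- plastic_mask[eidx, eidx]
  blk <- w[eidx, eidx]
  blk[pm] <- pmin(stdp$w_max, pmax(stdp$w_min, blk[pm]))
  w[eidx, eidx] <- blk
  w
}

#' Simulate one trial of the network
#'
#' Runs the network through a trial consisting of a baseline period, a
#' linear ramp of the stimulus input current from 0 to full gain over
#' `ramp_ms` (0 = step onset), and a plateau at full gain.  The stimulus is
#' a pixel image flattened onto the input neurons (one pixel each).  All
#' neurons receive independent Gaussian background-noise current throughout.
#' Plasticity (STDP) acts only when `plastic = TRUE`.
#'
#' Time is reported relative to stimulus onset (t = 0), so baseline spikes
#' have negative times.
#'
#' @param net an `izh_network`.
#' @param stimulus a `stimulus_image` or numeric vector/matrix of pixel
#'   intensities in \[0,1\], length equal to the input subset.
#' @param ramp_ms ramp duration (e.g. 0, 50, 100).
#' @param baseline_ms baseline before stimulus onset (default 100).
#' @param plateau_ms plateau duration at full gain (default 50).
#' @param plastic apply STDP during the trial.
#' @param seed seed for the background noise of this trial.
#' @param rate_cap_hz abort when the mean excitatory rate over the trial
#'   exceeds this cap (divergence guard).
#' @return list with `spikes` (data.frame `neuron`, `time_ms`), `net` (with
#'   updated weights when plastic), and `mean_exc_rate_hz`.
#' @export
run_trial <- function(net, stimulus, ramp_ms = 0, baseline_ms = 100,
                      plateau_ms = 50, plastic = FALSE, seed = NULL,
                      rate_cap_hz = 200) {
  px <- if (inherits(stimulus, "stimulus_image")) as.numeric(stimulus$pixels)
  else as.numeric(stimulus)
  if (length(px) != length(net$input_idx))
    stop("stimulus has ", length(px), " pixels but the network has ",
         length(net$input_idx), " input neurons", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dt <- net$dt_ms
  total_ms <- baseline_ms + ramp_ms + plateau_ms
  n_steps <- as.integer(round(total_ms / dt))
  n <- net$n
  p <- net$params
  v <- rep(-65, n)
  u <- p$b * v
  x_pre <- x_post <- numeric(n)
  decay <- exp(-dt / net$stdp$tau_ms)
  sgn <- ifelse(net$exc, net$exc_gain, -net$inh_gain)
  noise_sd <- ifelse(net$exc, net$noise_amp_exc, net$noise_amp_inh)
  w <- net$w
  buf <- vector("list", net$delay_steps)  # delayed spike index queue
  spk_t <- spk_n <- vector("list", n_steps)
  n_spikes <- 0L
  for (st in seq_len(n_steps)) {
    t_ms <- st * dt - baseline_ms   # time at end of step
    drive <- if (t_ms <= 0) 0
    else if (ramp_ms > 0 && t_ms < ramp_ms) t_ms / ramp_ms
    else 1
    I <- stats::rnorm(n, 0, noise_sd)
    if (drive > 0)
      I[net$input_idx] <- I[net$input_idx] + net$input_gain * drive * px
    arrived <- buf[[1L]]
    if (length(arrived))
      I <- I + colSums(w[arrived, , drop = FALSE] * sgn[arrived])
    stp <- izhikevich_step(v, u, I, p$a, p$b, p$c, p$d, dt)
    v <- stp$v; u <- stp$u
    fired <- stp$fired
    if (plastic && any(fired))
      w <- stdp_update(w, net$plastic_mask, fired, net$exc,
                       x_pre, x_post, net$stdp)
    x_pre <- x_pre * decay
    x_post <- x_post * decay
    if (any(fired)) {
      x_pre[fired] <- x_pre[fired] + 1
      x_post[fired] <- x_post[fired] + 1
      idx <- which(fired)
      spk_t[[st]] <- rep((st - 1) * dt - baseline_ms, length(idx))
      spk_n[[st]] <- idx
      n_spikes <- n_spikes + length(idx)
    }
    buf <- c(buf[-1L], list(which(fired)))
  }
  spikes <- data.frame(neuron = unlist(spk_n),
                       time_ms = unlist(spk_t))
  if (!nrow(spikes))
    spikes <- data.frame(neuron = integer(), time_ms = numeric())
  exc_rate <- sum(spikes$neuron <= net$n_exc) / net$n_exc / (total_ms / 1000)
  if (exc_rate > rate_cap_hz)
    stop(sprintf("network diverged: mean excitatory rate %.0f Hz > cap %.0f Hz",
                 exc_rate, rate_cap_hz), call. = FALSE)
  net$w <- w
  list(spikes = spikes, net = net, mean_exc_rate_hz = exc_rate)
}

#' Train the network on one stimulus with STDP
#'
#' Runs `n_trials` plastic trials of the training protocol (baseline then
#' step-onset stimulation, no ramp), carrying the weights across trials and
#' recording the weight-change norm per trial.  Weights stabilize after
#' roughly 200 trials: the multiplicative soft bounds drive E-to-E synapses
#' toward a stimulus-specific fixed-point structure.
#'
#' @param net an `izh_network`.
#' @param stimulus stimulus image / pixel vector (see [run_trial()]).
#' @param n_trials number of training trials (default 200).
#' @param baseline_ms,stim_ms training-trial phases (defaults 100 / 50 ms).
#' @param seed base seed; trial k uses `seed + k`.
#' @return list with `net` (trained), `weight_change` (Frobenius norm of the
#'   per-trial weight update), `mean_exc_rate_hz` per trial.
#' @export
train_network <- function(net, stimulus, n_trials = 200, baseline_ms = 100,
                          stim_ms = 50, seed = 1L) {
  wch <- rates <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    w_before <- net$w
    res <- run_trial(net, stimulus, ramp_ms = 0, baseline_ms = baseline_ms,
                     plateau_ms = stim_ms, plastic = TRUE, seed = seed + k)
    net <- res$net
    wch[k] <- sqrt(sum((net$w - w_before)^2))
    rates[k] <- res$mean_exc_rate_hz
  }
  list(net = net, weight_change = wch, mean_exc_rate_hz = rates)
}

#' Convert spike rasters of simulated test trials to a spike dataset
#'
#' Packs a list of [run_trial()] rasters into the standard
#' [spike_dataset()] container (neurons become channels), so the latency,
#' sequence, and decoding machinery runs unchanged on simulated data.
#'
#' @param rasters list of `spikes` data.frames from [run_trial()].
#' @param net the generating `izh_network`.
#' @param ramp_ms,plateau_ms,baseline_ms the protocol of these trials.
#' @param stimulus_id,category labels stored with every trial.
#' @return a `spike_dataset`.
#' @export
raster_to_dataset <- function(rasters, net, ramp_ms, plateau_ms = 50,
                              baseline_ms = 100, stimulus_id = 1,
                              category = "simulated") {
  spikes <- do.call(rbind, lapply(seq_along(rasters), function(i) {
    r <- rasters[[i]]
    if (!nrow(r)) return(NULL)
    data.frame(trial_id = i, channel_id = r$neuron, time_ms = r$time_ms)
  }))
  if (is.null(spikes))
    spikes <- data.frame(trial_id = integer(), channel_id = integer(),
                         time_ms = numeric())
  trials <- data.frame(trial_id = seq_along(rasters),
                       stimulus_id = stimulus_id, category = category,
                       ramp_ms = ramp_ms, intensity = 1,
                       plateau_ms = plateau_ms)
  spike_dataset(spikes, trials,
                meta = list(n_channels = net$n,
                            t_min_ms = -baseline_ms,
                            t_max_ms = ramp_ms + plateau_ms,
                            alignment = "t=0 = stimulus onset", units = "ms"))
}

#' Trial-mean peak latencies of simulated neurons
#'
#' Computes, for each neuron of a set, the peak latency of the
#' trial-averaged firing rate (short sliding windows) across a set of test
#' trials.
#'
#' @param rasters list of `spikes` data.frames from [run_trial()].
#' @param net the `izh_network`.
#' @param neurons neuron indices to evaluate (default: excitatory neurons
#'   without direct input).
#' @param ramp_ms,plateau_ms,baseline_ms protocol of the trials.
#' @param window_ms,step_ms rate-estimation windows (default 30/1).
#' @param k responsiveness gate in baseline SDs (default 0: any neuron with
#'   a positive trial-mean peak gets a latency).
#' @return named numeric vector of peak latencies (ms), `NA` where
#'   undefined.
#' @export
snn_peak_latencies <- function(rasters, net, neurons = NULL, ramp_ms,
                               plateau_ms = 50, baseline_ms = 100,
                               window_ms = 30, step_ms = 1, k = 0) {
  if (is.null(neurons))
    neurons <- setdiff(which(net$exc), net$input_idx)
  ds <- raster_to_dataset(rasters, net, ramp_ms, plateau_ms, baseline_ms)
  rt <- compute_rates(ds, window_ms, step_ms)
  psth <- apply(rt$values, c(2, 3), mean)   # neurons x bins, trial mean
  lat <- vapply(neurons, function(nn)
    peak_latency(psth[nn, ], rt$bin_centers_ms, k = k), numeric(1))
  stats::setNames(lat, neurons)
}

#' Inter-trial peak-latency dispersion of simulated neurons
#'
#' Measures the precision of a simulated response sequence: for every
#' evaluated neuron, the SD of its single-trial peak latencies across the
#' trials in which a latency is defined (the neuron fired).  Neurons with
#' fewer than `min_defined` such trials get `NA`.
#'
#' Networks differing in how many neurons respond reliably must be compared
#' on the *matched* neuron set (defined SD under both), otherwise newly
#' recruited, marginally responsive neurons bias the comparison; see the
#' methods vignette.
#'
#' @inheritParams snn_peak_latencies
#' @param min_defined minimal number of trials with a defined single-trial
#'   latency for a neuron's SD to be reported.
#' @return named numeric vector: per-neuron SD of single-trial peak
#'   latencies (ms), `NA` where the neuron is too unreliable.  The number of
#'   defined single-trial latencies per neuron is attached as attribute
#'   `n_defined`.
#' @export
snn_latency_dispersion <- function(rasters, net, neurons = NULL, ramp_ms,
                                   plateau_ms = 50, baseline_ms = 100,
                                   window_ms = 30, step_ms = 1,
                                   min_defined = 5) {
  if (is.null(neurons))
    neurons <- setdiff(which(net$exc), net$input_idx)
  ds <- raster_to_dataset(rasters, net, ramp_ms, plateau_ms, baseline_ms)
  rt <- compute_rates(ds, window_ms, step_ms)
  lt <- latency_table(rt, k = 0)
  lt <- lt[lt$channel_id %in% neurons, , drop = FALSE]
  per <- split(lt$peak_ms, factor(lt$channel_id, levels = neurons))
  sds <- vapply(per, function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= min_defined) stats::sd(x) else NA_real_
  }, numeric(1))
  structure(stats::setNames(sds, neurons),
            n_defined = vapply(per, function(x) sum(!is.na(x)), numeric(1)))
}

#' Orderliness of a simulated response sequence
#'
#' Sorts neurons by their trial-mean peak latency under a sorting condition
#' and computes the Pearson correlation between the evaluated condition's
#' latencies (in that order) and the sorted neuron index — a quantification
#' of how well the population response unfolds as an orderly sequence.
#' When sort and eval condition coincide this measures the linearity of the
#' sorted latency profile.
#'
#' @param lat_sort,lat_eval named latency vectors over the same neuron set
#'   (from [snn_peak_latencies()]); `NA`s are excluded pairwise.
#' @return list with `r`, `p_value`, `n` (number of neurons used).
#' @export
orderliness_correlation <- function(lat_sort, lat_eval) {
  stopifnot(length(lat_sort) == length(lat_eval))
  ok <- !is.na(lat_sort) & !is.na(lat_eval)
  if (sum(ok) < 10)
    stop("fewer than 10 responsive neurons", call. = FALSE)
  ls <- lat_sort[ok]; le <- lat_eval[ok]
  ord <- order(ls)
  ct <- stats::cor.test(seq_along(ord), le[ord])
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
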