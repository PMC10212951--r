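---
title: "Sequence coding, decoding, and the spiking-network model in rankseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence coding, decoding, and the spiking-network model in rankseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankseq)
```

## The scientific problem

When a visual stimulus appears, the channels of a multi-electrode recording
do not respond simultaneously: each multi-unit site has its own response
latency, and the resulting *sequence* of transient firing-rate peaks across
channels is stimulus-specific. If the stimulus intensity is ramped up slowly
instead of stepped on, the sequence stretches out in time — but
sub-proportionally, and with its rank order preserved. `rankseq` implements
the full analysis chain for this phenomenon:

1. **Preprocessing** — spike detection from filtered broadband traces and
   sliding-window firing-rate tensors.
2. **Sequences** — per-channel peak/onset latencies, and the line fit to
   rank-sorted latencies that summarizes a sequence by its *span* (latency
   difference between the fitted endpoints) and *center time* (fitted value
   at the middle rank).
3. **Decoding** — rank-order template matching (Spearman similarity),
   Gaussian naive-Bayes decoding of latency and rate vectors,
   fastest-channel curves, time-resolved decoding and its decay slope.
4. **Trajectories** — population state-space analysis: PCA projection for
   display, native-space distances, and a discriminability index.
5. **snn** — a 250-neuron recurrent Izhikevich network with multiplicative
   STDP that learns a stimulus and then replays stretched sequences under
   ramped input.
6. **Synthetic data** — a generator that emulates the statistical structure
   of such recordings, so every stage is testable without animal data.

Because no real recordings ship with the package, every quantitative claim
made by the test suite is a claim about *synthetic* data from the generator
or about the network simulation — both fully specified below.

## The synthetic MUA generator

Each channel/stimulus pair has a ground-truth latency offset; per stimulus
the offsets are a random permutation of equally spaced values spanning
exactly `base_span_ms`, so the sorted latencies of a noiseless dataset lie
on an exact line and `fit_sequence()` has a known truth to recover. The
firing intensity of channel *c* under stimulus *s* is

  rate(t) = baseline + A·exp(−(t − L)² / 2σ²) + [t ≥ L]·(S + D·exp(−(t−L)/τ)),

with transient amplitude `A = peak_rate_hz` (scaled by relative stimulus
intensity), transient width σ = 15 ms by default (the data give no analytic
shape; a Gaussian is the simplest single-peaked choice), sustained level
`S = sustained_rate_hz`, and a stimulus-specific sustained deviation `D`
drawn uniformly within ±0.8·S that decays with time constant τ. Spikes are
drawn from an inhomogeneous Poisson process evaluated piecewise-constant on
a 1 ms grid (exact for that intensity; the expected count is the plain sum
of the rate grid).

**Ramp dilation.** The transient center is
`L = base_latency·m_lat(R) + offset·m_span(R) + jitter`. The span
multiplier is `m(R) = (1 + R/R_max)^e` with `e` chosen so that the ratio
between the longest ramp and half that ramp is exactly
`2^dilation_exponent`; `m(0) = 1`. The defaults
`dilation_exponent = log2(1.56)` and `latency_dilation_exponent = log2(1.3)`
make the slow/fast span ratio 1.56 and the latency ratio 1.3 — the
sub-proportional dilation regime the package is built to analyze. Latency
and span use separate exponents because the two observed factors differ.

**Category structure (`prior_match`).** Stimulus categories that match
natural-scene statistics evoke more precisely timed and more persistent
responses. The generator encodes one sufficient mechanism for this: with
prior match *p* ∈ [0,1], trial-to-trial latency jitter is scaled by
(1.5 − *p*) and the sustained-persistence time constant by (0.5 + *p*).
This is a modeling hypothesis, not a demonstrated mechanism: passing the
category-ordering tests shows the pipeline *detects* such structure when it
is present, not that real cortical data contain it for this reason.

What the generator deliberately does **not** emulate: correlated noise
across channels, adaptation across trials, eye movements, channel-specific
contrast sensitivity, or any natural-image statistics. Conclusions from
passing tests transfer to real data only insofar as those features do not
dominate.

## Latency estimation choices

Rates are estimated in half-open windows `[center − w/2, center + w/2)`
(left-closed, so non-overlapping windows partition spikes); windows
extending outside the recorded trial are dropped, not zero-padded. The two
canonical settings are 30 ms windows moved in 1 ms steps for latency
estimation (light single-trial smoothing) and 100 ms windows in 100 ms
steps for rate decoding (long integration).

A channel's **peak latency** is the time of the global rate maximum in the
response window, with ties broken to the earliest bin; a peak is only
accepted if it exceeds the pre-stimulus baseline mean by 3 baseline SDs
(the data analyzed are "responsive channels" with no stated criterion, so
the gate is explicit and configurable, with an absolute floor for
degenerate all-zero baselines). **Onset latency** is the first time the
rate exceeds baseline mean + 3 SD and stays above for ≥ 10 consecutive
1 ms bins — also an explicit stand-in, since no published criterion is
available. Trial-to-channel summaries use the mean (configurable).

One practical caveat the test design exposed: when the sustained period is
long, the single-trial *global* maximum can land on a Poisson fluctuation
of the sustained activity rather than on the transient — and it does so
*more often for high-persistence data*, silently inverting category
comparisons. Latency-based decoding of data with substantial sustained
activity should therefore restrict `response_window` to the transient
epoch; the category-ordering acceptance test uses [0, 800] ms for this
reason.

## Decoders

`spearman_rho()` assigns midranks (ties share the average rank) and
computes the Pearson correlation of the rank vectors explicitly; the suite
verifies it against the closed form `1 − 6Σd²/(n(n²−1))` on all 720
permutations of n = 6 and against the reference midrank implementation on
1000 tied vectors, to 1e−12.

**Rank decoding**: per stimulus, the template is the midrank vector of
trial-mean latencies over the channels responsive for *every* stimulus;
a test trial is assigned the label of the most Spearman-similar template.
Ties break deterministically toward the smallest label; a trial with fewer
than 5 defined latencies on template channels is not classified (and counts
as an error in accuracy summaries). Because templates are ranks,
normalization of latencies is moot.

**Gaussian naive Bayes** (`nb_fit`/`nb_predict`): class-conditional
independent Gaussians with maximum-likelihood priors, log-space posteriors,
and a variance floor of 1e−9 (a class with zero variance in a feature is
floored, not fatal). Missing features in a test vector are skipped — their
likelihood factor is omitted — so trials with a few unresponsive channels
remain classifiable. The implementation is ~30 lines and is cross-checked
against `e1071::naiveBayes` in the test suite; it is kept in-package so the
floor and the missing-feature policy are explicit parts of the method.

**Cross-validation** is stratified: within each class, shuffled trial
indices are dealt round-robin into the folds under a fixed seed, so results
are exactly reproducible. Chance level is 100/n_stimuli within the decoded
set (33.3% for the three-stimulus designs used throughout).

**Fastest-channel curves** order channels by their global mean latency
(over all trials and stimuli) and decode with the k fastest; the
rate-equivalent control feeds the decoder each included channel's spike
count between stimulus onset and that channel's mean latency — same
channels, same time intervals, rates instead of latencies.

**Decay slope**: the descending phase of a time-resolved accuracy curve is
operationalized as the interval from the accuracy peak (first bin attaining
the maximum) to the end of the plateau; the least-squares slope over that
interval is reported in %/s. When comparing decay between conditions whose
curves reach the chance floor at different times, the fit should be
truncated before the floor — a floor segment flattens the fitted line and
can reverse comparisons.

## Trajectories and discriminability

PCA is performed on the covariance matrix of the channel-by-(time ×
condition) data matrix (column means removed — standard covariance PCA; the
source procedure does not state its centering) and the three leading
eigenvectors are kept for display. All quantitative distances are computed
in the native channel space. Baseline and endpoint covariance ellipsoids
summarize trial-to-trial variability of the window-averaged population
vector (200 ms pre-stimulus, last 200 ms of the plateau); the mesh is a
tessellated unit sphere mapped through 0.5·cov^{1/2} (20×20 grid by
default; note the equator lies on the grid only for odd resolutions).

The **discriminability index** at time *t* is the ratio between the mean
pairwise Euclidean distance of stimulus-mean vectors ("inter-trajectory
distance") and the RMS distance of single-trial vectors from their own
stimulus mean, computed per stimulus and then averaged ("trajectory
variability"). Neither term is defined precisely in the source description,
so both are the documented defaults of pluggable choices; a pooled-variance
alternative is available (`variability = "pooled"`). The index is
dimensionless and invariant to channel permutation and uniform rate
scaling; when the variability term falls below 1e−12 the index is reported
as `NA` rather than a spurious large value.

## The spiking-network model

250 Izhikevich neurons (200 regular-spiking excitatory, 50 fast-spiking
inhibitory, the standard heterogeneity recipe in r²), Bernoulli 40%
connectivity without self-connections, initial weights uniform on [0,1].
A 7×7 binary digit glyph maps one pixel to each of 49 excitatory input
neurons; ramping stimuli are simulated as input current rising linearly to
full gain over the ramp. Integration is forward Euler with the reference
stepping convention (v advanced in 0.5 ms half-steps; spike at v ≥ 30;
reset v ← c, u ← u + d), dt = 0.5 ms.

**Plasticity** is all-to-all trace-based STDP with multiplicative soft
bounds on E→E synapses only: potentiation `lr·(w_max − w)·x_pre` when the
postsynaptic neuron fires, depression `lr·w·x_post` when the presynaptic
neuron fires, with τ = 20 ms traces, lr = 0.02, and weights confined to
(0, 2] (lower bound 1e−6 keeps the interval open at zero). At w = w_max
the potentiation increment vanishes. Under uncorrelated background
activity this kernel drifts weights toward w_max/2, so stimulus-specific
structure is carried by the *deviation* from that equilibrium; per-trial
weight-change norms consequently settle onto a fluctuation floor rather
than decaying to zero — training "stabilizes" in the sense that the
directed drift of the weight vector shrinks (to about a third of its
initial block over 200 trials), not that updates stop.

Constants the source leaves free were calibrated once for the stated
regimes and then frozen: background noise SD 5 (excitatory) / 2
(inhibitory) per step for a spontaneous rate of ≈1.3 Hz (target 1–3 Hz);
input gain 20 so input neurons fire at ≈65 Hz under full drive (target
50–100 Hz); recurrent excitatory gain 0.3 and inhibitory gain 1 for stable
training without runaway; a uniform 1 ms transmission delay. A divergence
guard aborts any trial whose mean excitatory rate exceeds 200 Hz.

**Measuring sequence precision.** Non-input excitatory neurons fire only a
handful of spikes per trial, so single-trial peak latencies are heavily
quantized. Two consequences shaped the analysis design. First, trial-mean
(PSTH) peak latencies are the right basis for the orderliness statistic
(Pearson correlation between latency-sorted neuron index and latency);
under the slow ramp the trained network reaches r ≈ 0.96–0.99 across
seeds. Second, when comparing latency dispersion between two networks, the
comparison must be paired on the *matched* set of neurons that respond
reliably under both: training recruits additional, marginally responsive
neurons, and including them in an unmatched average biases the comparison
against the training effect. With 30 test trials and the matched design,
training reduces inter-trial latency SD in 8/10 seeds and increases the
total number of defined single-trial latencies (participation reliability)
in 10/10.

## Problem sizes and reproducibility

All simulation sizes are chosen for desk-scale reproducibility: synthetic
datasets of 16–32 channels, 3 stimuli, and 20–30 trials per condition;
decoder-null checks with 100 label shuffles on one fixed dataset; category
ordering over 20 paired replicates (the three prior-match levels share one
generator seed per replicate, so ground-truth sequences are identical and
only jitter/persistence differ — an unpaired design is dominated by the
luck of how similar the random templates happen to be); network training
runs of 200 trials. Every stochastic step takes an explicit seed, and
identical seeds reproduce results bit-for-bit.

The `scripts/acceptance.R` entry point re-runs the network simulation from
scratch (build → 200 training trials → 10 slow-ramp test trials) and
reports the slow-ramp orderliness correlation.

## Known limitations

- The generator's category mechanism (jitter/persistence coupling) is one
  sufficient hypothesis; real category differences may arise otherwise.
- Onset-latency defaults stand in for an unavailable published criterion.
- The network learns a single stimulus per training run; simultaneous
  multi-stimulus learning, conductance-based synapses, and topographic
  connectivity are out of scope.
- The exact multiplicative-STDP dialect (nearest-neighbor pairing,
  depression scaling) varies across the literature; the all-to-all
  soft-bound kernel used here is one documented choice.
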