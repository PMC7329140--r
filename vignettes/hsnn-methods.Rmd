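---
title: "Modelling word recognition in noise with a hierarchical spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling word recognition in noise with a hierarchical spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsnn)
```

## The model

`hsnn` simulates a six-layer feed-forward network of leaky integrate-and-fire
(LIF) neurons modelling the ascending auditory pathway — one layer per
principal nucleus between cochlea and cortex — and evaluates how its
organization affects spoken-digit recognition in noise. The pipeline is:

1. **Cochlear front end.** A bank of 53 fourth-order gammatone filters with
   ERB (critical-band) bandwidths, center frequencies spaced 1/10 octave from
   100 Hz (`channel_grid()`), followed by envelope extraction (magnitude of
   the complex filter output, lowpass-smoothed) and compressive
   nonlinearity, sampled at 2 kHz frames (`cochleagram()`).
2. **Spiking layers.** Each layer holds 53 tonotopically organized neurons.
   Connections into layer $l$ are co-tuned Gaussian profiles on normalized
   tonotopic position with excitatory width $\sigma_l$ and inhibitory width
   $1.5\,\sigma_l$. Incoming activity is convolved with peak-normalized
   alpha-function EPSP/IPSP kernels ($\tau_E = \tau_l$,
   $\tau_I = 1.5\,\tau_l$) and combined as excitation minus $\beta = 2/3$
   times inhibition to give a *desired* membrane voltage. The injected
   current is obtained by exact discrete deconvolution of the membrane
   kernel, plus white current noise at 15 dB SNR, so the subthreshold
   voltage reproduces the desired trace precisely (`derive_current()`,
   `lif_simulate()`). Spikes occur at a threshold 20 mV above rest
   ($V_T = -45$, $V_r = -65$ mV), with reset and a 1 ms refractory period.
3. **Layer scaling.** The three per-layer parameters follow power laws
   $\tau_l = \tau_1 \alpha_\tau^{\,l-1}$,
   $\sigma_l = \sigma_1 \gamma_\sigma^{\,l-1}$,
   $N_l = N_1 \lambda_N^{\,l-1}$ with first-layer defaults
   $\tau_1 = 0.4$ ms, $\sigma_1 = 0.0269$, $N_1 = 0.5$ chosen to mimic
   auditory-nerve-like responses (fast, narrowly tuned, high rate). The
   *identity* network ($\alpha_\tau=\gamma_\sigma=\lambda_N=1$) keeps every
   layer at this high resolution; the *scaled* network with
   $\alpha_\tau = 1.9$ increases time constants 24.8-fold
   ($1.9^5$) across layers.
4. **Threshold normalization.** $N_l$ expresses the spike threshold in units
   of the layer's population voltage SD: a calibration ensemble (20 clean
   words by default) is run layer by layer, and a per-layer gain is frozen
   so that $\sigma_{V,l} = (V_T - V_r)/N_l$ (`calibrate_network()`). All
   evaluation runs reuse the frozen gains.
5. **Decoding.** Multi-neuron spike rasters are binarized at resolution
   $\Delta t$ (default 5 ms) and read by a Bernoulli naive-Bayes classifier:
   the likelihood of a spike in each neuron-time bin is its smoothed
   empirical frequency per digit, and the digit maximizing the log
   posterior wins (`fit_likelihood()`, `classify_response()`). Word accuracy
   rate (WAR) is leave-one-out cross-validated over the corpus
   (`crossval_war()`), and `run_grid()` searches the three scaling exponents
   by exhaustive cross-validated grid search.

## Synthetic corpus

The recognition task originally used a licensed isolated-digit corpus
(8 talkers x 10 digits x 10 utterances). Since that audio cannot be
redistributed, `generate_corpus()` synthesizes a factorial digit-like corpus
with the same design: each digit has a fixed template of voiced segments
(2–3 formant resonators with linear frequency trajectories, excited by a
glottal pulse train) and fricative-like noise bursts; talkers differ in
voicing pitch (80–140 Hz) and vocal-tract length scaling; utterances jitter
duration, pitch and formant scale by a few percent. Words last roughly
0.3–0.7 s, are onset-aligned (first upward crossing above 2 background SDs,
`align_onset()`), and are embedded in speech babble built by summing 7
randomly drawn corpus segments (`generate_babble()`), mixed at a prescribed
SNR over the word support (`mix_at_snr()`).

What the generator emulates: formant trajectories, voicing periodicity,
onset structure, talker variability, babble statistics. What it does not:
coarticulation, natural prosody, consonant inventories, recording-channel
effects. Accuracy numbers on this corpus therefore cannot be compared with
accuracies on natural speech — only *relative* comparisons between network
configurations on the same corpus are meaningful, and the package's tests
assert directions and contracts, not absolute accuracies.

## Probe stimuli and characterization

* **Dynamic moving ripple (DMR).** `generate_dmr()` modulates the carrier
  bank by a ripple whose density (0–4 cyc/oct) and drift rate (±350 Hz)
  wander over their ranges, at 30 dB modulation depth; the envelope design
  is stored for reverse correlation. Both drift directions are included so
  the stimulus autocorrelation stays separable. Two non-default choices
  matter for short probes: `wander = "sweep"` replaces the random walk by
  deterministic triangular scans that cover the modulation plane uniformly,
  and `phase0 = pi` yields the polarity-inverted envelope of the same
  stimulus. Estimating an STRF from a polarity-balanced pair
  (`combine_strf()`) cancels the even-order distortion that output
  rectification otherwise leaves in a spike-triggered average; with a 60 s
  balanced pair a planted 20-parameter Gabor kernel is recovered with
  correlation above 0.9.
* **STRF metrics.** Latency is the lag of the peak of the temporal marginal
  envelope; integration time is twice the SD of that envelope about its
  centroid; bandwidth is the spectral marginal's full width at half maximum
  in octaves. These definitions are fixed so cross-layer trends are
  comparable.
* **Gabor model.** Measured STRFs are summarized by a sum of two
  time-frequency Gabor components, 10 parameters each (gain, temporal
  center, width, modulation frequency and phase, a temporal-phase gradient
  along frequency capturing orientation, spectral center, width, ripple
  density and phase). Fitting is least squares with a rank-2 SVD
  initialization and multi-start quasi-Newton refinement (`fit_gabor()`).
  The rendered kernels parameterize the single-layer LP/LNP baselines
  (`build_glm_bank()`), giving 53 x 20 = 1060 parameters.
* **Mutual information.** The direct (word-histogram) method on 2 ms binary
  rasters: total entropy from the word distribution across time, noise
  entropy from across-trial distributions at fixed times, extrapolated
  linearly in inverse data fraction (1, 1/2, 1/4) and inverse word length
  (2–10 bins). Word lengths with fewer than 4 trials per occupied state are
  flagged as undersampled and dropped. On stimulus-independent rasters the
  residual bias stays below a few percent of the total entropy rate.
* **Response spectra.** Trial-averaged responses estimate the signal; Welch
  periodograms (1024-sample Kaiser window, beta 5, 50% overlap, not
  demeaned so DC is retained) of the average and of single trials give
  signal and signal-plus-noise spectra; the noise spectrum follows by
  subtraction, floored at zero, with the SNR capped at 40 dB where it
  underflows. Band SNR integrates the dB curve over the fluctuation
  (1–25 Hz) and periodicity-pitch (75–150 Hz) bands; the band modulation
  index normalizes band signal power by the total DC power.

## Numerical choices

* **Time step.** Per-layer step $dt_l$ is the largest divisor of the 0.5 ms
  cochlear frame not exceeding $\tau_l/8$ (0.05 ms in layer 1), so alpha
  kernels are resolved everywhere; spike times are carried continuously
  between layers and kernels are evaluated at exact spike offsets.
* **Membrane discretization.** The membrane filter is the exact exponential
  integrator $V_k = aV_{k-1} + (1-a)I_k$, $a = e^{-dt/\tau}$; its inverse is
  algebraic, which is why the deconvolution identity holds to machine
  precision and constant-current interspike intervals match the closed-form
  LIF period within one step.
* **Connectivity truncation.** Gaussian profiles are truncated at 4 SD and
  left unrenormalized at the grid edges, preserving the stated peak weight.
* **Smoothing.** Naive-Bayes likelihoods use Jeffreys smoothing $a = 0.5$;
  empirical probabilities of 0 or 1 would otherwise zero entire posteriors.
  Under leave-one-out the held-out class trains on one fewer utterance,
  which slightly penalizes it in very sparse regimes; this is inherent to
  the stated likelihood formula and is visible only when the discriminative
  signal is tiny.
* **Babble for one-talker corpora.** Babble segments exclude the test
  word's talker whenever at least two talkers exist; a single-talker corpus
  falls back to the full pool.
* **Seeds.** Every stochastic stage takes a seed; `run_grid()`,
  `run_experiment()` and the acceptance script expand one master seed into
  per-cell, per-utterance, per-trial child seeds, so any run is exactly
  reproducible.

## Desk-scale experiments

The packaged tests and the acceptance script run reduced versions of the
figure-level experiments: a 2 x 10 x 2 corpus (40 utterances) in babble at
5 dB SNR, two calibrated networks (scaled $\alpha_\tau = 1.9$ vs identity),
leave-one-out decoding per layer, an 8-point spike-timing resolution sweep,
and 8-trial response spectra on a short digit sequence. These sizes keep a
full run in minutes on one core while preserving the qualitative layer-wise
phenomena: firing rates fall across layers of the scaled network but not
the identity network; the scaled network's accuracy at 5 dB exceeds the
identity network's; its accuracy peaks at a coarser spike-timing resolution;
and it attenuates the periodicity-pitch band (75–150 Hz) across layers much
more strongly than the identity network. The fluctuation-band (1–25 Hz)
*enhancement* seen at full scale is marginal at this corpus size and is
logged rather than asserted. The full grid search
(15 x 8 x 12 cells, 800-fold leave-one-out, six SNRs) is supported by
`run_grid()` but is a long-running computation.

## Known limitations

* The synthesis recipe is intentionally simple; absolute accuracies are not
  comparable to natural-speech benchmarks.
* The network omits descending feedback, synaptic adaptation,
  conductance-based synapses and per-neuron heterogeneity.
* The spike-triggered average is bias-limited for short ripple probes; the
  sweep-mode polarity-balanced protocol mitigates but does not eliminate
  this for strongly oriented kernels.
* Mutual-information estimates at 50 trials remain biased for word lengths
  beyond a few bins; the coverage rule drops those lengths rather than
  correcting them.

## A worked example

```{r example, eval = FALSE}
g <- channel_grid()
corpus <- generate_corpus(2, 10, 2, seed = 42)
labels <- vapply(corpus$utterances, `[[`, 1, "digit_label")

clean <- lapply(corpus$utterances[seq(1, 40, by = 4)], function(u)
  cochleagram(u$waveform, u$sample_rate, g))
net <- calibrate_network(scaling_rule(alpha_tau = 1.9), clean, g, seed = 7)

specs <- lapply(corpus$utterances, function(u) {
  babble <- generate_babble(length(u$waveform) / u$sample_rate, corpus,
                            seed = u$talker_id * 100 + u$utterance_index,
                            exclude_talker = u$talker_id)
  cochleagram(mix_at_snr(u, babble, 5)$waveform, u$sample_rate, g)
})
rasters <- lapply(seq_along(specs), function(i)
  run_network(net, specs[[i]], seed = 9000 + i))

layer_profiles(rasters, labels, delta_t = 5)
```
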