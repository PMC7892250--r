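---
title: "Single-trial auditory evoked fields: enhancement, imaging and recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial auditory evoked fields: enhancement, imaging and recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aefmeg)
```

## The problem

An auditory evoked field (AEF) is the stereotyped magnetic response of
auditory cortex to a sound: a triphasic P50/N100/P200 complex peaking roughly
68, 108 and 193 ms after the sound reaches the ear. In a single 0.3 s trial
the AEF is buried in ongoing brain rhythms, physiological artifacts and
environmental noise, which is why MEG practice traditionally averages
hundreds of trials — discarding everything that varies from trial to trial.

`aefmeg` implements a single-trial route. The key observation is spatial:
sensors over an active cortical patch record the *same* evoked waveform (up
to gain and sign), while noise is largely uncorrelated between sensors that
are centimeters apart. Correlation between neighbouring channels is therefore
a signature of evoked activity that survives at the single-trial level.

## The enhancement model

For each sensor $S_i$ a neighbourhood is defined as all sensors within a
Euclidean radius of $0.022 \times 1.7$ m (about 5-8 neighbours on a CTF-like
274-channel cap; `default_radius()` generalizes this as 1.7 times the mean
nearest-neighbour distance for other layouts). Within one 0.3 s trial the
Pearson correlation $c_{ij}$ between channel $i$ and each neighbour $j$ is
computed from population moments,

$$c_{ij} = \frac{E[X_i X_j] - E[X_i]E[X_j]}
                {\sqrt{\mathrm{Var}(X_i)\,\mathrm{Var}(X_j)}},$$

and neighbours with $|c_{ij}| \ge 0.8$ qualify. With $n$ qualifying
neighbours the enhanced channel is

$$X_i' = X_i + \frac{\sum_{j} c_{ij} X_j}{n - 1} \quad (n \ge 2),$$

with $X_i' = X_i + c_j X_j$ for $n = 1$ and $X_i' = X_i$ for $n = 0$. All
channels are computed from the original trial — there is no sequential
update. Three details are deliberate design choices:

* **The $n=1$ case.** Read literally, a denominator of $n-1$ is undefined at
  $n = 1$; the adopted rule adds the single weighted neighbour directly.
  Alternative conventions (divide the whole superposition by $n+1$; divide
  the neighbour sum by $n$) are selectable via `enhance_trial(rule =)` so the
  reading can be compared.
* **Signed weights with magnitude qualification.** A dipolar field pattern
  makes sensors on opposite sides of the source *anticorrelated*;
  qualification by $|c| \ge 0.8$ with the signed $c$ as weight lets such
  neighbours contribute constructively.
* **Ties.** Qualification uses $\ge$, so a correlation of exactly 0.8 counts.

After enhancement, each channel's energy $\sum_t X_i'(t)^2$ is normalized to
a maximum of 1; on an AEF trial the energy concentrates over the auditory
areas of the temporal lobes, strongly on the right in the default scenario
(the simulated subject's left ear is the less sensitive one).

## Preprocessing chain

Everything upstream of enhancement follows standard M/EEG practice:

* **Event marking.** Stimulus onsets are detected on the *audio* channel
  (rectified envelope crossing half its maximum, 0.5 s refractory), not the
  electrical trigger: the audio channel lags the trigger by the 0.13 s sound
  delivery delay and is therefore aligned with what the subject hears, so no
  latency correction is needed. Blink and cardiac events are threshold
  detections on EOG/ECG in robust-SD units (default 4).
* **SSP.** One spatial component per artifact kind is estimated from
  event-locked epochs (±0.2 s) and projected out of the MEG channels.
  Projecting is idempotent and annihilates a rank-1 artifact exactly.
* **Notch filters.** Second-order IIR notches at 10, 11, 20 and 21 Hz with an
  exact single-pass −3 dB bandwidth of 2 Hz, applied forward-backward so
  peak latencies do not shift; the input is reflection-padded by
  $3 \cdot \mathrm{rate}/\mathrm{bandwidth}$ samples because the notch poles
  lie close to the unit circle and the filter transient would otherwise leak
  into the session.
* **Low-pass FIR.** A type-I (even order, symmetric) Kaiser-window design,
  passband edge 40 Hz, stopband edge 55 Hz, nominal 60 dB stopband
  attenuation designed with a 5 dB margin so the *measured* minimum stopband
  attenuation stays above 60 dB. The 60/120/180 Hz line components fall in
  the stopband, which the filter asserts at design time — no separate line
  filter exists. Group delay is integer (even order) and compensated, so the
  output is time-aligned.
* **Interception.** One MEG-only window of `round(0.3 * rate)` samples per
  stimulus, starting at the stimulus (a configurable pre-stimulus offset
  defaults to 0, since the full P50-P200 complex lies inside 0.3 s
  post-stimulus).
* **Screening.** A trial's statistic is the maximum over channels of the
  channel mean square; trials above `median + 10 * MAD` (literal median
  absolute deviation) are rejected. If the MAD is zero nothing is rejected.
  The statistic and the k = 10 default are this package's concretization of
  rejecting "very high power" trials; k = 10 sits far in the tail for
  Gaussian-like data so ordinary trials are essentially never lost.

## Topographic imaging

Sensors are projected to the plane by an azimuthal-equidistant map from the
vertex (planar radius proportional to polar angle, azimuth preserved, the
array's largest polar angle mapped to the unit circle). Normalized energies
are interpolated over the disc with a thin-plate spline — chosen because it
is deterministic, smooth, and *exact at sensor sites* — clipped to $[0, 1]$,
passed through a fixed perceptually-uniform colormap (viridis, dark
background), and rasterized at 224 × 224, the input size of standard image
classification networks. Pixels are quantized to 8 bits at render time so the
PNG round trip is lossless. No head or nose outline is drawn: decorations
carry no class information and would complicate bit-level determinism. The
interpolation system is factored once per layout (`topomap_renderer()`), so
rendering hundreds of trials costs one small matrix solve each.

## Recognition

The classifier separates AEF-trial images from empty-room-noise images. Two
backbones share one contract (224 × 224 × 3 input in $[0,1]$, two classes,
final dropout 0.6, learning rate $10^{-4}$, 10 epochs, batch 16, momentum
0.9, stratified 80/20 train/validation split):

* `pretrained-inception`: fine-tuning a large pretrained inception-style
  network with its final dropout raised to 0.6 and its last fully-connected
  and classification layers rebuilt for the two classes. This requires an
  external deep-learning runtime and downloaded weights, so the constructor
  refuses it with a pointer to the compact backbone.
* `compact-scratch` (default, used by all tests): a small convolutional
  network implemented in this package — fixed 8 × 8 average pooling to
  28 × 28, one 5 × 5 convolution with 8 filters and ReLU, 4 × 4 max pooling,
  dropout, and a zero-initialized 2-way softmax head — trained from random
  (He) initialization with momentum SGD.

One normalization detail matters at the specified learning rate: the
max-pooled ReLU features are nonnegative, so their common mode plus any class
imbalance dominates early training of a zero-initialized head. The compact
backbone therefore standardizes the feature vector with a frozen
normalization layer (per-feature mean and SD computed once on the training
set before optimization, stored in the model and applied identically at
inference). This is the usual role of a normalization layer, not a tuned
constant. The paper-level settings (dropout 0.6, lr $10^{-4}$, 10 epochs)
are then sufficient for the task.

The method does not depend on the backbone: the separable structure is in
the images (a stereotyped right-temporal energy blob versus spatially random
noise patterns), which is why a compact scratch-trained network suffices at
desk scale.

## The synthetic session generator

`synth_scenario()` / `simulate_session()` generate the study conditions end
to end: 274 point radial magnetometers on a quasi-uniform Fibonacci lattice
over a 105° spherical cap of radius 0.11 m; 600 Hz sampling; 360 s sessions
with 200 (199) stimuli at jittered ~1.8 s intervals; an audio channel whose
tone bursts lag the trigger by 0.13 s; bilateral auditory current dipoles
(right gain 1, left 0.5) whose radial fields follow the spherical-conductor
dipole formula; the triphasic waveform with peaks at 68/108/193 ms (widths
12/16/25 ms, relative amplitudes +1/−1.5/+1.2 — the widths and relative
amplitudes are not independently sourced and are stated, configurable
parameters); and a noise mixture of per-channel white and 1/f noise, 60 Hz
line interference with a global spatial pattern, amplitude-modulated
10/11/20/21 Hz rhythms over posterior sensors, frontal blink transients
mirrored into EOG, and QRS-like cardiac transients mirrored into ECG. A
separate 120 s empty-room session carries the same environmental floor
without sources or physiological components.

**SNR.** The scenario's `snr` is the ratio of source power to total noise
power over temporal-region sensors within stimulated windows, enforced by
scaling the noise mixture (the scale is estimated from a 20 s seeded probe of
the same mixture, so AEF and empty-room sessions share one noise floor). The
default is `snr = 2`, chosen once so that single-trial neighbourhood
correlations over the auditory-region sensors reach the > 0.8 regime the
enhancement presumes — the level reported for real auditory channels — after
the 40 Hz low-pass has removed the out-of-band noise. It was not adjusted
afterwards.

**What the generator does not emulate.** Real CTF axial gradiometers
(baselines, coil orientations) are approximated as point radial
magnetometers; anatomy is a sphere, not a head; trial-to-trial variability
of the evoked response (latency jitter, habituation) is absent; the
empty-room spectrum is an assumption, not a fit to measured noise. Passing
tests on this generator therefore demonstrate the pipeline's correctness and
the method's behaviour under its stated assumptions — not performance on any
particular real dataset.

## Numerical and degenerate-input rules

* Correlations use population (1/N) moments — the choice cancels in the
  ratio — and are clamped to $[-1, 1]$; zero-variance channels are treated as
  having no qualifying neighbours (with a warning) rather than erroring
  mid-pipeline.
* Neighbourhoods use closed-ball distance (ties included) on straight 3-D
  Euclidean distances, not geodesics on the cap — the simplest reading of a
  "radius", and the difference is second-order at these angles.
* The projection rim is the maximum polar angle present in the array, which
  makes images comparable across layouts; sensors at polar angles ≥ 150° are
  rejected (the azimuthal-equidistant map degenerates toward the antipode).
* An all-zero trial cannot be energy-normalized and errors; a trial set with
  zero MAD screens nothing out; `epochs = 0` returns a valid untrained model
  (it predicts the first class on ties, i.e. chance on balanced data).
* All randomness flows from explicit integer seeds through temporary RNG
  states, so library calls never perturb the caller's RNG and every artifact
  is reproducible from (configuration, seed).

## Scale of the shipped experiments

The full experiment (two 360 s sessions at 274 sensors, 200 + 199 stimuli,
400 noise segments, 799 images, 10 training epochs) runs in roughly ten
minutes on one CPU core and is exercised by the acceptance test and
`scripts/acceptance.R`. Unit and property tests use smaller sessions
(typically 30-120 sensors, 8-20 stimuli, 10-40 s) — sizes chosen so each
property is still informative while the whole suite stays fast. The
localization-recovery property is tested at `snr = 0.1`, a deliberately
degraded regime in which the raw energy argmax finds the temporal patch in
under 70% of trials, so the paired improvement from enhancement is visible
rather than saturated.

## Known limitations

* The pretrained-inception backbone is a declared contract, not a shipped
  implementation; reproducing the original transfer-learning configuration
  requires a deep-learning runtime and pretrained weights.
* Enhancement can amplify any spatially coherent signal, not only evoked
  activity: residual artifacts or chance correlations of low-frequency noise
  produce isolated bright spots in noise images (the classifier is what
  tells these apart — mirroring the method's own logic).
* The recording container is an RDS-based single-file format behind
  `read_recording()`/`write_recording()`; adapters for standard M/EEG
  container formats can implement the same surface, and sensor layouts
  exchange via a plain-text table.
* Batch operation only: the pipeline processes recorded sessions, it does not
  stream.
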