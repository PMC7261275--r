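---
title: "Classifying instrument–tissue interaction from electrosurgical sound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{surgsound methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During minimally invasive surgery the surgeon loses most haptic feedback
and relies almost entirely on the endoscopic view. Electrosurgery
(diathermy) — cutting or coagulating tissue with high-frequency current —
is loud, and the sound it makes depends on the tissue being treated and on
the generator's operation mode. `surgsound` implements a complete pipeline
for exploiting that signal: it turns short audio clips recorded near the
surgical site into log-mel-spectrogram "auditory images", classifies them
with a transfer-learning-style classifier (a frozen convolutional feature
extractor feeding a trained softmax layer), and evaluates both the
classification quality and the ability to localize the moment the
instrument passes from one tissue to another within a longer recording.

Because no public corpus of intra-abdominal diathermy recordings exists,
the package ships a first-class synthetic-audio generator that emulates
the statistical structure of such recordings. Everything — synthesis,
feature extraction, training, evaluation — runs from a single seed and is
bit-reproducible.

## The front end

Each clip (mono PCM, canonically 44.1 kHz) is cut into fixed-length
analysis windows of 300, 500 or 1000 ms with 75% overlap; trailing partial
windows are discarded because the image-rendering stage needs fixed-size
inputs. Within a window the short-time Fourier transform uses frames of
`n_fft = 2048` samples hopped by 512 samples, each frame weighted by the
symmetric Hann window `w[n] = (1 - cos(2*pi*n/(M-1)))/2`. Squared
magnitudes are pooled by a bank of 256 triangular filters spaced evenly on
the mel scale `f_mel = 2595 * log10(1 + f/700)` (the HTK-style constant:
1000 Hz maps to 1000 mel within 0.1) between `f_min` and `f_max = 11025`
Hz, then mapped to decibels as `10*log10(max(P, eps))` with
`eps = 10^(db_floor/10)`, `db_floor = -80` dB. There is no reference-power
division; the global normalization absorbs absolute scale.

The `f_min = 2000` setting implements a hard low-cut in the spectral
domain: filters simply receive no weight below 2 kHz. The low band of
operating-room audio is dominated by environmental noise, so discarding it
concentrates the 256 bands on the informative range. Filterbank triangles
have unit peak height (no area normalization); a triangle so narrow that
no FFT bin falls inside its support is snapped to the bin nearest its
centre so that every band keeps positive weight — with 256 bands over the
full 0–11 kHz range at 2048-point resolution the lowest few filters are
narrower than one 21.5 Hz bin, and erroring there would make the standard
configuration unusable. The bank refuses outright only when `n_mels`
exceeds the number of FFT bins in range.

Spectrograms are normalized by a single global mean and population
(divide-by-N) standard deviation pooled over every cell. By default the
statistics are fitted on the **training split only**, which prevents test
statistics from leaking into the features; `norm_on = "all"` pools over
the entire dataset instead for strict comparability with protocols that
normalize globally. The normalized matrix is bilinearly resized
(align-corners convention) to `image_size x image_size` (default 299),
oriented low-frequency-at-bottom, and replicated across three identical
channels. Grayscale replication is information-preserving and avoids
committing to any colormap.

## The classifier

The backbone contract is *image in, fixed-length vector out*. The default
backbone is a seeded, frozen, random-weight convolutional extractor: the
image is reduced to 64 x 64, decomposed into 5 x 5 patches at stride 2,
projected through 32 random Gaussian filters with ReLU, and average-pooled
over an 8 x 8 grid — 2048 features, the dimensionality convention of
large pretrained image CNNs. Untrained convolutional filters are a
recognised baseline for auditory images: the discriminative content of a
log-mel spectrogram of resonant textures is mostly *where* energy sits on
the frequency axis, which random band-like filters plus spatial pooling
expose well. The extractor needs no downloaded weights and is fully
deterministic per seed; any pretrained CNN exposing the same contract can
be plugged in.

On top sits a single fully connected softmax layer trained with mini-batch
RMSprop (batch 32, fixed learning rate 1e-3, decay 0.9, epsilon 1e-8) on
the softmax cross-entropy `H(y, p) = -sum_c y_c log p_c` (natural log,
probabilities clamped at 1e-12). Training stops when validation loss has
not improved for 10 epochs (budget 100), and the weights of the best
validation epoch are kept. The learning rate, patience and epoch budget
are desk-scale choices surfaced in `train_config()`; the optimization
problem is convex, so they affect speed rather than the solution. Features
are standardized per dimension with training-set statistics stored inside
the model.

Two label schemes are supported: `tissue5` (idle, fat, fascia, liver,
muscle) and `tissue_mode9` (idle plus tissue x cutting/coagulation).
Splits are assigned at **clip level**, stratified by class, 80/10/10:
windows of one clip overlap by 75%, so window-level splitting would let
near-duplicates of training windows into the test set. Clip-level
splitting is the conservative choice; accuracies under it are not inflated
by that leakage path.

## Notch filtering of alarm tones

Electrosurgical generators emit regulatory alarm tones — pure sines at
2020/3035 Hz (cutting) and 1380/2270 Hz (coagulation) — that are audible
in recordings. `apply_notch()` cascades one second-order IIR notch
(audio-EQ-cookbook biquad) per tone at Q = 30: a 67 Hz-wide notch at 2 kHz
removes a sine while sparing neighbouring diathermy content (measured:
> 27 dB broadband RMS attenuation of each tone on 2 s sines, < 0.01 dB
change at 5 kHz). Notch filtering is **off by default** in the pipeline:
the alarm tones are mode-informative, and removing them does not improve
classification; the switch exists for experiments that must not rely on
them.

## Transition localization

`localize_transition()` classifies every sliding window of a stream,
smooths the label sequence with a width-3 majority filter (the smallest
filter that kills single-window flickers), and places the estimated
transition at the midpoint between the temporal *centres* of the last
window of the first stable run and the first window of the next run. A
window's label describes its whole span, so window centres are the
unbiased time coordinate; midpointing window *starts* would shift every
estimate early by half a window (250 ms at the 500 ms setting). A stream
whose smoothed labels never change yields an explicit "no transition"
outcome rather than a fabricated time.

## The synthetic generator

Each class is a `sound_profile`: resonant spectral peaks shaping white
noise (one constant-peak-gain biquad resonator per peak), Poisson crackle
transients (broadband bursts with ~4 ms exponential decay), and a level.
Clips add mode-matched alarm sines and a 1/f-tilted environmental bed
band-limited below 2 kHz; `idle` is the bed alone. Durations are normal
with mean 2 s and sd 300 ms (truncated at 1.2 x the longest analysis
window) — about the mean application length of an electrosurgical
activation, with enough spread to exercise variable window counts. Modes
are balanced exactly within every tissue.

Easy-difficulty profiles place tissue peaks between 2.8 and 9.6 kHz with
power-spectral centroids separated by more than 1 kHz inside the 2–11 kHz
analysis band; cutting variants raise the crackle rate (x1.6) and the
first peak's gain (+6 dB) over coagulation. Hard-difficulty profiles
compress all centroids into 4–5.6 kHz. The generator emulates the
*class-conditional spectral envelope* structure of diathermy audio — it
does not model tissue vaporization physics, box/abdomen room acoustics,
instrument motion, or non-stationary alarm patterns. Passing tests
therefore demonstrate that the pipeline recovers class structure of this
kind when it is present; they do not certify performance on real
operating-room recordings.

## Validation protocol and problem sizes

The standard validation run (see `scripts/acceptance.R` and the test
suite) uses 20 clips per `tissue5` class (100 clips, ~1300 analysis
windows at the 500 ms setting), the 2 kHz low-cut front end, and the
seeded random backbone. It checks: STFT equality with a naive O(N^2) DFT
oracle (50 random signals, <= 1e-6 relative); the analytic closed forms of
the Hann window, mel map and dB map; window/frame counts against
brute-force enumeration; exact standardization after normalization; notch
attenuation; >= 0.90 window-level test accuracy on `tissue5` and >= 0.80
on `tissue_mode9`; a label-shuffled control inside the binomial 99% band
around chance; a 3 x 2 window-length x low-cut accuracy grid in which
1000 ms columns must not fall below 300 ms columns; and transition
localization on 30 two-texture clips (12 s, transitions uniform in 3–9 s,
100 ms crossfade) with median offset <= 250 ms — the ballpark of trained
human reaction-time precision on the same task. These sizes keep a full
validation run in a few CPU-minutes while leaving every check
statistically meaningful.

## Numerical and degenerate-input choices

* Resampling is FFT-domain rational resampling (spectrum truncation or
  zero-padding with Nyquist-bin splitting): exact for band-limited
  content, length-exact to one sample.
* WAV I/O is integer PCM (8/16/24/32 bit read; 16/24 write). Writing
  refuses clips whose peak exceeds full scale rather than hard-clipping.
* `power_to_db` floors inside the log, so silence maps to exactly the
  floor and all outputs are finite.
* Zero-variance normalization input and empty collections are errors, not
  NaN propagation.
* Softmax argmax ties resolve to the lowest class index; logits are
  max-shifted before exponentiation.
* All randomness flows from one top-level seed through named substreams
  (`synth`, `split`, `backbone`, `train`), so changing how many random
  numbers one stage draws cannot perturb another stage.

## Known limitations

* The synthetic generator's stationary textures are a deliberate
  simplification; no claim transfers to in-vivo audio without real data.
* The random-weight backbone underperforms a pretrained deep CNN on hard
  discrimination problems; it is the dependency-free default, not the
  ceiling.
* The transition localizer assumes a single transition; multi-segment
  streams report only the first boundary.
* Only integer-PCM WAV is read; compressed formats are out of scope.
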