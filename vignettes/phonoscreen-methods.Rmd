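---
title: "Screening congenital heart disease from phonocardiograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening congenital heart disease from phonocardiograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonoscreen)
```

## The problem

Auscultation is the front line of congenital heart disease (CHD) screening:
septal defects (ASD, VSD) and a patent ductus arteriosus produce murmurs —
broadband noise superimposed on the cardiac cycle — that a trained ear
recognizes against the two dominant heart sounds, S1 and S2. `phonoscreen`
automates this chain for digital stethoscope recordings
(phonocardiograms, PCG): it locates the four phases of each cardiac cycle,
summarizes each recording as a pair of two-dimensional energy maps, fuses
them, and classifies the fused map as normal or CHD with a small
convolutional network.

The pipeline has four stages, each usable on its own:

1. **Segmentation** — a duration-constrained hidden Markov model (a hidden
   semi-Markov model) over the cyclic phase sequence
   S1 → systole → S2 → diastole.
2. **Features** — Mel-frequency spectral coefficients (MFSC, the log Mel
   filter-bank energies) and a per-cycle homomorphic-envelope matrix.
3. **Fusion** — an energy-gated local overlay that sums the two maps where
   a sliding window flags elevated energy (where S1/S2 live) and averages
   them elsewhere.
4. **Classification** — a lightweight CNN with mixed pooling and
   coordinate attention ending in a sigmoid CHD probability, trained with
   binary cross-entropy and Adam.

## Segmentation model

Heart sound is quasi-periodic. The cardiac cycle length is estimated as the
most prominent peak of the autocorrelation
$\tilde r_x(l) = \frac{1}{N}\sum_{n} x(n+l)\,x(n)$ of the Hilbert envelope,
searched over 0.375–2 s (30–160 bpm); outside that band, or when no peak
reaches 15% of the zero-lag coefficient, the recording is reported as
aperiodic rather than silently mis-segmented.

The phase model fixes the transition matrix to the cyclic permutation
(S1 can only be followed by systole, and so on) and the initial
distribution to 1/4 per phase — a stethoscope lands at an arbitrary point
of the cycle. What is learned from data are, per phase $j$:

* a dwell-time mean $\bar d_j$ and variance, turned into a discretized
  Gaussian duration pmf truncated to $[\max(1,\mu-3\sigma),\,\mu+3\sigma]$;
* a Gaussian emission over the per-frame observation.

The observation is the **homomorphic envelope averaged per 25 ms frame
(10 ms hop), z-scored per recording**. The model's sources never pin down
the emission feature; a one-dimensional envelope emission is the minimal
choice consistent with envelope-based cycle analysis, and the z-scoring
makes segmentation exactly invariant to recording gain (the test suite
asserts this). Decoding is duration-explicit Viterbi in log space. The
first and last segments are *duration-censored*: a recording starts and
ends mid-phase, so their observed dwell $d$ is scored with the survival
function $P(D \ge d)$ instead of the exact pmf. Ties break toward the
earliest boundary (shorter durations are examined first and only strict
improvements switch the argmax). On short sequences the decoder is checked
against exhaustive enumeration of every admissible segmentation under the
same semantics.

When a synchronized ECG is available, labels come directly from the
fiducials: S1 starts at each R peak with the rule's mean S1 duration
(default 0.2 s); S2 is centered on the largest envelope peak after the
T-wave end with half-width half the mean S2 duration; systole and diastole
fill the gaps. These ECG-guided maps are what the duration model is fitted
on. The phrasing of the underlying labeling rule conflates the R–R
interval with the S1 duration; we read $\bar S_1$ as the mean S1 dwell
(the only reading that yields a bounded S1), and keep the rule's standard
deviations as quality-control tolerances rather than boundary parameters.

## Feature maps

**MFSC.** Frames (25 ms Hamming, 10 ms hop) are zero-padded to a 512-point
FFT; the one-sided power spectrum passes through a 64-filter triangular
Mel bank spanning 25–1000 Hz, and each filter's energy is floored at
$10^{-10}$ before the natural log. The floor keeps silent frames finite;
the bank satisfies the exact partition property (adjacent filter edges sum
to 1 between centers). Frame length, FFT size and filter count are not
dictated by the method's sources; these values give roughly square maps at
the 2 kHz canonical rate and a comfortable margin against duplicate center
bins.

**Envelope matrix.** The homomorphic envelope is band-pass filtered
(order-2 Butterworth, 25–400 Hz), converted to its analytic magnitude,
log-transformed, low-pass filtered forward-backward (order 1, 8 Hz, zero
phase) and exponentiated. About half a second of the signal is reflected
at each end first so the filter transients stay in the padding — this also
makes the whole chain exactly amplitude-equivariant. Each complete cycle's
envelope is max-pooled over 3-sample windows (the minimum region that
still smooths without erasing pathological detail), logged, resampled to a
common row length, and stacked; the stack is centralized and normalized,
$G = (Q-\bar Q)/\max|Q-\bar Q|$, so $\mathrm{mean}(G)=0$ and
$\max|G| = 1$. We read the normalization denominator as the maximum
*absolute* deviation: the literal maximum of $Q-\bar Q$ would leave
negative excursions unbounded below $-1$. The global scalar mean (not
per-row) is used, keeping between-cycle amplitude differences visible.

**Fusion.** Frame energy is the channel mean of the MFSC map. Per cardiac
cycle, the threshold is that cycle's mean frame energy; a 0.2 s sliding
window (stride one frame) strictly exceeding the threshold flags all its
frames, and the mask is the union over windows. Strict inequality makes
the constant-map case well defined (nothing is flagged). Where the mask is
true $W = M + G$; elsewhere $W = (M+G)/2$, with the per-cycle envelope row
broadcast across the Mel channel axis at each frame. The two maps live on
different scales (log-energy vs dimensionless $[-1,1]$); the overlay is
applied as defined, without rescaling, and the classifier's per-map
z-scoring absorbs the offset.

## Classifier

Four groups of convolution → batch normalization → ReLU → mixed pooling
(2×2, stride 2) → coordinate attention, then global average pooling and a
sigmoid unit. Groups 1–2 use standard 3×3 convolutions (32, 64 channels);
groups 3–4 use depthwise-separable convolutions (128, 256 channels), which
cut the parameter count (e.g. $64\cdot9 + 64\cdot128 = 8{,}768$ weights
versus $73{,}728$ for the standard equivalent). Group counts 1–5 all
build; 4 is the default.

*Mixed pooling* blends max and average pooling,
$y = \lambda\,\max + (1-\lambda)\,\mathrm{mean}$, with
$\lambda \sim \mathrm{Bernoulli}(0.5)$ redrawn per pooling layer per
training batch (the sources say only "a random value"). At inference
$\lambda$ is fixed at 0.5: stochastic inference would make predictions
non-deterministic for no accuracy benefit.

*Coordinate attention* average-pools the block along each spatial axis
separately, concatenates the two pooled maps along the spatial axis,
squeezes them through a shared 1×1 bottleneck (reduction 8, with batch
normalization and ReLU), re-expands per axis, and gates the input with the
two sigmoid maps — so the attention retains positional information along
both the time and frequency axes, unlike a squeeze-and-excitation gate.

Training minimizes clipped binary cross-entropy with Adam (learning rate
0.001, batch 64, default 100 epochs; the validation experiments in this
package use 25 or fewer — problem sizes are stated below). Input maps are
bilinearly resized to 32×32 and z-scored per map. All randomness
(initialization, shuffling, $\lambda$ draws) derives from one seed, and
training is bitwise reproducible single-threaded.

One numerical choice deserves a note: after the last epoch the batch-norm
running statistics are recomputed in a single equal-weight pass over the
training set. With few gradient steps the momentum-0.9 running averages
are still close to their initialization and inference quality collapses;
the recalibration makes inference statistics match the data exactly,
independent of epoch count.

## Synthetic data: what it emulates, and what it does not

The generator builds each recording as Gaussian-windowed tone bursts — S1
at 50 Hz (amplitude 1.0), S2 at 70 Hz (amplitude 0.8) — on a quasi-periodic
grid: cycle lengths are 0.8 s on average with per-cycle Gaussian jitter
(sd 0.02 s, truncated at ±3 sd), S1 and S2 each last 0.2 s, and the S2
onset is placed at $s_1 + 0.3\,(L - s_1 - s_2)$ into the cycle so systole
is shorter than diastole, as in a real cycle (this asymmetry also breaks
the half-cycle relabeling symmetry that would make an envelope-only
segmenter ambiguous). CHD records add a murmur: zero-mean noise band-passed
100–400 Hz, gated by the systolic window (or the whole cycle for
"continuous"), at 6 dB below the heart-sound power — a clearly audible
but non-dominant murmur. White noise is added at 20 dB SNR, a clean
clinical recording; the sources describe collection in cluttered
environments but give no noise model, so this is a free choice. Defaults
are 2 kHz sampling (the canonical internal rate) and 10 s duration
(a dozen cycles — enough for stable per-cycle statistics at a fraction of
the compute of a 20 s record). R peaks fall at S1 onsets and T-wave ends
20 ms before S2 onsets, including for a final cycle the recording cuts
short, as a real synchronized ECG would show.

Validation against this generator shows that the pipeline's machinery is
correct and that the classifier can learn a murmur signature; it does not
show clinical performance. Real PCG has inter-patient variability in heart
rate, murmur character, sensor coupling and noise that the generator does
not model, and the published accuracies on clinical databases are not
reproducible from synthetic data.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use: 20 recordings for
segmentation recovery (≥90% frame agreement required), a 200-recording
cohort (100 normal / 100 CHD, stratified 70/20/10 split) for the
end-to-end surrogate with 25 training epochs for the fused model and 8 for
the single-feature ablations, 50 sixteen-frame instances for decoder
optimality against exhaustive enumeration, and 100 seeded instances per
brute-force oracle (autocorrelation, MFSC, mixed pooling, local overlay,
depthwise-separable convolution) at $10^{-9}$ relative tolerance. Every
randomized step takes its seed from the one passed on the command line.

## Known limitations

* The emission model is one-dimensional; recordings whose murmur energy
  rivals S1/S2 (loud continuous murmurs) blur the envelope contrast the
  segmenter relies on. ECG-guided labeling is unaffected and is used
  whenever fiducials are present.
* Eq-level faithfulness means the fused map mixes units (log-energy plus a
  dimensionless envelope); the classifier normalizes per map, but the
  fused values themselves are not interpretable as energies.
* The CNN engine is plain R + BLAS; it is fast enough for desk-scale
  experiments (seconds per epoch at 32×32) but not for database-scale
  training.
* `eval_report` returns `NA` (not 0) for metrics whose denominator class
  is absent, so single-class test splits surface as missing values rather
  than inflated averages.
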