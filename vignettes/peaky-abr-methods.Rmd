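---
title: "Deriving brainstem responses to continuous speech: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving brainstem responses to continuous speech: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakyabr)
```

## The problem

The auditory brainstem response (ABR) is a sub-10-ms scalp potential whose
component waves (I, III, V) index successive stations from the auditory
nerve to the rostral brainstem. Classically it is evoked by isolated clicks;
with regressor-based deconvolution it can also be derived from EEG recorded
during *continuous* speech, provided the speech is re-synthesized so that
its voiced portions are click-like ("peaky" speech). Because voiced speech
excites the ear quasi-periodically at the fundamental frequency (f0), f0
acts as an effective stimulation rate: talkers with higher f0 evoke smaller,
later ABRs, which confounds talker comparisons. This package implements the
complete analysis chain for studying that rate/f0 effect — stimulus
construction, response derivation, a forward model of the periphery, and the
comparison statistics — together with a seeded synthetic-data generator so
that every stage can be validated against known ground truth without any
recorded data.

## The measurement model

The core assumption is linearity at the level of the pulse train: the EEG
recorded during a trial is modelled as

$$x(t) = \sum_k h(t - t_k) + \varepsilon(t),$$

where $t_k$ are glottal-pulse or click times, $h$ is the ABR kernel
(impulse response, nV) and $\varepsilon$ is noise. Writing the pulse train
as a unit-impulse regressor $r(t)$, the kernel is estimated per condition in
the frequency domain. For clicks the estimator is the normalized
cross-correlation $\hat H = \overline{R} X / n_\text{pulses}$; for peaky
speech it is the regularized deconvolution

$$\hat H(f) = \frac{\sum_i w_i \overline{R_i}(f) X_i(f)}
                  {\sum_i w_i |R_i(f)|^2 + \epsilon \cdot
                   \overline{\sum_i w_i |R_i|^2}},$$

pooling trials $i$ with inverse-variance weights
$w_i = (1/v_i) / \sum_j (1/v_j)$, $v_i$ the variance of trial $i$'s
filtered EEG over the trial proper (pads excluded). Pooling before the
division matters: a single short trial's regressor autospectrum has deep
valleys between f0 harmonics, and dividing per trial amplifies noise there;
summing autospectra across trials with differing prosody fills the valleys.
The per-trial route is retained (`combine = "per_trial"`), and coincides
with the pooled route for spectrally flat regressors. The ridge defaults to
$\epsilon = 10^{-3}$ of the mean pooled autospectrum; bins with no regressor
energy at all are zeroed.

Regressors are *unsigned*: the ABR does not invert with acoustic polarity,
so counter-phased stimulus presentations (click epochs ordered
A⁺A⁻B⁺B⁻, speech segments alternating in sign) add constructively for the
neural response while polarity-locked stimulus artifacts cancel. This
cancellation is tested explicitly.

Epochs comprise the trial plus symmetric pads (1 s around a 10-s trial, so
12 s at the 10 kHz EEG rate); the FFT length equals the epoch length, so
circular wrap-around is confined to the pads. The front end is a causal
first-order Butterworth band-pass, 150–2000 Hz (causality preserves
component latencies), plus 5-Hz-wide second-order notches at odd multiples
of 60 Hz. Two recorded channels are combined by averaging the derived
per-channel responses. A fixed acoustic delay (0.9 ms earphone tubing in the
reference recording setup) can be removed on the lag axis. The retained lag
axis spans −20 to +60 ms; the pre-stimulus part estimates the noise floor.

## Stimuli

Six speech conditions (two talkers × three target f0s: each talker's own
mean f0, the other's, and their geometric mean — `target_f0_set(123, 183)`
gives 123, 150.03, 183 Hz) and three click conditions at matching mean
rates.

* **Pitch tracking** is frame-based normalized autocorrelation (40 ms
  frames, 10 ms hop, 60–400 Hz search range, voicing threshold 0.45 with
  parabolic peak interpolation). The tracker settings are declared package
  defaults; they are not facts about any particular recording.
* **Pitch shifting** is time-domain pitch-synchronous overlap-add (PSOLA):
  two-period Hann grains centred on the signal's own glottal pulses are
  re-positioned at pulse times integrated from the scaled f0 contour.
  Grains are not resampled, so formants are preserved and duration is
  unchanged. Shift factors follow the semitone convention
  $2^{\text{semitones}/12}$ and are restricted to [0.5, 2].
* **Peaky re-synthesis** is phase-only: in voiced STFT frames (1024 samples
  at 48 kHz, hop 256, Hann) the phase is replaced by the phase of the pulse
  train rendered as unit impulses, while magnitudes are kept; frames outside
  voiced spans keep the original complex spectrum, and overlap-add
  synthesis cross-fades the boundaries. This aligns harmonic phases at each
  glottal pulse — the waveform becomes click-like, the magnitude
  spectrogram is preserved (tested: magnitude correlation ≥ 0.90, strictly
  increased excess kurtosis, RMS within ±3 dB).
* **Click trains** are pseudorandom Poisson processes: exponential
  inter-click intervals with a 1 ms refractory floor (the exponential mean
  is reduced so the overall mean ISI is exactly 1/rate); 150 unique 1-s
  epochs per rate, each followed by its polarity-inverted twin, concatenated
  into 10-s trials. Clicks are rectangular, 2 samples at 48 kHz (~100 µs),
  spectrally flat beyond 10 kHz.
* **Segmentation**: silences longer than 0.5 s are truncated (frame RMS
  more than 40 dB below the peak frame RMS marks silence — a declared
  default), audio is spliced into exact 10-s segments with 0.03-s
  raised-cosine fades, remainders dropped, polarity alternating between
  segments.

## The synthetic-data generator

The generator defines the study conditions every test runs under.

* **Kernel**: each wave is a Gaussian-windowed single cycle (Gabor-like
  bump) whose positive lobe peaks exactly at the stated latency with the
  stated amplitude and whose trough follows one width later — unambiguous
  targets for peak-to-trough measurement. Defaults: waves I/III/V at
  1.7/3.9/6.9 ms, 30/45/100 nV, widths 0.5/0.7/1.1 ms — canonical click-ABR
  morphology with wave V dominant.
* **Speech**: a source–filter stand-in. Voiced spans excite resonators
  (default formants 500/1500/2500 Hz) with pulses placed where the running
  phase $2\pi\int f_0\,dt$ crosses multiples of $2\pi$; unvoiced spans are
  low-level filtered noise. The exact pulse times are returned. It makes no
  attempt at acoustic realism beyond what the analysis is sensitive to; in
  particular it cannot reproduce narrator idiosyncrasies, so passing tests
  validate the machinery, not claims about any real talker.
* **Glottal-like regressor trains** carry a slow AR(1) prosodic drift of
  the local rate (SD 12%, correlation ~0.985 per cycle) plus 3%
  cycle-to-cycle jitter and occasional unvoiced gaps. The drift is what
  gives natural narration its dense regressor spectrum; without it a
  constant-f0 train is spectrally sparse and deconvolution is ill-posed.
* **EEG**: per trial, the unsigned regressor is convolved with the
  (rate-adjusted) kernel; noise is pink (1/f power, synthesized by
  spectral shaping), plus 60 Hz odd harmonics, plus per-trial variance
  multipliers drawn log-uniformly from [0.25, 4] so that inverse-variance
  weighting is genuinely better than uniform averaging. Identical seeds
  give bit-identical recordings.
* **Noise level**: the published split-half null correlations of the
  reference study (medians 0.96/0.93/0.83 over 2–12 ms) pin down its
  effective waveform SNR; reproducing them at the 20-min study scale gives
  the defaults of 2500 nV broadband pink RMS and 500 nV per line harmonic
  (~1.1 µV in the 150–2000 Hz analysis band).
* **Rate adaptation** emulates the measured f0/rate effects as a per-trial
  global kernel scale and shift driven by the train's design rate:
  −0.74 nV/Hz on the wave V peak (which yields the measured 1.80× male/
  female amplitude ratio between 123 and 183 Hz on a 100 nV wave V) and
  +0.003 ms/Hz latency. Per-pulse (ISI-conditioned) adaptation is out of
  scope: the mean-rate trends are what the package needs to be able to
  recover, and rate-of-f0-change effects are unresolved in the literature.
  The design rate rather than the realized pulses-per-second drives the
  adjustment, because unvoiced pauses would otherwise dilute the rate of a
  train whose voiced stretches pulse at exactly f0.

Desk-scale property simulations use fewer and shorter trials than the 20-min
(120 × 10 s) recording conditions; noise RMS is scaled by the square root of
the data-length reduction so the derived-waveform SNR stays representative
(`scaled_noise_spec()`).

## The forward model

A bundled `simple` auditory-periphery backend drives wave synthesis; any
published auditory-nerve model can be plugged in as a function with the same
contract (CF × time firing-rate matrix at the EEG rate).

Per characteristic frequency (42 CFs log-spaced 125 Hz–16 kHz, both
endpoints included — near 1/6-octave spacing), the `simple` backend chains:
a first-order 350–6000 Hz middle-ear band-pass; a 4th-order gammatone filter
with unit gain at CF (so basal channels respond to broadband transients with
large fast responses, as they should); broken-stick compression (linear
below ~31 dB SPL, exponent 0.4 above); half-wave rectification with a
700 Hz inner-hair-cell low-pass (the phase-locking limit of the far-field
generators); a saturating synapse (1200 spikes/s ceiling); three-stage
subtractive exponential adaptation (2/60/300 ms); a 60 spikes/s spontaneous
floor; and anti-aliased decimation from 48 kHz to 10 kHz. Stimuli enter at
65 dB peSPL with digital full scale mapping to the peak pressure of an
equally-peaked sinusoid.

Simulated EEG is the population rate — channels summed with weights
proportional to $\sqrt{\mathrm{ERB}(CF)}$, reflecting the growth of the
synchronously driven fiber count with filter bandwidth — copied once per
wave with a per-wave scale (nV per unit rate) and latency shift
(constant brainstem conduction delays, increasing I→III→V). The simulated
EEG passes the same 150–2000 Hz front end as measured EEG before
derivation; this removes the slow voicing-locked rate pedestal that would
otherwise dominate speech responses. Wave scales and shifts are fitted to a
reference click ABR by grid search: coordinate descent over waves in order
V, III, I with a second refinement sweep, objective RMS error over 0–10 ms
lags. Sequential single-pass fitting in I→III→V order cannot recover
planted parameters because the per-wave unit responses overlap strongly and
wave V dominates; the two-sweep descent recovers on-grid truth exactly.

With these defaults the model reproduces the qualitative pattern of the
measured data: wave V amplitudes fall strictly with rate/f0 for both
stimulus classes; clicks are larger and earlier than speech at every
matched rate; modeled click latency does not move with rate, and modeled
speech latency is non-decreasing in f0. The backend's parameters were fixed
by inspecting single-click population morphology (one clean dominant bump,
small late energy), not by tuning to the comparison outcomes.

## Statistics

* `window_pearson()` compares waveform morphologies over 2–12 ms.
* `split_half_null()` builds the null: trials split into even/odd halves
  balanced across the two conditions, so each half contains both conditions
  equally and any condition effect is nullified; the halves are derived
  exactly like conditions. Odd trial counts drop the last trial with a
  warning.
* `signed_rank()` wraps the Wilcoxon signed-rank test: exact p by
  enumeration for n ≤ 25 without ties, normal approximation with continuity
  correction otherwise. `fdr_adjust()` is Benjamini–Hochberg.
* `pick_wave_v()` takes the largest local maximum in 4–12 ms (ties to the
  earlier peak — the study picked peaks manually, so an automated
  deterministic rule is required) and the minimum within 6 ms after the
  peak as the following trough. A first-local-minimum trough rule proved
  unstable on waveforms with residual ripple (it can latch onto a sub-nV
  dip one sample after the peak); the bounded-window minimum is the
  standard clinical reading and is identical on clean kernels. The peak
  must exceed twice the pre-stimulus (−20–0 ms) RMS or the measure is
  flagged not-found.
* `summarize_conditions()` returns tidy per-condition means ± SE and
  per-participant male/female amplitude ratios (paired on target f0 when a
  `target_f0` column is present, else per participant), ready for any
  external mixed-model fitter; mixed-effects estimation itself is
  deliberately out of scope.

## Numerical choices and problem sizes

* Filters: IIR cascades run through `stats::filter`; recordings longer than
  10⁶ samples use an exact FFT-domain application of the cascade's combined
  frequency response (5-smooth FFT lengths), identical up to circular wrap
  at the recording edges, which the pads absorb.
* Kernel-recovery experiments compare the derived waveform against the
  embedded kernel *as observed through the acquisition front end*: the
  causal first-order band-pass reshapes any waveform passing through it and
  caps correlation against the raw kernel near 0.966 regardless of noise.
  The raw-kernel correlation is reported alongside.
* The weighting-benefit experiments measure residual error against the
  noise-free output of the identical pipeline on the same trains: weighting
  addresses noise, and the deterministic ISI-echo structure (identical
  under both weightings) would otherwise mask the comparison. Under
  deconvolution, concentrating weight on a few trials impoverishes the
  pooled regressor spectrum and can offset the variance gain — a real
  effect worth knowing about; the property is therefore demonstrated on the
  cross-correlation route.
* Statistical calibration uses cohorts of 6 × 0.5-s trials per condition,
  one channel, pink-only noise with the band-pass front end, at the
  SNR-preserving noise scale; 500 null cohorts (n = 9) for size and 150
  effect cohorts (n = 15) for power. Kernel recovery uses the study's full
  20 min per condition (120 × 10-s trials) on the two-channel montage. The embedded
  amplitude-ratio recovery runs at a 2-h-equivalent SNR because
  peak-picking on noisy waveforms is biased upward more for the smaller
  response, compressing measured ratios — at study SNR the 1.80 embedded
  ratio reads ~1.5, itself an instructive property of the estimator, not a
  defect.
* Peak-latency precision: the argmax of a smooth ~1-ms-wide bump under
  band-limited noise has a dispersion of several 0.1-ms samples even at
  20 dB SNR; exact one-sample recovery holds only in the noise-free case,
  and the tests assert exactly that plus a median error bound at 6 dB.

## Limitations

The generator's speech is a resonator vowel stand-in: no articulation,
coarticulation, or narrator idiosyncrasies, so residual talker differences
observed in real data are outside what these simulations can probe. The
`simple` periphery is a didactic signal-chain model — it reproduces
qualitative rate and stimulus-class effects, not absolute physiological
rates or level series; quantitative modeling should plug in a published
auditory-nerve model via the `backend` hook. Adaptation in the generator is
mean-rate only. The split-half machinery assumes two conditions with
interleaved presentation.
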