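#' Specification of a ground-truth ABR kernel
#'
#' Describes an ABR impulse response as a sum of biphasic bumps, one per
#' component wave. Waves must appear in canonical order (I before III before
#' V) with strictly increasing latencies.
#'
#' @param waves data frame (or tibble) with columns `label` (one of
#'   `"I"`, `"III"`, `"V"`), `latency_ms`, `amplitude_nv`, `width_ms`.
#'   May have zero rows (silent kernel).
#' @param duration_ms total kernel duration; must cover
#'   `max(latency + 3 * width)`.
#' @param sample_rate Hz (default 10000, the EEG rate).
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(waves = default_abr_waves(), duration_ms = 16,
                        sample_rate = 10000) {
  waves <- as.data.frame(waves)
  if (nrow(waves)) {
    need <- c("label", "latency_ms", "amplitude_nv", "width_ms")
    if (!all(need %in% names(waves))) {
      stop("waves needs columns label, latency_ms, amplitude_nv, width_ms")
    }
    ord <- c(I = 1, III = 2, V = 3)
    if (!all(waves$label %in% names(ord))) stop("wave labels must be I, III or V")
    o <- ord[waves$label]
    if (any(diff(o) <= 0) || any(diff(waves$latency_ms) <= 0)) {
      stop("latencies must be strictly increasing in label order I < III < V")
    }
    if (any(waves$width_ms <= 0)) stop("widths must be > 0")
    if (duration_ms < max(waves$latency_ms + 3 * waves$width_ms)) {
      stop("duration must cover max latency + 3 x width")
    }
  }
  structure(list(waves = waves, duration_ms = duration_ms,
                 sample_rate = sample_rate),
            class = "kernel_spec")
}

#' Canonical wave I/III/V parameters used as ground truth
#'
#' Latencies follow typical click-ABR component latencies; wave V dominates,
#' as in scalp recordings.
#'
#' @return Data frame of wave parameters.
#' @export
default_abr_waves <- function() {
  data.frame(
    label = c("I", "III", "V"),
    latency_ms = c(1.7, 3.9, 6.9),
    amplitude_nv = c(30, 45, 100),
    width_ms = c(0.5, 0.7, 1.1)
  )
}

#' Rate-adaptation specification for the EEG simulator
#'
#' Emulates the measured stimulation-rate effects: wave amplitudes shrink and
#' latencies grow with increasing pulse rate (mean f0 or click rate). At the
#' reference rate the kernel is unmodified. The amplitude slope is expressed
#' in nV of wave V peak per Hz and applied as a global scale; the latency
#' slope shifts the whole kernel.
#'
#' @param amplitude_slope nV per Hz, must be <= 0.
#' @param latency_slope ms per Hz, must be >= 0.
#' @param reference_rate Hz at which the kernel is unmodified.
#' @return An `adaptation_spec` object.
#' @export
adaptation_spec <- function(amplitude_slope = -0.74, latency_slope = 0.003,
                            reference_rate = 123) {
  if (amplitude_slope > 0) stop("amplitude_slope must be <= 0")
  if (latency_slope < 0) stop("latency_slope must be >= 0")
  structure(list(amplitude_slope = amplitude_slope,
                 latency_slope = latency_slope,
                 reference_rate = reference_rate),
            class = "adaptation_spec")
}

# scale factor and latency shift for a train at mean rate `rate`
adaptation_terms <- function(adaptation, rate, peak_nv) {
  if (is.null(adaptation)) return(list(scale = 1, shift_ms = 0))
  d <- rate - adaptation$reference_rate
  scale <- (peak_nv + adaptation$amplitude_slope * d) / peak_nv
  if (scale <= 0) stop("adaptation drives kernel amplitude to <= 0 at this rate")
  list(scale = scale, shift_ms = adaptation$latency_slope * d)
}

#' Noise specification for synthetic EEG
#'
#' Pink (1/f power) background noise plus line harmonics at odd multiples of
#' the line frequency, the two artifact classes the ABR band-pass and notch
#' comb are designed against, with per-trial variance heterogeneity so that
#' inverse-variance weighting is strictly better than uniform averaging.
#'
#' @param pink_noise_rms broadband pink-noise RMS in nV.
#' @param line_freq line frequency in Hz (60 in North America).
#' @param line_harmonic_rms RMS in nV of each odd harmonic (60, 180, 300, ...).
#' @param per_trial_variance_spread length-2 range of per-trial variance
#'   multipliers, drawn log-uniformly; `c(1, 1)` disables heterogeneity.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(pink_noise_rms = 2500, line_freq = 60,
                       line_harmonic_rms = 500,
                       per_trial_variance_spread = c(0.25, 4)) {
  if (pink_noise_rms < 0 || line_harmonic_rms < 0) stop("RMS values must be >= 0")
  s <- sort(as.numeric(per_trial_variance_spread))
  if (length(s) != 2 || s[1] <= 0) stop("variance spread must be within (0, Inf)")
  structure(list(pink_noise_rms = pink_noise_rms, line_freq = line_freq,
                 line_harmonic_rms = line_harmonic_rms,
                 per_trial_variance_spread = s),
            class = "noise_spec")
}

#' Build a sampled ABR kernel from a wave specification
#'
#' Each wave is a Gaussian-windowed single cycle (Gabor-like biphasic bump):
#' the positive lobe peaks exactly at the stated latency with the stated
#' amplitude, and a negative lobe (trough) follows one width later, giving
#' unambiguous targets for peak-to-trough measurement. Waves close enough to
#' merge their peaks raise a warning, not an error.
#'
#' @param spec a [kernel_spec()].
#' @return A [response_waveform()] on lags `0 .. duration_ms`.
#' @export
make_kernel <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  n <- round(spec$duration_ms / 1000 * spec$sample_rate) + 1L
  lags <- (seq_len(n) - 1L) / spec$sample_rate * 1000
  amp <- numeric(n)
  for (i in seq_len(nrow(spec$waves))) {
    w <- spec$waves[i, ]
    tau <- lags - w$latency_ms
    sigma <- 0.75 * w$width_ms
    amp <- amp + w$amplitude_nv * exp(-tau^2 / (2 * sigma^2)) *
      cos(pi * tau / w$width_ms)
  }
  if (nrow(spec$waves) > 1) {
    # each stated peak must survive as a local maximum; merged peaks warn
    idx <- vapply(spec$waves$latency_ms, function(l) which.min(abs(lags - l)), 1L)
    ok <- vapply(idx, function(j) {
      j > 1 && j < n && amp[j] >= amp[j - 1] && amp[j] >= amp[j + 1]
    }, logical(1))
    if (!all(ok)) warning("overlapping waves merged one or more peaks")
  }
  response_waveform(lags, amp)
}

# seeded pink noise: white Gaussian spectrum shaped by 1/sqrt(f), scaled to rms
pink_noise <- function(n, rms) {
  if (rms == 0 || n == 0) return(numeric(n))
  m <- if (n > 1e6) stats::nextn(n, c(2, 3, 5)) else n  # fast FFT length
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- c(1, seq_len(m - 1))          # avoid f = 0; DC kept at lowest-bin gain
  f <- pmin(f, m - f + 1)            # mirror for negative frequencies
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  y <- y - mean(y)
  y * rms / stats::sd(y)
}

# line noise: sinusoids at odd multiples of line_freq, random seeded phase
line_noise <- function(n, sample_rate, line_freq, harmonic_rms, max_freq = 2500) {
  if (harmonic_rms == 0) return(numeric(n))
  t <- (seq_len(n) - 1) / sample_rate
  freqs <- line_freq * seq(1, floor(max_freq / line_freq), by = 2)
  y <- numeric(n)
  for (f in freqs) {
    y <- y + sqrt(2) * harmonic_rms * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
  }
  y
}

#' Synthesize a voiced/unvoiced speech-like signal with known pulse times
#'
#' A source-filter stand-in for narrated speech: within voiced spans a glottal
#' pulse train (placed by integrating the f0 contour's phase) excites a
#' cascade of second-order resonators at the given formant frequencies;
#' unvoiced spans are resonator-filtered white noise at low level. The exact
#' excitation times are returned, giving ground truth for pitch tracking and
#' for ABR regressors.
#'
#' @param contour an [f0_contour()] (f0 in 60-400 Hz where voiced).
#' @param formant_freqs resonator centre frequencies in Hz.
#' @param duration total duration in s (>= contour extent).
#' @param sample_rate Hz, >= 16000.
#' @param seed integer seed.
#' @param unvoiced_level RMS of unvoiced noise relative to voiced RMS.
#' @return List with elements `audio` (an [audio_stimulus()]) and `pulses`
#'   (a [pulse_train()]).
#' @export
make_synthetic_speech <- function(contour, formant_freqs = c(500, 1500, 2500),
                                  duration = NULL, sample_rate = 48000,
                                  seed = 1, unvoiced_level = 0.15) {
  stopifnot(inherits(contour, "f0_contour"))
  if (sample_rate < 16000) stop("sample_rate must be >= 16000")
  if (any(contour$f0[contour$voiced_mask] < 60) ||
      any(contour$f0[contour$voiced_mask] > 400)) {
    stop("voiced f0 must lie within [60, 400] Hz")
  }
  if (is.null(duration)) duration <- max(contour$frame_times)
  if (duration <= 0) stop("duration must be > 0")
  set.seed(seed)
  n <- round(duration * sample_rate)
  pulses <- pulses_from_contour(contour, duration = duration)
  x <- numeric(n)
  idx <- round(pulses$times * sample_rate) + 1L
  idx <- idx[idx >= 1 & idx <= n]
  x[idx] <- 1
  spans <- voiced_spans_from_contour(contour)
  # unvoiced excitation: low-level white noise outside voiced spans
  unv <- stats::rnorm(n) * unvoiced_level * sqrt(mean(contour$f0[contour$voiced_mask]) / sample_rate)
  if (nrow(spans)) {
    t <- (seq_len(n) - 1) / sample_rate
    voiced_here <- rep(FALSE, n)
    for (k in seq_len(nrow(spans))) {
      voiced_here <- voiced_here | (t >= spans[k, 1] & t < spans[k, 2])
    }
    unv[voiced_here] <- 0
  }
  excitation <- x + unv
  y <- excitation
  for (f in formant_freqs) {
    bw <- 0.06 * f + 50
    r <- exp(-pi * bw / sample_rate)
    a <- c(1, -2 * r * cos(2 * pi * f / sample_rate), r^2)
    g <- sum(a)  # unit gain at DC keeps levels tame
    y <- as.numeric(signal::filter(signal::Arma(b = g, a = a), y))
  }
  y <- y / max(abs(y))
  audio <- audio_stimulus(y, sample_rate, voiced_spans = spans, kind = "speech")
  list(audio = audio, pulses = pulses)
}

# voiced spans (start, end) from a contour's frame mask
voiced_spans_from_contour <- function(contour) {
  v <- contour$voiced_mask
  if (!any(v)) return(matrix(numeric(0), ncol = 2))
  dt <- if (length(contour$frame_times) > 1) diff(contour$frame_times)[1] else 0.01
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  cbind(contour$frame_times[starts[keep]] - dt / 2,
        contour$frame_times[ends[keep]] + dt / 2)
}

#' Convenience constant-or-modulated f0 contour
#'
#' @param duration s.
#' @param mean_f0 Hz.
#' @param vibrato_hz modulation rate of the f0 wobble (0 for constant f0).
#' @param vibrato_depth fractional f0 excursion.
#' @param voiced_fraction fraction of frames voiced; voicing is laid out as
#'   alternating voiced/unvoiced stretches (1 = fully voiced).
#' @param hop frame hop in s.
#' @return An [f0_contour()].
#' @export
synth_f0_contour <- function(duration, mean_f0, vibrato_hz = 0,
                             vibrato_depth = 0.02, voiced_fraction = 1,
                             hop = 0.01) {
  t <- seq(hop / 2, duration, by = hop)
  f0 <- mean_f0 * (1 + vibrato_depth * sin(2 * pi * vibrato_hz * t))
  if (voiced_fraction < 1) {
    # ~1 s voiced stretches separated by unvoiced gaps
    cycle <- 1 / voiced_fraction
    f0[(t %% cycle) > 1] <- 0
  }
  f0_contour(t, f0)
}

#' Simulate one subject's EEG from a kernel and per-trial pulse trains
#'
#' Forward model of the measurement: per trial the signed pulse regressor is
#' convolved with the (rate-adjusted) kernel; pink noise, line harmonics and
#' per-trial variance heterogeneity are added per [noise_spec()]. Trials are
#' laid out back to back after a leading pad so that 1-s epoch pads contain
#' genuine noise. Identical seeds give bit-identical recordings.
#'
#' @param kernel a [response_waveform()] at the EEG rate (lags from 0).
#' @param trains list of [pulse_train()], one per trial (equal durations).
#' @param noise a [noise_spec()].
#' @param adaptation an [adaptation_spec()] or `NULL`.
#' @param n_channels number of EEG channels (2 in the recording montage).
#' @param seed integer seed.
#' @param sample_rate EEG rate, Hz.
#' @param edge_pad leading/trailing recording pad in s.
#' @return An [eeg_recording()]; attribute `"embedded_kernels"` holds the
#'   per-trial rate-adjusted kernels actually convolved in, and
#'   `"variance_multipliers"` the per-trial noise variance draws.
#' @export
simulate_subject_eeg <- function(kernel, trains, noise = noise_spec(),
                                 adaptation = NULL, n_channels = 2, seed = 1,
                                 sample_rate = 10000, edge_pad = 1.5) {
  stopifnot(inherits(kernel, "response_waveform"))
  trial_dur <- trains[[1]]$duration
  if (any(vapply(trains, function(tr) tr$duration, 1) != trial_dur)) {
    stop("all trials must have equal duration")
  }
  if (max(kernel$lags_ms) / 1000 >= trial_dur) stop("kernel longer than trial")
  set.seed(seed %% 2147483647)
  n_trials <- length(trains)
  npad <- round(edge_pad * sample_rate)
  ntrial <- round(trial_dur * sample_rate)
  n <- 2L * npad + n_trials * ntrial
  onsets <- edge_pad + (seq_len(n_trials) - 1) * trial_dur
  kpeak <- max(abs(kernel$amplitude_nv))
  embedded <- vector("list", n_trials)
  signal_tr <- matrix(0, n_trials, ntrial + length(kernel$amplitude_nv) - 1L)
  for (i in seq_len(n_trials)) {
    tr <- trains[[i]]
    # adaptation follows the train's design rate (mean f0 / click rate);
    # pulses-per-duration would be diluted by unvoiced pauses
    rate <- if (tr$nominal_rate > 0) {
      tr$nominal_rate
    } else if (trial_dur > 0) length(tr$times) / trial_dur else 0
    ad <- adaptation_terms(adaptation, rate, kpeak)
    k <- kernel
    k$amplitude_nv <- k$amplitude_nv * ad$scale
    k$lags_ms <- k$lags_ms + ad$shift_ms
    k <- resample_response(k, kernel$lags_ms + c(0))  # back to lag grid, 0..dur
    embedded[[i]] <- k
    # neural response is polarity-insensitive: unsigned impulse regressor
    reg <- numeric(ntrial)
    ix <- round(tr$times * sample_rate) + 1L
    ix <- ix[ix >= 1 & ix <= ntrial]
    reg[ix] <- 1
    signal_tr[i, ] <- fft_convolve(reg, k$amplitude_nv)
  }
  mult <- exp(stats::runif(n_trials,
                           log(noise$per_trial_variance_spread[1]),
                           log(noise$per_trial_variance_spread[2])))
  eeg <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    noi <- pink_noise(n, noise$pink_noise_rms) +
      line_noise(n, sample_rate, noise$line_freq, noise$line_harmonic_rms)
    for (i in seq_len(n_trials)) {
      a <- npad + (i - 1L) * ntrial
      span <- (a + 1L):(a + ntrial)
      noi[span] <- noi[span] * sqrt(mult[i])
    }
    eeg[ch, ] <- noi
    for (i in seq_len(n_trials)) {
      a <- npad + (i - 1L) * ntrial
      len <- min(ncol(signal_tr), n - a)
      span <- (a + 1L):(a + len)
      eeg[ch, span] <- eeg[ch, span] + signal_tr[i, seq_len(len)]
    }
  }
  rec <- eeg_recording(eeg, sample_rate, trial_onsets = onsets)
  attr(rec, "embedded_kernels") <- embedded
  attr(rec, "variance_multipliers") <- mult
  rec
}

# linear convolution via FFT, returns length nx + nk - 1
fft_convolve <- function(x, k) {
  n <- length(x) + length(k) - 1L
  nf <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                     stats::fft(c(k, numeric(nf - length(k)))), inverse = TRUE)) / nf
  y[seq_len(n)]
}
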