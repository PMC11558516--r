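#' Track the fundamental-frequency contour of an audio signal
#'
#' Frame-based normalized-autocorrelation pitch tracker in the Praat family:
#' 40 ms analysis frames at a 10 ms hop, candidate lags spanning
#' `fmin`..`fmax`, a frame declared voiced when the normalized
#' autocorrelation peak exceeds `voicing_threshold`, with parabolic
#' interpolation of the peak lag.
#'
#' @param audio an [audio_stimulus()].
#' @param fmin,fmax pitch search range in Hz.
#' @param hop frame hop in s.
#' @param frame_dur analysis frame length in s.
#' @param voicing_threshold normalized autocorrelation threshold (default 0.45).
#' @return An [f0_contour()].
#' @export
track_pitch <- function(audio, fmin = 60, fmax = 400, hop = 0.01,
                        frame_dur = 0.04, voicing_threshold = 0.45) {
  stopifnot(inherits(audio, "audio_stimulus"))
  if (fmin >= fmax) stop("fmin must be < fmax")
  x <- audio$samples
  if (!length(x)) stop("audio is empty")
  sr <- audio$sample_rate
  nf <- round(frame_dur * sr)
  nh <- round(hop * sr)
  lag_min <- max(2L, floor(sr / fmax))
  lag_max <- ceiling(sr / fmin)
  if (lag_max >= nf) stop("frame too short for fmin")
  starts <- seq(1L, length(x) - nf + 1L, by = nh)
  if (!length(starts)) stop("audio shorter than one analysis frame")
  times <- (starts - 1 + nf / 2) / sr
  f0 <- numeric(length(starts))
  glob_rms <- sqrt(mean(x^2))
  for (i in seq_along(starts)) {
    fr <- x[starts[i]:(starts[i] + nf - 1L)]
    fr <- fr - mean(fr)
    e0 <- sum(fr^2)
    if (e0 < (1e-4 * glob_rms)^2 * nf || e0 == 0) next  # silent frame
    ac <- stats::acf(fr, lag.max = lag_max, plot = FALSE,
                     demean = FALSE, type = "correlation")$acf[, 1, 1]
    cand <- lag_min:lag_max
    r <- ac[cand + 1L]
    j <- which.max(r)
    if (r[j] < voicing_threshold) next
    lag <- cand[j]
    # parabolic interpolation around the peak
    if (j > 1 && j < length(cand)) {
      y1 <- r[j - 1]; y2 <- r[j]; y3 <- r[j + 1]
      den <- y1 - 2 * y2 + y3
      if (den < 0) lag <- lag + 0.5 * (y1 - y3) / den
    }
    f0[i] <- sr / lag
  }
  f0[f0 < fmin | f0 > fmax] <- 0
  f0_contour(times, f0)
}

#' The three target f0 conditions for a talker pair
#'
#' Given the natural f0s of two talkers, returns the sorted set of target
#' f0s each talker is shifted to: each talker's own f0, the other talker's
#' f0, and the geometric mean of the two (six conditions in total over two
#' talkers).
#'
#' @param f0_a,f0_b natural mean f0s in Hz.
#' @return Sorted numeric vector of three target f0s.
#' @export
target_f0_set <- function(f0_a, f0_b) {
  if (f0_a <= 0 || f0_b <= 0) stop("f0s must be > 0")
  sort(c(f0_a, sqrt(f0_a * f0_b), f0_b))
}

#' Shift the mean f0 of speech while preserving the spectral envelope
#'
#' Time-domain pitch-synchronous overlap-add (PSOLA): the signal's own
#' glottal pulses are located by pitch tracking, two-period Hann-windowed
#' grains centred on those pulses are re-positioned at the new pulse times
#' obtained by scaling the f0 contour by `factor`, and unvoiced stretches are
#' passed through unchanged. Duration is unchanged; formants are preserved
#' because the grains are not resampled. The shift factor follows the
#' semitone convention `factor = 2^(semitones/12)`.
#'
#' @param audio an [audio_stimulus()].
#' @param factor f0 ratio in `[0.5, 2]`.
#' @return A pitch-shifted [audio_stimulus()].
#' @export
shift_pitch <- function(audio, factor) {
  stopifnot(inherits(audio, "audio_stimulus"))
  if (factor < 0.5 || factor > 2) stop("factor must lie in [0.5, 2]")
  if (factor == 1) return(audio)
  sr <- audio$sample_rate
  contour <- track_pitch(audio)
  old_pulses <- pulses_from_contour(contour, duration = audio_duration(audio))
  if (!length(old_pulses$times)) return(audio)
  shifted <- contour
  shifted$f0 <- contour$f0 * factor
  shifted <- f0_contour(shifted$frame_times, shifted$f0)
  new_pulses <- pulses_from_contour(shifted, duration = audio_duration(audio))
  x <- audio$samples
  n <- length(x)
  spans <- voiced_spans_from_contour(contour)
  voiced_mask <- rep(FALSE, n)
  t <- (seq_len(n) - 1) / sr
  for (k in seq_len(nrow(spans))) {
    voiced_mask <- voiced_mask | (t >= spans[k, 1] & t < spans[k, 2])
  }
  y <- x
  y[voiced_mask] <- 0
  acc <- numeric(n)
  for (tp in new_pulses$times) {
    j <- which.min(abs(old_pulses$times - tp))
    src <- round(old_pulses$times[j] * sr) + 1L
    # local original period sets the grain length (two periods, Hann)
    per <- if (j < length(old_pulses$times)) {
      old_pulses$times[j + 1] - old_pulses$times[j]
    } else if (j > 1) {
      old_pulses$times[j] - old_pulses$times[j - 1]
    } else 0.008
    half <- max(8L, round(per * sr))
    g <- (-half):(half)
    w <- 0.5 * (1 + cos(pi * g / half))
    si <- src + g
    ok <- si >= 1 & si <= n
    dst <- round(tp * sr) + 1L + g
    ok <- ok & dst >= 1 & dst <= n
    y[dst[ok]] <- y[dst[ok]] + x[si[ok]] * w[ok]
    acc[dst[ok]] <- acc[dst[ok]] + w[ok]
  }
  # normalize overlap-add gain inside voiced regions
  fix <- voiced_mask & acc > 0.25
  y[fix] <- y[fix] / acc[fix]
  out <- audio
  out$samples <- y
  out
}

#' Glottal pulse times from an f0 contour
#'
#' Within each voiced span the running phase `phi(t) = 2*pi*Int f0 dt`
#' (f0 linearly interpolated between frames) is integrated and a pulse is
#' placed at every crossing of an integer multiple of `2*pi`. Unvoiced spans
#' carry no pulses and the phase restarts at each voiced span.
#'
#' @param contour an [f0_contour()].
#' @param duration optional total duration in s (default: contour extent).
#' @return A [pulse_train()] with nominal rate equal to the contour mean f0.
#' @export
pulses_from_contour <- function(contour, duration = NULL) {
  stopifnot(inherits(contour, "f0_contour"))
  if (is.null(duration)) duration <- max(contour$frame_times)
  spans <- voiced_spans_from_contour(contour)
  times <- numeric(0)
  dt <- 1e-4
  for (k in seq_len(nrow(spans))) {
    a <- max(0, spans[k, 1]); b <- min(duration, spans[k, 2])
    if (b <= a) next
    tt <- seq(a, b, by = dt)
    vf <- contour$frame_times[contour$voiced_mask]
    vv <- contour$f0[contour$voiced_mask]
    f <- stats::approx(vf, vv, xout = tt, rule = 2)$y
    phase <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * dt))  # cycles
    n_p <- floor(phase[length(phase)])
    if (n_p < 1) next
    times <- c(times, stats::approx(phase, tt, xout = seq_len(n_p))$y)
  }
  times <- sort(times[times < duration])
  rate <- if (is.na(contour$mean_f0)) 0 else contour$mean_f0
  pulse_train(times, duration = duration, nominal_rate = rate)
}

# --- STFT helpers (Hann analysis/synthesis, hop = n/4, COLA-normalized) -----

stft_mat <- function(x, n = 1024L, hop = n %/% 4L) {
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  starts <- seq(1L, length(x) - n + 1L, by = hop)
  fr <- vapply(starts, function(s) x[s:(s + n - 1L)] * w, numeric(n))
  list(S = stats::mvfft(fr), starts = starts, n = n, hop = hop, len = length(x))
}

istft_mat <- function(st) {
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(st$n - 1)) / st$n)
  fr <- Re(stats::mvfft(st$S, inverse = TRUE)) / st$n
  y <- numeric(st$len)
  norm <- numeric(st$len)
  for (i in seq_along(st$starts)) {
    ix <- st$starts[i]:(st$starts[i] + st$n - 1L)
    y[ix] <- y[ix] + fr[, i] * w
    norm[ix] <- norm[ix] + w^2
  }
  ok <- norm > 1e-8
  y[ok] <- y[ok] / norm[ok]
  y
}

#' Re-synthesize speech as broadband peaky speech
#'
#' Phase-only re-synthesis: the magnitude spectrogram of the input is kept
#' while, in voiced frames, the short-time phase is replaced with the phase
#' of the glottal pulse train rendered as unit impulses. This aligns the
#' harmonic phases at each glottal pulse, making the voiced waveform
#' click-like while the spectro-temporal content is preserved. Frames
#' entirely outside voiced spans keep the original complex spectrum, so
#' unvoiced portions come from the original audio, and the overlap-add
#' synthesis cross-fades voiced/unvoiced boundaries.
#'
#' @param audio an [audio_stimulus()].
#' @param pulses a [pulse_train()]; every pulse must lie inside a voiced span.
#' @param voiced_spans optional override of `audio$voiced_spans`.
#' @param n_fft STFT size in samples (21 ms at 48 kHz by default).
#' @return An [audio_stimulus()] of the same length.
#' @export
resynthesize_peaky <- function(audio, pulses, voiced_spans = NULL,
                               n_fft = 1024L) {
  stopifnot(inherits(audio, "audio_stimulus"), inherits(pulses, "pulse_train"))
  if (is.null(voiced_spans)) voiced_spans <- audio$voiced_spans
  voiced_spans <- matrix(as.numeric(voiced_spans), ncol = 2)
  in_span <- function(tt) {
    if (!nrow(voiced_spans)) return(rep(FALSE, length(tt)))
    ok <- rep(FALSE, length(tt))
    for (k in seq_len(nrow(voiced_spans))) {
      ok <- ok | (tt >= voiced_spans[k, 1] & tt <= voiced_spans[k, 2])
    }
    ok
  }
  if (length(pulses$times) && !all(in_span(pulses$times))) {
    stop("all pulses must lie inside voiced spans")
  }
  sr <- audio$sample_rate
  x <- audio$samples
  pad <- n_fft
  xp <- c(numeric(pad), x, numeric(pad))
  imp <- numeric(length(xp))
  ix <- pad + round(pulses$times * sr) + 1L
  imp[ix] <- pulses$polarity
  stx <- stft_mat(xp, n = n_fft)
  sti <- stft_mat(imp, n = n_fft)
  centers <- (stx$starts - 1 + n_fft / 2 - pad) / sr
  voiced_frame <- in_span(centers)
  mag_i <- Mod(sti$S)
  has_pulse <- colSums(mag_i) > 0
  repl <- voiced_frame & has_pulse
  if (any(repl)) {
    ph <- sti$S[, repl, drop = FALSE]
    ph <- ph / pmax(Mod(ph), 1e-12)
    stx$S[, repl] <- Mod(stx$S[, repl, drop = FALSE]) * ph
  }
  y <- istft_mat(stx)[pad + seq_along(x)]
  out <- audio
  out$samples <- y
  out$voiced_spans <- voiced_spans
  out
}

#' Randomized Poisson click-train epochs with counter-phased twins
#'
#' Unique epochs are drawn with exponentially distributed inter-click
#' intervals (a refractory floor keeps successive 100-us clicks physically
#' realizable; the exponential part has its mean reduced so the overall mean
#' ISI is exactly `1/rate`). Each epoch is paired with its polarity-inverted
#' twin, giving the presentation order A+ A- B+ B- ...
#'
#' @param rate mean click rate in Hz.
#' @param epoch_dur epoch duration in s.
#' @param n_epochs number of unique epochs.
#' @param seed integer seed.
#' @param refractory minimum ISI in s (default 1 ms).
#' @return List of length `n_epochs`; each element is a list of two
#'   [pulse_train()]s `(plus, minus)` with identical times and opposite
#'   polarity.
#' @export
make_poisson_clicks <- function(rate, epoch_dur = 1, n_epochs = 150, seed = 1,
                                refractory = 0.001) {
  if (rate <= 0) stop("rate must be > 0")
  if (1 / rate <= refractory) stop("rate too high for the refractory floor")
  set.seed(seed)
  lapply(seq_len(n_epochs), function(i) {
    times <- numeric(0)
    t <- 0
    repeat {
      t <- t + refractory + stats::rexp(1, 1 / (1 / rate - refractory))
      if (t >= epoch_dur) break
      times <- c(times, t)
    }
    plus <- pulse_train(times, duration = epoch_dur, polarity = 1,
                        nominal_rate = rate)
    list(plus = plus, minus = invert_polarity(plus))
  })
}

#' Concatenate click epochs (A+ A- B+ B- ...) into presentation trials
#'
#' @param epoch_pairs result of [make_poisson_clicks()].
#' @param trial_dur trial duration in s (10 s matches the speech buffers).
#' @return List of [pulse_train()]s, one per trial.
#' @export
concat_click_epochs <- function(epoch_pairs, trial_dur = 10) {
  seq_trains <- unlist(lapply(epoch_pairs, function(p) list(p$plus, p$minus)),
                       recursive = FALSE)
  epoch_dur <- seq_trains[[1]]$duration
  per_trial <- round(trial_dur / epoch_dur)
  n_trials <- floor(length(seq_trains) / per_trial)
  out <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    times <- numeric(0); pol <- numeric(0)
    for (j in seq_len(per_trial)) {
      tr <- seq_trains[[(i - 1) * per_trial + j]]
      times <- c(times, tr$times + (j - 1) * epoch_dur)
      pol <- c(pol, tr$polarity)
    }
    out[[i]] <- pulse_train(times, duration = trial_dur, polarity = pol,
                            nominal_rate = seq_trains[[1]]$nominal_rate)
  }
  out
}

#' Render a pulse train as a click waveform
#'
#' Rectangular condensation/rarefaction clicks of `click_samples` samples
#' (2 samples at 48 kHz, ~100 us, flat to beyond 10 kHz).
#'
#' @param train a [pulse_train()].
#' @param sample_rate Hz.
#' @param click_samples click width in samples.
#' @param amplitude peak amplitude.
#' @return An [audio_stimulus()] with `kind = "click"`.
#' @export
render_clicks <- function(train, sample_rate = 48000, click_samples = 2L,
                          amplitude = 1) {
  n <- round(train$duration * sample_rate)
  x <- numeric(n)
  for (k in seq_along(train$times)) {
    i0 <- round(train$times[k] * sample_rate) + 1L
    ix <- i0:min(n, i0 + click_samples - 1L)
    x[ix] <- amplitude * train$polarity[k]
  }
  audio_stimulus(x, sample_rate, kind = "click",
                 condition = sprintf("clicks_%g", train$nominal_rate))
}

#' Truncate silences, splice into fixed segments and apply fades
#'
#' Stretches where the 10-ms frame RMS stays more than 40 dB below the
#' signal's peak frame RMS for longer than `max_silence` are shortened to
#' `max_silence`. The result is spliced into consecutive segments of
#' `seg_dur` seconds (any remainder shorter than a full segment is dropped),
#' each given a raised-cosine fade-in/out of `fade_dur`, with polarity
#' optionally alternating between consecutive segments.
#'
#' @param audio an [audio_stimulus()].
#' @param seg_dur segment duration in s.
#' @param fade_dur cosine fade duration in s.
#' @param max_silence maximum retained silence in s.
#' @param alternate_polarity flip the sign of every second segment.
#' @return List of [audio_stimulus()] segments with `segment_index` set.
#' @export
segment_and_fade <- function(audio, seg_dur = 10, fade_dur = 0.03,
                             max_silence = 0.5, alternate_polarity = TRUE) {
  stopifnot(inherits(audio, "audio_stimulus"))
  sr <- audio$sample_rate
  x <- truncate_silences(audio$samples, sr, max_silence)
  nseg <- round(seg_dur * sr)
  if (length(x) < nseg) stop("audio shorter than one segment")
  n_out <- floor(length(x) / nseg)
  nf <- round(fade_dur * sr)
  fade <- 0.5 * (1 - cos(pi * (0:(nf - 1)) / nf))
  lapply(seq_len(n_out), function(k) {
    seg <- x[((k - 1) * nseg + 1):(k * nseg)]
    seg[seq_len(nf)] <- seg[seq_len(nf)] * fade
    seg[(nseg - nf + 1):nseg] <- seg[(nseg - nf + 1):nseg] * rev(fade)
    if (alternate_polarity && k %% 2 == 0) seg <- -seg
    audio_stimulus(seg, sr, condition = audio$condition,
                   segment_index = k, kind = audio$kind)
  })
}

# shorten runs of sub-threshold frames to max_silence seconds
truncate_silences <- function(x, sr, max_silence, frame = 0.01, floor_db = -40) {
  nf <- round(frame * sr)
  n_frames <- floor(length(x) / nf)
  if (n_frames < 2) return(x)
  rms <- sqrt(colMeans(matrix(x[seq_len(n_frames * nf)], nf)^2))
  thr <- max(rms) * 10^(floor_db / 20)
  silent <- rms < thr
  r <- rle(silent)
  keep <- rep(TRUE, length(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  max_frames <- round(max_silence / frame)
  for (k in which(r$values & r$lengths > max_frames)) {
    drop_from <- (starts[k] + max_frames - 1) * nf + 1
    drop_to <- ends[k] * nf
    keep[drop_from:drop_to] <- FALSE
  }
  x[keep]
}
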