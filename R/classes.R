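#' Pulse train of glottal pulses or clicks
#'
#' An ordered set of event times, the universal regressor object for
#' ABR derivation: glottal pulse times for speech, click times for click
#' trains. Each event carries a polarity (+1 condensation, -1 rarefaction);
#' counter-phased click epochs flip the sign of the whole train.
#'
#' @param times numeric vector of event times in seconds, strictly increasing.
#' @param duration total duration in seconds; all times must lie in
#'   `[0, duration)`.
#' @param polarity +1/-1, either one value for the whole train or one per event.
#' @param nominal_rate nominal event rate in Hz (mean f0 or click rate), or
#'   `NULL` to infer `length(times)/duration`.
#' @return A `pulse_train` object (list with `times`, `polarity`, `duration`,
#'   `nominal_rate`).
#' @export
pulse_train <- function(times, duration, polarity = 1, nominal_rate = NULL) {
  times <- as.numeric(times)
  if (any(is.na(times))) stop("pulse times must be finite")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("pulse times must be strictly increasing")
  }
  if (length(times) && (min(times) < 0 || max(times) >= duration)) {
    stop("pulse times must lie in [0, duration)")
  }
  if (!length(polarity) %in% c(1L, max(1L, length(times)))) {
    stop("polarity must be scalar or one value per event")
  }
  if (!all(polarity %in% c(-1, 1))) stop("polarity must be +1 or -1")
  polarity <- rep_len(as.numeric(polarity), length(times))
  if (is.null(nominal_rate)) {
    nominal_rate <- if (duration > 0) length(times) / duration else 0
  }
  structure(
    list(times = times, polarity = polarity, duration = as.numeric(duration),
         nominal_rate = as.numeric(nominal_rate)),
    class = "pulse_train"
  )
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> %d events over %.3f s (nominal rate %.1f Hz)\n",
              length(x$times), x$duration, x$nominal_rate))
  invisible(x)
}

#' Invert the polarity of a pulse train
#'
#' Returns the counter-phased twin: identical event times, negated polarity.
#'
#' @param train a [pulse_train()].
#' @return A `pulse_train` with the same times and negated polarity.
#' @export
invert_polarity <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  train$polarity <- -train$polarity
  train
}

#' Sampled audio stimulus
#'
#' @param samples numeric waveform.
#' @param sample_rate sampling rate in Hz (48000 for presented stimuli).
#' @param voiced_spans two-column matrix (start_s, end_s) of voiced intervals,
#'   non-overlapping and sorted; may have zero rows.
#' @param condition free-form label (talker, target f0 or click rate).
#' @param segment_index optional integer index after segmentation.
#' @param kind `"speech"` or `"click"`; selects the derivation method
#'   (deconvolution vs cross-correlation) downstream.
#' @return An `audio_stimulus` object.
#' @export
audio_stimulus <- function(samples, sample_rate, voiced_spans = NULL,
                           condition = NA_character_, segment_index = NA_integer_,
                           kind = c("speech", "click")) {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (is.null(voiced_spans)) voiced_spans <- matrix(numeric(0), ncol = 2)
  voiced_spans <- matrix(as.numeric(voiced_spans), ncol = 2)
  if (nrow(voiced_spans) > 1) {
    o <- order(voiced_spans[, 1])
    voiced_spans <- voiced_spans[o, , drop = FALSE]
    if (any(voiced_spans[-1, 1] < voiced_spans[-nrow(voiced_spans), 2])) {
      stop("voiced spans must be non-overlapping")
    }
  }
  if (nrow(voiced_spans) && any(voiced_spans[, 2] <= voiced_spans[, 1])) {
    stop("voiced spans must have positive length")
  }
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         voiced_spans = voiced_spans, condition = condition,
         segment_index = segment_index, kind = kind),
    class = "audio_stimulus"
  )
}

#' @export
print.audio_stimulus <- function(x, ...) {
  cat(sprintf(
    "<audio_stimulus> %.2f s @ %g Hz, %d voiced span(s), kind=%s, condition=%s\n",
    length(x$samples) / x$sample_rate, x$sample_rate, nrow(x$voiced_spans),
    x$kind, as.character(x$condition)))
  invisible(x)
}

#' Duration of an audio stimulus in seconds
#' @param audio an [audio_stimulus()].
#' @return Duration in seconds.
#' @export
audio_duration <- function(audio) length(audio$samples) / audio$sample_rate

#' Frame-wise fundamental-frequency contour
#'
#' f0 is 0 on unvoiced frames; `voiced_mask` is `f0 > 0` and `mean_f0` is
#' computed over voiced frames only.
#'
#' @param frame_times frame centre times in seconds.
#' @param f0 frame-wise f0 in Hz, 0 where unvoiced.
#' @return An `f0_contour` object with fields `frame_times`, `f0`,
#'   `voiced_mask`, `mean_f0`.
#' @export
f0_contour <- function(frame_times, f0) {
  frame_times <- as.numeric(frame_times)
  f0 <- as.numeric(f0)
  stopifnot(length(frame_times) == length(f0))
  if (any(f0 < 0)) stop("f0 must be >= 0 (0 marks unvoiced frames)")
  voiced <- f0 > 0
  structure(
    list(frame_times = frame_times, f0 = f0, voiced_mask = voiced,
         mean_f0 = if (any(voiced)) mean(f0[voiced]) else NA_real_),
    class = "f0_contour"
  )
}

#' @export
print.f0_contour <- function(x, ...) {
  cat(sprintf("<f0_contour> %d frames, %.0f%% voiced, mean f0 %.1f Hz\n",
              length(x$f0), 100 * mean(x$voiced_mask), x$mean_f0))
  invisible(x)
}

#' Multi-channel EEG recording
#'
#' @param samples channels x samples numeric matrix (amplitude in nV).
#' @param sample_rate sampling rate in Hz (10000 in this pipeline).
#' @param trial_onsets trial start times in seconds.
#' @param channel_names optional character vector.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(samples, sample_rate, trial_onsets = numeric(),
                          channel_names = NULL) {
  samples <- rbind(samples)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  stopifnot(length(channel_names) == nrow(samples))
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         trial_onsets = as.numeric(trial_onsets),
         channel_names = channel_names),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %.1f s @ %g Hz, %d trial onset(s)\n",
              nrow(x$samples), ncol(x$samples) / x$sample_rate, x$sample_rate,
              length(x$trial_onsets)))
  invisible(x)
}

#' One epoched trial with its regressor pulse train
#'
#' The EEG is cut around one stimulus trial including `pad` seconds before
#' and after (12 s total for the standard 10-s trials), and the pulse train
#' is rendered as a sampled regressor of the same length: signed unit
#' impulses at pulse sample positions, zero in the pads.
#'
#' @param eeg channels x samples matrix.
#' @param regressor numeric vector, same number of samples as `eeg`.
#' @param sample_rate Hz.
#' @param pad pad length in seconds on each side.
#' @param condition condition label.
#' @param index trial index within its condition.
#' @return A `trial_epoch` object.
#' @export
trial_epoch <- function(eeg, regressor, sample_rate, pad = 1,
                        condition = NA_character_, index = NA_integer_) {
  eeg <- rbind(eeg)
  if (ncol(eeg) != length(regressor)) {
    stop("eeg and regressor must have the same number of samples")
  }
  npad <- round(pad * sample_rate)
  if (npad > 0) {
    head_r <- regressor[seq_len(npad)]
    tail_r <- regressor[seq.int(length(regressor) - npad + 1, length(regressor))]
    if (any(head_r != 0) || any(tail_r != 0)) {
      stop("regressor must be zero inside the pads")
    }
  }
  structure(
    list(eeg = eeg, regressor = as.numeric(regressor),
         sample_rate = as.numeric(sample_rate), pad = pad,
         condition = condition, index = index),
    class = "trial_epoch"
  )
}

#' Derived response waveform (ABR kernel)
#'
#' Amplitude as a function of lag relative to the pulses, in nV, on a
#' uniform lag axis (0.1 ms steps at the 10 kHz EEG rate).
#'
#' @param lags_ms lag axis in ms, uniform spacing.
#' @param amplitude_nv amplitude in nV, same length as `lags_ms`.
#' @param n_trials number of trials combined.
#' @param weights_used `TRUE` if inverse-variance weighting was applied.
#' @param channels_averaged `TRUE` if channels were averaged.
#' @return A `response_waveform` object.
#' @export
response_waveform <- function(lags_ms, amplitude_nv, n_trials = 1L,
                              weights_used = FALSE, channels_averaged = FALSE) {
  lags_ms <- as.numeric(lags_ms)
  amplitude_nv <- as.numeric(amplitude_nv)
  stopifnot(length(lags_ms) == length(amplitude_nv))
  if (any(!is.finite(amplitude_nv))) stop("amplitude must be finite")
  if (length(lags_ms) > 2) {
    d <- diff(lags_ms)
    if (max(abs(d - d[1])) > 1e-9) stop("lag axis must be uniform")
  }
  structure(
    list(lags_ms = lags_ms, amplitude_nv = amplitude_nv,
         n_trials = as.integer(n_trials), weights_used = weights_used,
         channels_averaged = channels_averaged),
    class = "response_waveform"
  )
}

#' @export
print.response_waveform <- function(x, ...) {
  cat(sprintf(
    "<response_waveform> lags %.1f..%.1f ms (%d samples), peak %.1f nV, %d trial(s)%s\n",
    min(x$lags_ms), max(x$lags_ms), length(x$lags_ms), max(x$amplitude_nv),
    x$n_trials, if (x$weights_used) ", inverse-variance weighted" else ""))
  invisible(x)
}

# interpolate a response onto a given lag axis (linear, 0 outside support)
resample_response <- function(resp, lags_ms) {
  amp <- stats::approx(resp$lags_ms, resp$amplitude_nv, xout = lags_ms,
                       yleft = 0, yright = 0)$y
  response_waveform(lags_ms, amp, n_trials = resp$n_trials,
                    weights_used = resp$weights_used,
                    channels_averaged = resp$channels_averaged)
}
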