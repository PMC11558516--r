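#' Characteristic-frequency grid for the periphery model
#'
#' Log-spaced characteristic frequencies from 125 Hz to 16 kHz (42 CFs,
#' close to 1/6-octave spacing), high-spontaneous-rate fiber class.
#'
#' @param n number of CFs.
#' @param f_lo,f_hi endpoint CFs in Hz (inclusive).
#' @return A `cf_grid` object with fields `cf` (Hz) and `fiber_class`.
#' @export
cf_grid <- function(n = 42, f_lo = 125, f_hi = 16000) {
  if (n < 2 || f_lo <= 0 || f_hi <= f_lo) stop("invalid CF grid")
  structure(list(cf = 2^seq(log2(f_lo), log2(f_hi), length.out = n),
                 fiber_class = "high_spont"),
            class = "cf_grid")
}

# equivalent rectangular bandwidth (Glasberg & Moore) in Hz
erb_hz <- function(cf) 24.7 * (4.37 * cf / 1000 + 1)

# gammatone FIR (4th order) at the audio rate, truncated where the envelope
# has decayed to 1e-5 of its maximum
gammatone_fir <- function(cf, sample_rate) {
  b <- 1.019 * erb_hz(cf)
  t_peak <- 3 / (2 * pi * b)
  t_max <- t_peak + 12 / (2 * pi * b)
  t <- seq(0, t_max, by = 1 / sample_rate)
  g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  # unit gain at CF: a tone at CF passes at unity in every channel
  g / Mod(sum(g * exp(-2i * pi * cf * t)))
}

#' Simulate auditory-nerve population firing rates
#'
#' Bundled `simple` periphery backend: per characteristic frequency, a
#' 4th-order gammatone band-pass, broken-stick compression (linear below a
#' knee, power-law above), inner-hair-cell style half-wave rectification and
#' low-pass, three-stage exponential adaptation (2, 60, 300 ms), and a
#' high-spontaneous-rate floor. The stimulus is calibrated so that full
#' scale corresponds to the stated peak-equivalent SPL. An `external`
#' backend hook accepts a user function with the same output contract
#' (CF x time matrix of rates at the EEG rate).
#'
#' @param stimulus an [audio_stimulus()] (full scale = `level_db_spl` peSPL).
#' @param grid a [cf_grid()].
#' @param level_db_spl presentation level, dB peSPL.
#' @param backend `"simple"` or a function `(pressure, sample_rate, grid)`
#'   returning a CF x time rate matrix at `eeg_rate`.
#' @param eeg_rate output sample rate, Hz.
#' @param spont spontaneous rate, spikes/s.
#' @param ihc_lp inner-hair-cell membrane low-pass cutoff, Hz (phase-locking
#'   limit of the far-field generators).
#' @return An `an_population` object: list with `rates` (CF x time matrix,
#'   spikes/s), `cf`, `sample_rate`, `spont`.
#' @export
periphery <- function(stimulus, grid = cf_grid(), level_db_spl = 65,
                      backend = "simple", eeg_rate = 10000, spont = 60,
                      ihc_lp = 700) {
  stopifnot(inherits(stimulus, "audio_stimulus"))
  # digital full scale (+-1) maps to the peak pressure of an equally-peaked
  # sinusoid at level_db_spl (peSPL); stimuli are synthesized at full scale
  p_peak <- sqrt(2) * 20e-6 * 10^(level_db_spl / 20)
  x <- stimulus$samples * p_peak
  sr <- stimulus$sample_rate
  if (is.function(backend)) {
    rates <- backend(x, sr, grid)
  } else {
    rates <- periphery_simple(x, sr, grid, eeg_rate, spont, ihc_lp)
  }
  structure(list(rates = rates, cf = grid$cf, sample_rate = eeg_rate,
                 spont = spont),
            class = "an_population")
}

periphery_simple <- function(x, sr, grid, eeg_rate, spont, ihc_lp = 700) {
  n_out <- floor(length(x) / sr * eeg_rate)
  t_out <- (seq_len(n_out) - 1) / eeg_rate
  t_in <- (seq_along(x) - 1) / sr
  # middle-ear band-pass: attenuates low-frequency energy before the cochlea
  me <- signal::butter(1, c(350, 6000) / (sr / 2), type = "pass")
  x <- as.numeric(signal::filter(me, x))
  knee <- 1e-3                 # Pa, ~31 dB SPL compression knee
  # IHC membrane low-pass: loss of phase locking to fine structure
  lp <- signal::butter(2, min(0.9, ihc_lp / (sr / 2)), type = "low")
  # anti-alias low-pass before decimation to the EEG rate
  aa <- signal::butter(6, min(0.9, 0.8 * eeg_rate / 2 / (sr / 2)), type = "low")
  taus <- c(0.002, 0.060, 0.300)
  wts <- c(0.5, 0.25, 0.15)
  r_sat <- 1200                # instantaneous saturation rate, spikes/s
  d50 <- 4e-4                  # IHC drive at half saturation
  rates <- matrix(0, length(grid$cf), n_out)
  Xf <- NULL
  for (k in seq_along(grid$cf)) {
    fir <- gammatone_fir(grid$cf[k], sr)
    nconv <- length(x) + length(fir) - 1L
    nf <- stats::nextn(nconv, 2)
    if (is.null(Xf) || length(Xf) != nf) {
      Xf <- stats::fft(c(x, numeric(nf - length(x))))
    }
    bm <- Re(stats::fft(Xf * stats::fft(c(fir, numeric(nf - length(fir)))),
                        inverse = TRUE)) / nf
    bm <- bm[seq_along(x)]
    # broken-stick compression
    big <- abs(bm) > knee
    bm[big] <- sign(bm[big]) * knee * (abs(bm[big]) / knee)^0.4
    # IHC: half-wave rectification + low-pass
    ihc <- pmax(bm, 0)
    ihc <- as.numeric(signal::filter(lp, ihc))
    # saturating synapse: instantaneous rate capped at r_sat
    syn <- r_sat * ihc / (ihc + d50)
    # three-stage exponential adaptation (subtractive, first-order IIR states)
    drive <- syn
    for (s in seq_along(taus)) {
      alpha <- 1 / (taus[s] * sr)
      state <- as.numeric(stats::filter(alpha * syn, 1 - alpha,
                                        method = "recursive"))
      drive <- drive - wts[s] * state
    }
    # anti-alias the driven component only (the constant floor has no
    # start-up transient to smooth)
    r <- spont + as.numeric(signal::filter(aa, pmax(drive, 0)))
    rates[k, ] <- stats::approx(t_in, r, xout = t_out, rule = 2)$y
  }
  rates
}

#' Per-wave scale and latency-shift parameters for EEG synthesis
#'
#' @param scales named numeric (`I`, `III`, `V`), nV per unit summed
#'   population rate; must be >= 0.
#' @param latency_shifts_ms named numeric (`I`, `III`, `V`) in `[0, 10]` ms,
#'   strictly increasing from I to V (constant brainstem conduction delays).
#' @return A `wave_params` object.
#' @export
wave_params <- function(scales = c(I = 0.03, III = 0.05, V = 0.12),
                        latency_shifts_ms = c(I = 1, III = 3, V = 5)) {
  lab <- c("I", "III", "V")
  stopifnot(all(lab %in% names(scales)), all(lab %in% names(latency_shifts_ms)))
  scales <- scales[lab]; latency_shifts_ms <- latency_shifts_ms[lab]
  if (any(scales < 0)) stop("scales must be >= 0")
  if (any(latency_shifts_ms < 0) || any(latency_shifts_ms > 10)) {
    stop("latency shifts must lie in [0, 10] ms")
  }
  if (any(diff(latency_shifts_ms) <= 0)) {
    stop("latency shifts must increase I -> III -> V")
  }
  structure(list(scales = scales, latency_shifts_ms = latency_shifts_ms),
            class = "wave_params")
}

#' Synthesize EEG from an auditory-nerve population response
#'
#' The driven population rate (summed over CFs, spontaneous rate removed)
#' generates each wave as a scaled, latency-shifted copy; the simulated EEG
#' is their sum, mirroring a constant-delay brainstem conduction model.
#'
#' @param an an `an_population` from [periphery()].
#' @param params a [wave_params()].
#' @return An [eeg_recording()] (one channel, nV).
#' @export
synthesize_eeg <- function(an, params) {
  stopifnot(inherits(an, "an_population"), inherits(params, "wave_params"))
  pop <- population_rate(an)
  n <- length(pop)
  eeg <- numeric(n)
  for (wv in c("I", "III", "V")) {
    sh <- round(params$latency_shifts_ms[[wv]] / 1000 * an$sample_rate)
    shifted <- c(numeric(sh), pop)[seq_len(n)]
    eeg <- eeg + params$scales[[wv]] * shifted
  }
  eeg_recording(matrix(eeg, 1), an$sample_rate)
}

# driven population rate summed over CFs with far-field weighting: channels
# contribute in proportion to the number of synchronously driven fibers,
# which grows with filter bandwidth (basal dominance); weights normalized to
# mean 1 over the grid
population_rate <- function(an) {
  w <- sqrt(erb_hz(an$cf))
  w <- w / mean(w)
  as.numeric(t(w) %*% (an$rates - an$spont))
}

#' Derive a modeled ABR for one stimulus
#'
#' Runs the periphery, synthesizes wave I/III/V EEG, and passes it through
#' the same derivation as measured EEG (cross-correlation for clicks,
#' deconvolution for speech) using the stimulus's own pulse train as the
#' regressor.
#'
#' @param stimulus an [audio_stimulus()] (`kind` selects the method).
#' @param pulses the stimulus's [pulse_train()].
#' @param params a [wave_params()].
#' @param grid a [cf_grid()].
#' @param level_db_spl presentation level, dB peSPL.
#' @param backend periphery backend (see [periphery()]).
#' @param pad epoch pad in s.
#' @param lag_range lags to retain, ms.
#' @return A [response_waveform()].
#' @export
model_abr <- function(stimulus, pulses, params = wave_params(),
                      grid = cf_grid(), level_db_spl = 65, backend = "simple",
                      pad = 0.5, lag_range = c(-20, 60)) {
  an <- periphery(stimulus, grid, level_db_spl, backend)
  sim <- synthesize_eeg(an, params)
  derive_model_response(sim, pulses, kind = stimulus$kind, pad = pad,
                        lag_range = lag_range)
}

# epoch a single-trial simulated EEG with its pulse train and derive;
# the simulated EEG passes the same 150-2000 Hz front end as measured EEG,
# removing the slow voicing-locked rate pedestal from speech responses
derive_model_response <- function(sim, pulses, kind = c("speech", "click"),
                                  pad = 0.5, lag_range = c(-20, 60)) {
  kind <- match.arg(kind)
  sim <- bandpass_abr(sim)
  sr <- sim$sample_rate
  npad <- round(pad * sr)
  ntrial <- min(ncol(sim$samples), round(pulses$duration * sr))
  eeg <- cbind(matrix(0, nrow(sim$samples), npad),
               sim$samples[, seq_len(ntrial), drop = FALSE],
               matrix(0, nrow(sim$samples), npad))
  reg <- numeric(ncol(eeg))
  ix <- npad + round(pulses$times * sr) + 1L
  ok <- ix > npad & ix <= npad + ntrial
  reg[ix[ok]] <- 1
  ep <- trial_epoch(eeg, reg, sr, pad = pad)
  derive_response(list(ep), method = if (kind == "click") "xcorr" else "deconv",
                  weights = "uniform", lag_range = lag_range)
}

#' Calibrate wave scales and latency shifts against a reference ABR
#'
#' Sequential grid search, one wave at a time in order I, III, V: for each
#' wave, every (scale, latency-shift) grid point is evaluated by the RMS
#' error between the modeled and reference waveforms over 0-10 ms lags,
#' holding already-fitted waves fixed and not-yet-fitted waves at zero scale.
#' The modeled waveform is linear in each wave's contribution, so per-wave
#' unit-scale responses are precomputed once per candidate latency.
#'
#' @param an_ref `an_population` for the reference stimulus (lowest-rate
#'   clicks).
#' @param ref_pulses the reference stimulus's [pulse_train()].
#' @param reference_abr the reference (grand-average) click
#'   [response_waveform()].
#' @param scale_grids named list (`I`, `III`, `V`) of candidate scales.
#' @param latency_grids named list of candidate latency shifts, ms.
#' @param fit_window lag window for the objective, ms.
#' @return A [wave_params()] at the best grid point.
#' @export
calibrate_waves <- function(an_ref, ref_pulses, reference_abr,
                            scale_grids = default_scale_grids(),
                            latency_grids = default_latency_grids(),
                            fit_window = c(0, 10)) {
  lab <- c("I", "III", "V")
  if (any(vapply(scale_grids[lab], length, 1L) == 0) ||
      any(vapply(latency_grids[lab], length, 1L) == 0)) {
    stop("empty calibration grid")
  }
  kind <- "click"
  sr <- an_ref$sample_rate
  pop <- population_rate(an_ref)
  ref <- resample_response(reference_abr,
                           seq(fit_window[1], fit_window[2], by = 1000 / sr))
  # unit-scale derived response for each wave latency candidate
  unit_resp <- function(shift_ms) {
    n <- length(pop)
    sh <- round(shift_ms / 1000 * sr)
    eeg <- eeg_recording(matrix(c(numeric(sh), pop)[seq_len(n)], 1), sr)
    r <- derive_model_response(eeg, ref_pulses, kind = kind)
    resample_response(r, ref$lags_ms)$amplitude_nv
  }
  lat_all <- sort(unique(unlist(latency_grids[lab])))
  units <- lapply(lat_all, unit_resp)
  names(units) <- as.character(lat_all)
  best <- list(scales = c(I = 0, III = 0, V = 0),
               latency_shifts_ms = c(I = 0, III = 0, V = 0))
  contrib <- function(w) {
    if (best$scales[w] == 0) return(0)
    best$scales[w] * units[[as.character(best$latency_shifts_ms[w])]]
  }
  # one wave at a time, dominant wave V first, with a second refinement
  # sweep: the unit responses overlap strongly, so each wave is refit with
  # the others held at their current estimates (coordinate descent)
  for (sweep in 1:2) {
    for (w in c("V", "III", "I")) {
      others <- Reduce(`+`, lapply(setdiff(lab, w), contrib), numeric(length(ref$amplitude_nv)))
      err_best <- Inf
      for (l in latency_grids[[w]]) {
        u <- units[[as.character(l)]]
        for (s in scale_grids[[w]]) {
          e <- sqrt(mean((ref$amplitude_nv - others - s * u)^2))
          if (e < err_best) {
            err_best <- e
            best$scales[w] <- s
            best$latency_shifts_ms[w] <- l
          }
        }
      }
    }
  }
  # enforce strictly increasing latencies for the wave_params invariant
  eps <- 1000 / sr / 2
  for (i in 2:3) {
    if (best$latency_shifts_ms[i] <= best$latency_shifts_ms[i - 1]) {
      best$latency_shifts_ms[i] <- best$latency_shifts_ms[i - 1] + 2 * eps
    }
  }
  wave_params(best$scales, best$latency_shifts_ms)
}

#' @rdname calibrate_waves
#' @export
default_scale_grids <- function() {
  list(I = seq(0, 0.06, by = 0.01),
       III = seq(0, 0.1, by = 0.01),
       V = seq(0.02, 0.3, by = 0.02))
}

#' @rdname calibrate_waves
#' @export
default_latency_grids <- function() {
  list(I = seq(0.5, 2, by = 0.3),
       III = seq(2.3, 4.1, by = 0.3),
       V = seq(4.4, 7.4, by = 0.3))
}
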