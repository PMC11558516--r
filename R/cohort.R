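#' Glottal-pulse-like train at a given mean rate
#'
#' Speech-like regressor timing: inter-pulse intervals concentrated near
#' `1/rate`, in contrast to the exponential ISIs of Poisson clicks. The
#' local rate follows a slow AR(1) prosodic drift (as pitch does across a
#' narrated phrase), with a small cycle-to-cycle jitter and occasional
#' unvoiced gaps; the drift sweeps the harmonic structure of the regressor,
#' giving it the dense spectrum natural narration has. Uses the current RNG
#' state; seed at the caller.
#'
#' @param rate mean pulse rate (f0) in Hz.
#' @param duration s.
#' @param jitter cycle-to-cycle log-ISI jitter SD (fractional).
#' @param drift_sd SD of the slow log-rate prosodic drift (fractional).
#' @param drift_ar AR(1) coefficient of the drift, per glottal cycle.
#' @param gap_prob probability that a pulse starts an unvoiced gap.
#' @param gap_dur gap duration in s.
#' @return A [pulse_train()].
#' @export
glottal_like_train <- function(rate, duration, jitter = 0.03,
                               drift_sd = 0.12, drift_ar = 0.985,
                               gap_prob = 0.01, gap_dur = 0.1) {
  n_max <- ceiling(duration * rate * 1.5) + 20L
  innov <- stats::rnorm(n_max, 0, drift_sd * sqrt(1 - drift_ar^2))
  innov[1] <- stats::rnorm(1, 0, drift_sd)
  drift <- as.numeric(stats::filter(innov, drift_ar, method = "recursive"))
  isi <- exp(stats::rnorm(n_max, log(1 / rate) - drift, jitter)) +
    gap_dur * (stats::runif(n_max) < gap_prob)
  times <- stats::runif(1, 0, 1 / rate) + cumsum(isi)
  times <- c(times[1] - isi[1], times)
  times <- times[times < duration]
  pulse_train(times, duration = duration, nominal_rate = rate)
}

#' Scale the noise specification to a reduced amount of data
#'
#' Desk-scale simulations use fewer/shorter trials than the 20-min
#' (120 x 10 s) recording conditions; to keep the derived-waveform
#' signal-to-noise ratio representative, noise RMS is divided by the square
#' root of the data-length reduction.
#'
#' @param n_trials trials per condition in the simulation.
#' @param trial_dur trial duration in s.
#' @param base the full-scale [noise_spec()].
#' @param full_trials,full_dur the reference recording condition.
#' @return A [noise_spec()] with scaled RMS values.
#' @export
scaled_noise_spec <- function(n_trials, trial_dur, base = noise_spec(),
                              full_trials = 120, full_dur = 10) {
  k <- sqrt((full_trials * full_dur) / (n_trials * trial_dur))
  noise_spec(pink_noise_rms = base$pink_noise_rms / k,
             line_freq = base$line_freq,
             line_harmonic_rms = base$line_harmonic_rms / k,
             per_trial_variance_spread = base$per_trial_variance_spread)
}

#' Simulate one subject's epochs for a two-condition comparison
#'
#' Generates glottal-like pulse trains at the two condition rates, simulates
#' EEG from the kernel (with optional rate adaptation), applies the band-pass
#' and notch front end, and epochs the result. Conditions are interleaved
#' trial by trial, as in a randomized presentation.
#'
#' @param kernel ground-truth [response_waveform()].
#' @param rates length-2 condition rates in Hz (equal rates give a
#'   no-effect null subject).
#' @param n_trials trials per condition.
#' @param trial_dur s.
#' @param noise a [noise_spec()] (already desk-scaled).
#' @param adaptation an [adaptation_spec()] or `NULL`.
#' @param seed integer seed.
#' @param n_channels EEG channels.
#' @param pad epoch pad, s.
#' @param front_end `"full"` (band-pass + notch comb) or `"bandpass"`
#'   (band-pass only; appropriate when the noise model carries no line
#'   harmonics).
#' @return List with `epochs` and `conditions` (labels `"a"`, `"b"`).
#' @export
simulate_subject_epochs <- function(kernel, rates, n_trials = 8,
                                    trial_dur = 1, noise, adaptation = NULL,
                                    seed = 1, n_channels = 2, pad = 0.5,
                                    front_end = c("full", "bandpass")) {
  front_end <- match.arg(front_end)
  seed <- seed %% 2147483647
  set.seed(seed)
  cond <- rep(c("a", "b"), n_trials)
  trains <- lapply(cond, function(cc) {
    glottal_like_train(if (cc == "a") rates[1] else rates[2], trial_dur)
  })
  rec <- simulate_subject_eeg(kernel, trains, noise = noise,
                              adaptation = adaptation,
                              n_channels = n_channels,
                              seed = seed + 1000003L, edge_pad = pad + 0.1)
  rec <- bandpass_abr(rec)
  if (front_end == "full") rec <- notch_comb(rec)
  list(epochs = make_epochs(rec, trains, pad = pad), conditions = cond)
}

#' Run the correlation comparison procedure on a simulated cohort
#'
#' For each of `n_subjects`, simulates a two-condition subject, computes the
#' cross-condition and split-half-null correlations over the window, then
#' applies the Wilcoxon signed-rank test to the paired differences.
#'
#' @param n_subjects cohort size.
#' @param rates length-2 condition rates (equal = null cohort).
#' @param kernel ground-truth kernel (default [make_kernel()] of the
#'   canonical spec).
#' @param adaptation an [adaptation_spec()] or `NULL`.
#' @param n_trials,trial_dur per-condition trial layout.
#' @param noise a [noise_spec()]; default is the full-scale spec scaled to
#'   this trial layout.
#' @param seed integer seed.
#' @param window correlation window, ms.
#' @param n_channels,pad recording layout of the simulated subjects.
#' @param reg_epsilon deconvolution regularization passed through to the
#'   pooled estimator.
#' @return Output of [compare_correlations()].
#' @export
cohort_correlation_test <- function(n_subjects = 15, rates = c(123, 183),
                                    kernel = make_kernel(kernel_spec()),
                                    adaptation = adaptation_spec(),
                                    n_trials = 6, trial_dur = 0.5,
                                    noise = scaled_noise_spec(
                                      n_trials, trial_dur,
                                      base = noise_spec(line_harmonic_rms = 0)),
                                    seed = 1, window = c(2, 12),
                                    n_channels = 1, pad = 0.3,
                                    reg_epsilon = 1e-3) {
  fits <- lapply(seq_len(n_subjects), function(s) {
    sub <- simulate_subject_epochs(kernel, rates, n_trials = n_trials,
                                   trial_dur = trial_dur, noise = noise,
                                   adaptation = adaptation,
                                   seed = (seed * 10007) %% 2147483647 + s,
                                   n_channels = n_channels, pad = pad,
                                   front_end = "bandpass")
    fit_subject_correlations(sub$epochs, sub$conditions, window = window,
                             reg_epsilon = reg_epsilon)
  })
  compare_correlations(fits)
}

#' Simulate a talker cohort and measure wave V per condition
#'
#' Each subject hears a "male" (123 Hz) and a "female" (183 Hz) condition;
#' rate adaptation embeds the amplitude/latency rate effects. Per subject
#' and condition the response is derived and wave V is measured, giving the
#' tidy table consumed by [summarize_conditions()]. The default noise level
#' corresponds to a 2-h-equivalent recording per condition so that
#' peak-picking noise bias does not confound recovery of the embedded
#' amplitude ratio.
#'
#' @param n_subjects cohort size.
#' @param rates named vector `c(male = , female = )` in Hz.
#' @param kernel ground-truth kernel.
#' @param adaptation an [adaptation_spec()].
#' @param n_trials,trial_dur per-condition trial layout.
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @return Tibble with `participant`, `talker`, `rate_f0`, `amplitude_nv`,
#'   `latency_ms`, `found`.
#' @export
simulate_talker_measures <- function(n_subjects = 15,
                                     rates = c(male = 123, female = 183),
                                     kernel = make_kernel(kernel_spec()),
                                     adaptation = adaptation_spec(),
                                     n_trials = 8, trial_dur = 1,
                                     noise = scaled_noise_spec(
                                       n_trials, trial_dur,
                                       full_trials = 720),
                                     seed = 1) {
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sub <- simulate_subject_epochs(kernel, unname(rates), n_trials = n_trials,
                                   trial_dur = trial_dur, noise = noise,
                                   adaptation = adaptation,
                                   seed = (seed * 20011) %% 2147483647 + s)
    for (ci in 1:2) {
      ix <- which(sub$conditions == c("a", "b")[ci])
      resp <- derive_response(sub$epochs[ix], method = "deconv",
                              weights = "inverse_variance")
      wv <- pick_wave_v(resp)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant = s, talker = names(rates)[ci],
        rate_f0 = unname(rates[ci]),
        amplitude_nv = wv$p2t_amplitude_nv,
        latency_ms = wv$peak_latency_ms, found = wv$found)
    }
  }
  dplyr::bind_rows(rows)
}
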