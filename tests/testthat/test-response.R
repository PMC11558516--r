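test_that("band-pass is causal with the stated corner behavior", {
  sr <- 10000
  # DC is rejected
  dc <- bandpass_abr(rep(1, 5000), sample_rate = sr)
  expect_lt(abs(mean(dc[2000:5000])), 1e-3)

  # 600 Hz tone gain matches the designed filter's frequency response
  t <- (0:9999) / sr
  tone <- sin(2 * pi * 600 * t)
  y <- bandpass_abr(tone, sample_rate = sr)
  gain <- stats::sd(y[5000:10000]) / stats::sd(tone[5000:10000])
  f <- signal::butter(1, c(150, 2000) / (sr / 2), type = "pass")
  w <- 2 * pi * 600 / sr
  h <- Mod(sum(f$b * exp(-1i * w * (seq_along(f$b) - 1))) /
             sum(f$a * exp(-1i * w * (seq_along(f$a) - 1))))
  expect_lt(abs(20 * log10(gain) - 20 * log10(h)), 1)

  # causal: impulse response is zero before the impulse
  imp <- numeric(1000); imp[500] <- 1
  yi <- bandpass_abr(imp, sample_rate = sr)
  expect_true(all(abs(yi[1:499]) == 0))

  expect_error(bandpass_abr(tone, high = 6000, sample_rate = sr), "Nyquist")
})

test_that("notch comb removes odd line harmonics and little else", {
  sr <- 10000
  t <- (0:19999) / sr
  y180 <- notch_comb(sin(2 * pi * 180 * t), sample_rate = sr)
  expect_lte(stats::sd(y180[10000:20000]), 0.1 * stats::sd(sin(2 * pi * 180 * t)))

  y120 <- notch_comb(sin(2 * pi * 120 * t), sample_rate = sr)
  att <- -20 * log10(stats::sd(y120[10000:20000]) / sqrt(0.5))
  expect_lt(att, 1)

  # broadband power loss agrees with the integral of the magnitude response
  set.seed(11)
  wn <- rnorm(2^16)
  yw <- notch_comb(wn, sample_rate = sr)
  loss <- 1 - sum(yw[5000:2^16]^2) / sum(wn[5000:2^16]^2)
  imp <- c(1, numeric(2^14 - 1))
  H2 <- Mod(stats::fft(notch_comb(imp, sample_rate = sr)))^2
  loss_int <- 1 - mean(H2)
  expect_lt(abs(loss - loss_int), 0.02)
  expect_lt(loss, 0.10)
  # <1 dB ripple 20 Hz away from each notch
  t2 <- (0:19999) / sr
  y80 <- notch_comb(sin(2 * pi * 80 * t2), sample_rate = sr)
  expect_lt(abs(20 * log10(stats::sd(y80[10000:20000]) / sqrt(0.5))), 1)

  # combined front end is the same cascade in one pass
  expect_equal(abr_front_end(wn, sample_rate = sr),
               notch_comb(bandpass_abr(wn, sample_rate = sr), sample_rate = sr),
               tolerance = 1e-12)
})

test_that("frequency-domain cross-correlation matches the time-domain oracle", {
  set.seed(12)
  sr <- 10000
  for (i in 1:20) {
    n <- sample(2000:8000, 1)
    npad <- 500
    eeg <- matrix(rnorm(n), 1)
    reg <- numeric(n)
    ix <- sample((npad + 1):(n - npad), 20)
    reg[ix] <- 1
    ep <- trial_epoch(eeg, reg, sr, pad = npad / sr)
    resp <- derive_response(list(ep), method = "xcorr", weights = "uniform",
                            lag_range = c(-2, 6))
    lags <- round(resp$lags_ms / 1000 * sr)
    oracle <- xcorr_oracle(eeg[1, ], reg, lags, norm = 20)
    expect_lt(max(abs(resp$amplitude_nv - oracle)) /
                max(abs(oracle)), 1e-9)
  }
})

test_that("derivation recovers kernels and handles degenerate regressors", {
  k <- canonical_kernel()
  set.seed(13)
  tr <- list(glottal_like_train(123, 1))
  ep <- noiseless_epochs(k, tr)
  for (comb in c("pooled", "per_trial")) {
    resp <- derive_response(ep, method = "deconv", weights = "uniform",
                            reg_epsilon = 0, lag_range = c(0, 16),
                            combine = comb)
    expect_lt(max(abs(resp$amplitude_nv - kernel_on(k, resp$lags_ms))),
              1e-6 * max(k$amplitude_nv))
  }

  # a single unit pulse re-aligns the EEG to the pulse time
  sr <- 10000
  set.seed(14)
  eeg <- matrix(rnorm(5000), 1)
  reg <- numeric(5000); reg[2000] <- 1
  ep1 <- trial_epoch(eeg, reg, sr, pad = 0.05)
  r1 <- derive_response(list(ep1), method = "xcorr", weights = "uniform",
                        lag_range = c(0, 10))
  idx <- 2000 + round(r1$lags_ms / 1000 * sr)
  expect_equal(r1$amplitude_nv, eeg[1, idx], tolerance = 1e-9)

  ep_bad <- trial_epoch(eeg, numeric(5000), sr, pad = 0.05)
  expect_error(derive_response(list(ep_bad)), "zero")
})

test_that("inverse-variance weighting follows the normalized 1/var scheme", {
  w <- inverse_variance_weights(c(1, 4))
  expect_equal(w, c(0.8, 0.2))
  expect_equal(sum(inverse_variance_weights(c(0.3, 1.7, 9))), 1)

  # zero variance clamped, not infinite
  wz <- inverse_variance_weights(c(0, 1, 2, 3, 4))
  expect_true(all(is.finite(wz)) && abs(sum(wz) - 1) < 1e-12)

  k <- canonical_kernel()
  base <- response_waveform(k$lags_ms, k$amplitude_nv)
  other <- response_waveform(k$lags_ms, 2 * k$amplitude_nv)
  eq <- weighted_average(list(base, other), c(3, 3))
  expect_equal(eq$amplitude_nv, 1.5 * k$amplitude_nv)
  single <- weighted_average(list(base), 5)
  expect_equal(single$amplitude_nv, base$amplitude_nv)
})

test_that("delay correction shifts the lag axis and is invertible", {
  k <- canonical_kernel()
  r <- response_waveform(k$lags_ms + 0.9, k$amplitude_nv)
  rc <- correct_delay(r, 0.9)
  expect_equal(rc$lags_ms[which.max(rc$amplitude_nv)], 6.9, tolerance = 0.06)
  expect_identical(correct_delay(r, 0), r)
  expect_equal(correct_delay(correct_delay(r, 0.9), -0.9), r)
})

test_that("inverse-variance weighting beats uniform averaging under heteroscedasticity", {
  k <- canonical_kernel()
  set.seed(15)
  wins <- logical(25)
  for (i in seq_along(wins)) {
    trains <- lapply(1:16, function(j) glottal_like_train(123, 0.5))
    ns <- scaled_noise_spec(16, 0.5, base = noise_spec(line_harmonic_rms = 0))
    rec <- simulate_subject_eeg(k, trains, noise = ns, n_channels = 1,
                                seed = 5000 + i, edge_pad = 0.4)
    rec0 <- simulate_subject_eeg(k, trains,
                                 noise = noise_spec(0, 60, 0, c(1, 1)),
                                 n_channels = 1, seed = 5000 + i,
                                 edge_pad = 0.4)
    ep <- make_epochs(bandpass_abr(rec), trains, pad = 0.3)
    ep0 <- make_epochs(bandpass_abr(rec0), trains, pad = 0.3)
    # residual relative to the noise-free output of the same pipeline:
    # weighting addresses noise, so noise is what is measured
    ref <- derive_response(ep0, method = "xcorr", weights = "uniform")
    err <- function(wt) {
      r <- derive_response(ep, method = "xcorr", weights = wt)
      sqrt(mean((r$amplitude_nv - ref$amplitude_nv)^2))
    }
    wins[i] <- err("inverse_variance") <= err("uniform")
  }
  expect_gte(mean(wins), 0.85)
})

test_that("counter-phased pairs cancel polarity-locked stimulus artifacts", {
  sr <- 10000
  set.seed(16)
  art <- 50 * exp(-(0:49) / 10) * sin(2 * pi * 900 * (0:49) / sr)
  eps <- make_poisson_clicks(123, 1, 2, seed = 17)
  make_ep <- function(train) {
    n <- round(1.6 * sr)
    reg_signed <- numeric(n)
    ix <- round(0.3 * sr) + round(train$times * sr) + 1
    reg_signed[ix] <- train$polarity
    eeg <- matrix(peakyabr:::fft_convolve(reg_signed, art)[1:n], 1)
    reg <- numeric(n); reg[ix] <- 1
    trial_epoch(eeg, reg, sr, pad = 0.3)
  }
  pair <- list(make_ep(eps[[1]]$plus), make_ep(eps[[1]]$minus))
  both <- derive_response(pair, method = "xcorr", weights = "uniform")
  single <- derive_response(pair[1], method = "xcorr", weights = "uniform")
  expect_lt(max(abs(both$amplitude_nv)), 0.05 * max(abs(single$amplitude_nv)))
})
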