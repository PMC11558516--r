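test_that("kernel construction places biphasic waves at stated latencies", {
  k1 <- make_kernel(kernel_spec(
    data.frame(label = "V", latency_ms = 6.9, amplitude_nv = 100,
               width_ms = 1.1)))
  expect_equal(k1$lags_ms[which.max(k1$amplitude_nv)], 6.9, tolerance = 0.11)
  expect_equal(max(k1$amplitude_nv), 100, tolerance = 0.01)

  k0 <- make_kernel(kernel_spec(data.frame(label = character(),
                                           latency_ms = numeric(),
                                           amplitude_nv = numeric(),
                                           width_ms = numeric())))
  expect_true(all(k0$amplitude_nv == 0))

  # three local maxima recovered by a brute-force extrema scan
  k3 <- canonical_kernel()
  a <- k3$amplitude_nv
  mid <- 2:(length(a) - 1)
  ix <- mid[a[mid] > a[mid - 1] & a[mid] > a[mid + 1]]
  peaks <- k3$lags_ms[ix][a[ix] > 10]
  for (lat in c(1.7, 3.9, 6.9)) {
    expect_true(min(abs(peaks - lat)) <= 0.1)
  }
})

test_that("kernel spec validation enforces wave order and coverage", {
  expect_error(kernel_spec(data.frame(label = c("V", "I"),
                                      latency_ms = c(6.9, 1.7),
                                      amplitude_nv = c(100, 30),
                                      width_ms = c(1, 0.5))),
               "increasing")
  expect_error(kernel_spec(default_abr_waves(), duration_ms = 5), "duration")
  expect_warning(make_kernel(kernel_spec(
    data.frame(label = c("III", "V"), latency_ms = c(6.0, 6.4),
               amplitude_nv = c(100, 40), width_ms = c(2.5, 2.5)),
    duration_ms = 16)), "merged")
})

test_that("synthetic speech carries the requested pulse train and pitch", {
  ct <- synth_f0_contour(1, 123)
  sp <- make_synthetic_speech(ct, seed = 3)
  # pulse count from the f0 integral: 123 Hz over ~1 s of voicing
  expect_true(abs(length(sp$pulses$times) - 123) <= 2)

  # fully unvoiced contour -> no pulses
  silent <- f0_contour(seq(0.005, 1, by = 0.01), rep(0, 100))
  sp0 <- make_synthetic_speech(silent, seed = 4)
  expect_length(sp0$pulses$times, 0)

  # independent autocorrelation estimate of the output pitch
  sp150 <- make_synthetic_speech(synth_f0_contour(1, 150), seed = 5)
  est <- acf_pitch(sp150$audio$samples, sp150$audio$sample_rate)
  expect_lt(abs(est - 150) / 150, 0.02)

  expect_error(make_synthetic_speech(ct, duration = 0, seed = 1), "duration")
})

test_that("EEG simulation is exact without noise and seed-deterministic", {
  k <- canonical_kernel()
  set.seed(1)
  tr <- list(glottal_like_train(123, 1))
  ep <- noiseless_epochs(k, tr)
  # exact inversion: deconvolution with no ridge recovers the kernel
  resp <- derive_response(ep, method = "deconv", weights = "uniform",
                          reg_epsilon = 0, lag_range = c(0, 16))
  expect_lt(max(abs(resp$amplitude_nv - kernel_on(k, resp$lags_ms))),
            1e-6 * max(k$amplitude_nv))

  set.seed(2); tr2 <- list(glottal_like_train(123, 1), glottal_like_train(150, 1))
  r1 <- simulate_subject_eeg(k, tr2, noise = noise_spec(), seed = 7)
  r2 <- simulate_subject_eeg(k, tr2, noise = noise_spec(), seed = 7)
  expect_identical(r1$samples, r2$samples)

  expect_error(
    simulate_subject_eeg(make_kernel(kernel_spec(duration_ms = 600)),
                         list(pulse_train(0.1, duration = 0.5)),
                         noise = noise_spec(), seed = 1),
    "longer")
})

test_that("rate adaptation scales and shifts the embedded kernel", {
  k <- canonical_kernel()
  ad <- adaptation_spec(amplitude_slope = -0.3, latency_slope = 0.003,
                        reference_rate = 123)
  trains <- list(
    pulse_train(seq(0.1, 0.9, by = 1 / 123)[1:90], duration = 1,
                nominal_rate = 123),
    pulse_train(seq(0.1, 0.9, by = 1 / 183)[1:140], duration = 1,
                nominal_rate = 183))
  rec <- simulate_subject_eeg(k, trains, noise = noise_spec(0, 60, 0, c(1, 1)),
                              adaptation = ad, n_channels = 1, seed = 3)
  emb <- attr(rec, "embedded_kernels")
  p1 <- max(emb[[1]]$amplitude_nv); p2 <- max(emb[[2]]$amplitude_nv)
  # slope x rate difference: -0.3 nV/Hz x 60 Hz = 18 nV
  expect_equal(p1 - p2, 18, tolerance = 0.5)

  # monotonicity over rates: amplitude non-increasing, latency non-decreasing
  rates <- c(123, 150, 183)
  peaks <- numeric(3); lats <- numeric(3)
  for (i in seq_along(rates)) {
    tri <- list(pulse_train(seq(0.1, 0.9, length.out = 50), duration = 1,
                            nominal_rate = rates[i]))
    reci <- simulate_subject_eeg(k, tri, noise = noise_spec(0, 60, 0, c(1, 1)),
                                 adaptation = adaptation_spec(), seed = 4)
    e <- attr(reci, "embedded_kernels")[[1]]
    peaks[i] <- max(e$amplitude_nv)
    lats[i] <- e$lags_ms[which.max(e$amplitude_nv)]
  }
  expect_true(all(diff(peaks) <= 0))
  expect_true(all(diff(lats) >= 0))
})

test_that("pink noise follows a 1/f power trend and hits the requested RMS", {
  set.seed(8)
  x <- peakyabr:::pink_noise(2^15, rms = 100)
  expect_equal(stats::sd(x), 100, tolerance = 1e-6)
  sp <- Mod(stats::fft(x))^2
  lo <- mean(sp[10:100]); hi <- mean(sp[1000:10000])
  expect_gt(lo / hi, 5)   # substantially more power at low frequencies
})
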