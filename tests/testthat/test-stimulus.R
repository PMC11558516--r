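test_that("pitch tracking recovers known f0 and rejects aperiodic input", {
  sp <- make_synthetic_speech(synth_f0_contour(1, 123), seed = 3)
  ct <- track_pitch(sp$audio)
  expect_gte(ct$mean_f0, 120.5)
  expect_lte(ct$mean_f0, 125.5)

  set.seed(4)
  noise <- audio_stimulus(rnorm(48000), 48000)
  expect_lt(mean(track_pitch(noise)$voiced_mask), 0.10)

  silence <- audio_stimulus(numeric(48000), 48000)
  expect_true(all(!track_pitch(silence)$voiced_mask))

  expect_error(track_pitch(sp$audio, fmin = 400, fmax = 60), "fmin")
})

test_that("target f0 set is the two talkers plus their geometric mean", {
  t1 <- target_f0_set(123, 183)
  expect_equal(t1, c(123, sqrt(123 * 183), 183))
  expect_equal(round(t1[2]), 150)
  expect_equal(target_f0_set(100, 100), rep(100, 3))
  expect_equal(target_f0_set(90, 160)[2], 120)
  expect_error(target_f0_set(-1, 100), "> 0")
})

test_that("pitch shifting moves mean f0 by the factor, preserving duration", {
  sp <- make_synthetic_speech(synth_f0_contour(1.2, 123), seed = 3)
  expect_identical(shift_pitch(sp$audio, 1), sp$audio)

  up <- shift_pitch(sp$audio, 183 / 123)
  expect_length(up$samples, length(sp$audio$samples))
  f_up <- track_pitch(up)$mean_f0
  expect_gte(f_up, 179); expect_lte(f_up, 187)

  spf <- make_synthetic_speech(synth_f0_contour(1.2, 183), seed = 6)
  down <- shift_pitch(spf$audio, 123 / 183)
  f_dn <- track_pitch(down)$mean_f0
  expect_gte(f_dn, 120); expect_lte(f_dn, 126)

  # composition: shift by r then 1/r restores the mean f0 within 2%
  back <- shift_pitch(up, 123 / 183)
  expect_lt(abs(track_pitch(back)$mean_f0 - 123) / 123, 0.02)

  expect_error(shift_pitch(sp$audio, 2.5), "factor")
})

test_that("pulse placement integrates the f0 contour phase", {
  const <- synth_f0_contour(1.0001, 100)
  p <- pulses_from_contour(const, duration = 1.0001)
  expect_equal(length(p$times), 100, tolerance = 1)
  expect_equal(unname(diff(p$times)), rep(0.01, length(p$times) - 1),
               tolerance = 1e-6)

  ramp <- f0_contour(seq(0.005, 1, by = 0.01),
                     seq(100, 200, length.out = 100))
  pr <- pulses_from_contour(ramp, duration = 1)
  expect_equal(length(pr$times), 150, tolerance = 2)

  unv <- f0_contour(seq(0.005, 1, by = 0.01), rep(0, 100))
  expect_length(pulses_from_contour(unv, duration = 1)$times, 0)
})

test_that("peaky re-synthesis is phase-only and more impulsive", {
  sp <- make_synthetic_speech(synth_f0_contour(1.2, 123), seed = 3)
  pk <- resynthesize_peaky(sp$audio, sp$pulses)

  m_in <- mag_spectrogram(sp$audio$samples)
  m_out <- mag_spectrogram(pk$samples)
  expect_gte(stats::cor(as.vector(m_in), as.vector(m_out)), 0.90)

  v <- sp$audio$voiced_spans
  t <- (seq_along(sp$audio$samples) - 1) / sp$audio$sample_rate
  vm <- t >= v[1, 1] & t < v[1, 2]
  expect_gt(excess_kurtosis(pk$samples[vm]),
            excess_kurtosis(sp$audio$samples[vm]))

  # total RMS preserved within +-3 dB
  db <- 20 * log10(stats::sd(pk$samples[vm]) / stats::sd(sp$audio$samples[vm]))
  expect_lt(abs(db), 3)

  # silence with no pulses passes through unchanged
  sil <- audio_stimulus(numeric(24000), 48000)
  out <- resynthesize_peaky(sil, pulse_train(numeric(0), duration = 0.5))
  expect_lt(max(abs(out$samples)), 1e-10)

  # unvoiced-only audio: output equals input within cross-fade tolerance
  set.seed(9)
  unv <- audio_stimulus(rnorm(24000) * 0.1, 48000)
  out2 <- resynthesize_peaky(unv, pulse_train(numeric(0), duration = 0.5))
  expect_lt(max(abs(out2$samples - unv$samples)), 1e-8)

  expect_error(
    resynthesize_peaky(sp$audio, pulse_train(1.19, duration = 1.2),
                       voiced_spans = matrix(c(0, 0.5), 1)),
    "voiced")
})

test_that("Poisson click trains have exponential ISIs and inverted twins", {
  eps <- make_poisson_clicks(123, 1, 150, seed = 2)
  n_clicks <- sum(vapply(eps, function(p) length(p$plus$times), 1))
  expect_lt(abs(n_clicks - 150 * 123), 3 * sqrt(150 * 123))

  big <- make_poisson_clicks(123, 100, 2, seed = 3)
  isi <- unlist(lapply(big, function(p) diff(p$plus$times)))
  expect_gte(length(isi), 1e4)
  expect_lt(abs(mean(isi) - 1 / 123) / (1 / 123), 0.05)

  # ISIs exponential once the refractory floor is removed
  floor_s <- 0.001
  ks <- stats::ks.test(isi - floor_s, "pexp", 1 / (1 / 123 - floor_s))
  expect_gt(ks$p.value, 0.01)

  expect_identical(eps[[1]]$plus$times, eps[[1]]$minus$times)
  expect_identical(eps[[1]]$minus$polarity, -eps[[1]]$plus$polarity)
  expect_error(make_poisson_clicks(-5, 1, 1, seed = 1), "rate")
})

test_that("segmentation truncates silences, fades edges, alternates sign", {
  set.seed(10)
  sr <- 48000
  x <- rnorm(35 * sr) * 0.2
  segs <- segment_and_fade(audio_stimulus(x, sr), alternate_polarity = FALSE)
  expect_length(segs, 3)                       # floor(35 / 10), remainder dropped
  s1 <- segs[[1]]$samples
  expect_lt(abs(s1[1]), 1e-6)
  expect_lt(abs(s1[length(s1)]), 1e-6)
  expect_equal(length(s1) / sr, 10)

  segs2 <- segment_and_fade(audio_stimulus(x, sr), alternate_polarity = TRUE)
  expect_equal(segs2[[2]]$samples, -segs[[2]]$samples)

  # a 2-s silence is shortened to <= 0.5 s
  y <- c(rnorm(12 * sr) * 0.2, numeric(2 * sr), rnorm(10 * sr) * 0.2)
  expect_lt(length(peakyabr:::truncate_silences(y, sr, 0.5)) / sr, 22.6)
})

test_that("click epoch concatenation follows the A+A-B+B- ordering", {
  eps <- make_poisson_clicks(123, 1, 6, seed = 4)
  trials <- concat_click_epochs(eps, trial_dur = 3)
  expect_length(trials, 4)
  tr1 <- trials[[1]]
  # first second: epoch A+, second second: epoch A-, third: B+
  a_plus <- eps[[1]]$plus$times
  expect_equal(tr1$times[tr1$times < 1], a_plus)
  expect_equal(tr1$times[tr1$times >= 1 & tr1$times < 2] - 1, a_plus)
  pol_first <- tr1$polarity[tr1$times < 1]
  pol_second <- tr1$polarity[tr1$times >= 1 & tr1$times < 2]
  expect_true(all(pol_first == 1) && all(pol_second == -1))
})
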