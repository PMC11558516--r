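test_that("windowed Pearson correlation matches the covariance formula", {
  lags <- seq(-20, 60, by = 0.1)
  set.seed(20)
  a <- response_waveform(lags, rnorm(length(lags)))
  b <- response_waveform(lags, rnorm(length(lags)))
  expect_equal(window_pearson(a, a), 1)
  neg <- a; neg$amplitude_nv <- -a$amplitude_nv
  expect_equal(window_pearson(a, neg), -1)

  ix <- lags >= 2 & lags <= 12
  x <- a$amplitude_nv[ix]; y <- b$amplitude_nv[ix]
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(window_pearson(a, b), oracle, tolerance = 1e-12)

  const <- response_waveform(lags, rep(1, length(lags)))
  expect_error(window_pearson(a, const), "constant")
})

test_that("signed-rank test is exact for small n and matches enumeration", {
  five <- c(0.3, 1.2, 0.8, 2.2, 0.5)
  res <- signed_rank(five, alternative = "greater")
  expect_equal(res$p, 1 / 32)
  expect_equal(res$method, "exact")

  set.seed(21)
  x <- rnorm(15, mean = 0.4)
  res15 <- signed_rank(x)
  expect_equal(res15$p, signed_rank_enum(x), tolerance = 1e-12)

  # symmetric pairs sit at the null median of W
  sym <- c(1, -1.5, 2, -2.5, 3, -3.5, 4, -4.5)
  ressym <- signed_rank(sym)
  expect_gt(ressym$p, 0.5)

  expect_error(signed_rank(c(1, 2)), "at least 5")
  expect_error(signed_rank(rep(0, 6)), "zero")
})

test_that("FDR adjustment is the BH step-up and dominates raw p", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(22)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("wave V picking finds peak, following trough and gates on SNR", {
  k <- canonical_kernel()
  lags <- seq(-20, 60, by = 0.1)
  resp <- response_waveform(lags, kernel_on(k, lags))
  wv <- pick_wave_v(resp)
  expect_true(wv$found)
  expect_equal(wv$peak_latency_ms, 6.9, tolerance = 0.11)
  # independent expectation: window max minus the minimum in the 6 ms after
  a <- kernel_on(k, lags)
  pk <- which.max(a)
  tr_val <- min(a[lags > lags[pk] & lags <= lags[pk] + 6])
  expect_equal(wv$p2t_amplitude_nv, a[pk] - tr_val, tolerance = 1e-9)

  set.seed(23)
  noise <- response_waveform(lags, rnorm(length(lags), sd = 5))
  wn <- pick_wave_v(noise, snr_gate = 4)
  expect_false(wn$found)

  # tie between equal peaks resolves to the earlier one
  twin <- numeric(length(lags))
  twin[lags == 6] <- 10; twin[lags == 9] <- 10
  twin[lags == 7.5] <- -5
  tw <- pick_wave_v(response_waveform(lags, twin), snr_gate = 0)
  expect_equal(tw$peak_latency_ms, 6)

  expect_error(pick_wave_v(response_waveform(seq(0, 5, 0.1),
                                             numeric(51))), "window")
})

test_that("planted latencies are recovered exactly without noise, closely at 6 dB", {
  lags <- seq(-20, 60, by = 0.1)
  # noise-free: exact to one sample for every planted latency
  for (lat in seq(5, 9, by = 0.5)) {
    spec <- kernel_spec(data.frame(label = "V", latency_ms = lat,
                                   amplitude_nv = 100, width_ms = 1.1),
                        duration_ms = 16)
    sig <- kernel_on(make_kernel(spec), lags)
    wv <- pick_wave_v(response_waveform(lags, sig), snr_gate = 0)
    expect_lte(abs(wv$peak_latency_ms - lat), 0.1)
  }
  # at 6 dB (band-limited noise, RMS half the peak) the latency error stays
  # small in the median even though single-sample precision is not possible
  set.seed(24)
  errs <- numeric(60)
  for (i in seq_along(errs)) {
    lat <- sample(seq(5, 9, by = 0.1), 1)
    spec <- kernel_spec(data.frame(label = "V", latency_ms = lat,
                                   amplitude_nv = 100, width_ms = 1.1),
                        duration_ms = 16)
    sig <- kernel_on(make_kernel(spec), lags)
    n <- bandpass_abr(rnorm(3000), sample_rate = 1e4)[1500:(1499 + length(lags))]
    n <- n / stats::sd(n) * 100 / 2
    wv <- pick_wave_v(response_waveform(lags, sig + n), snr_gate = 0)
    errs[i] <- abs(wv$peak_latency_ms - lat)
  }
  expect_lte(stats::median(errs), 0.5)
})

test_that("split-half halves are balanced across conditions", {
  k <- canonical_kernel()
  set.seed(25)
  sub <- simulate_subject_epochs(
    k, c(123, 183), n_trials = 3, trial_dur = 0.5,
    noise = scaled_noise_spec(3, 0.5), seed = 26, n_channels = 1,
    pad = 0.3, front_end = "bandpass")
  # drop one trial of condition b: only condition a has an odd count
  keep <- c(1, 2, 3, 4, 5)
  expect_warning(
    halves <- split_half_null(sub$epochs[keep], sub$conditions[keep]),
    "odd")
  expect_equal(halves$even$n_trials, 2)
  expect_equal(halves$odd$n_trials, 2)

  # two trials total: one per half
  two <- split_half_null(sub$epochs[1:2], c("a", "a"))
  expect_equal(two$even$n_trials, 1)
  expect_equal(two$odd$n_trials, 1)
})

test_that("condition summaries report means, SEs and talker ratios", {
  m <- tibble::tibble(
    participant = rep(1:3, each = 2),
    talker = rep(c("male", "female"), 3),
    rate_f0 = rep(c(123, 183), 3),
    amplitude_nv = c(150, 100, 200, 100, 250, 100),
    latency_ms = rep(7, 6))
  s <- summarize_conditions(m)
  expect_equal(s$ratios$per_participant$ratio, c(1.5, 2, 2.5))
  expect_equal(s$ratios$group$ratio_mean, 2)
  expect_equal(s$ratios$group$ratio_se, sd(c(1.5, 2, 2.5)) / sqrt(3))

  all2 <- dplyr::mutate(m, amplitude_nv = rep(c(200, 100), 3))
  s2 <- summarize_conditions(all2)
  expect_equal(s2$ratios$group$ratio_mean, 2)
  expect_equal(s2$ratios$group$ratio_se, 0)

  expect_warning(summarize_conditions(m[-1, ]), "missing")
})

test_that("an embedded talker effect lowers cross-condition correlation", {
  res <- cohort_correlation_test(n_subjects = 8, rates = c(123, 183), seed = 33)
  expect_gt(mean(res$per_participant$r_null - res$per_participant$r_cross), 0)
  expect_lt(res$p, 0.05)
})
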