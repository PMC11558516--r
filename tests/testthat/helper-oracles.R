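# shared fixtures and independent oracles for the test suite

canonical_kernel <- function() make_kernel(kernel_spec())

# brute-force time-domain circular cross-correlation at selected lags,
# matching the frequency-domain estimator's indexing (lag 0 at index 1)
xcorr_oracle <- function(eeg, reg, lags, norm) {
  n <- length(eeg)
  vapply(lags, function(l) {
    shifted <- reg[((seq_len(n) - 1 - l) %% n) + 1]
    sum(eeg * shifted) / norm
  }, numeric(1))
}

# independent whole-signal autocorrelation pitch estimate (no framing)
acf_pitch <- function(x, sr, fmin = 60, fmax = 400) {
  x <- x - mean(x)
  lag_min <- floor(sr / fmax); lag_max <- ceiling(sr / fmin)
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = FALSE,
                   type = "correlation")$acf[, 1, 1]
  cand <- lag_min:lag_max
  sr / cand[which.max(ac[cand + 1])]
}

excess_kurtosis <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  mean((x - m)^4) / s^4 - 3
}

# magnitude spectrogram by plain windowed FFT frames (independent of the
# package's STFT helpers)
mag_spectrogram <- function(x, n = 512, hop = 256) {
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  starts <- seq(1, length(x) - n + 1, by = hop)
  sapply(starts, function(s) Mod(stats::fft(x[s:(s + n - 1)] * w))[1:(n / 2)])
}

# exact signed-rank p by enumeration of all 2^n sign patterns (two-sided)
signed_rank_enum <- function(x, alternative = "two.sided") {
  x <- x[x != 0]
  n <- length(x)
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  combos <- expand.grid(rep(list(c(0, 1)), n))
  Ws <- as.matrix(combos) %*% r
  p_ge <- mean(Ws >= W); p_le <- mean(Ws <= W)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Benjamini-Hochberg step-up from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# one noiseless trial epoched around a single train (for exact inversion)
noiseless_epochs <- function(kernel, trains, pad = 0.5, n_channels = 1,
                             seed = 5) {
  rec <- simulate_subject_eeg(
    kernel, trains,
    noise = noise_spec(0, 60, 0, c(1, 1)),
    adaptation = NULL, n_channels = n_channels, seed = seed,
    edge_pad = pad + 0.1)
  make_epochs(rec, trains, pad = pad)
}

kernel_on <- function(kernel, lags_ms) {
  stats::approx(kernel$lags_ms, kernel$amplitude_nv, xout = lags_ms,
                yleft = 0, yright = 0)$y
}
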