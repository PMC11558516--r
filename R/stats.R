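#' Pearson correlation of two response waveforms over a lag window
#'
#' Waveform morphologies are compared over the closed window (2-12 ms by
#' default, the speech-ABR comparison window).
#'
#' @param a,b [response_waveform()]s on a common lag axis.
#' @param window closed lag window in ms.
#' @return Pearson r.
#' @export
window_pearson <- function(a, b, window = c(2, 12)) {
  stopifnot(inherits(a, "response_waveform"), inherits(b, "response_waveform"))
  if (length(a$lags_ms) != length(b$lags_ms) ||
      max(abs(a$lags_ms - b$lags_ms)) > 1e-9) {
    stop("waveforms must share a common lag axis")
  }
  ix <- a$lags_ms >= window[1] & a$lags_ms <= window[2]
  x <- a$amplitude_nv[ix]; y <- b$amplitude_nv[ix]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant waveform in the window")
  }
  stats::cor(x, y)
}

#' Split-half (even/odd) null responses balanced across two conditions
#'
#' Trials of both conditions are interleaved and split into even and odd
#' halves such that each half contains an equal number of trials from each
#' condition, nullifying any condition effect; the two halves are then
#' derived like ordinary conditions. The even/odd correlation is the null
#' against which the cross-condition correlation is tested.
#'
#' @param epochs list of [trial_epoch()]s (all conditions together).
#' @param conditions condition label per epoch (two levels).
#' @param method,weights,lag_range passed to [derive_response()].
#' @return List with `even` and `odd` [response_waveform()]s.
#' @export
split_half_null <- function(epochs, conditions,
                            method = "deconv", weights = "inverse_variance",
                            lag_range = c(-20, 60)) {
  stopifnot(length(epochs) == length(conditions))
  lev <- unique(conditions)
  even_ix <- integer(0); odd_ix <- integer(0)
  for (l in lev) {
    ix <- which(conditions == l)
    if (length(ix) %% 2 == 1) {
      warning("odd trial count for condition '", l, "'; dropping last trial")
      ix <- ix[-length(ix)]
    }
    pos <- seq_along(ix)
    even_ix <- c(even_ix, ix[pos %% 2 == 0])
    odd_ix <- c(odd_ix, ix[pos %% 2 == 1])
  }
  list(even = derive_response(epochs[even_ix], method = method,
                              weights = weights, lag_range = lag_range),
       odd = derive_response(epochs[odd_ix], method = method,
                             weights = weights, lag_range = lag_range))
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Exact p (enumeration of sign patterns) for n <= 25 after removing zero
#' differences; normal approximation with continuity correction above.
#'
#' @param x paired differences, n >= 5.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List with `W` (signed-rank statistic), `p`, `n` and `method`.
#' @export
signed_rank <- function(x, alternative = "two.sided") {
  x <- x[!is.na(x)]
  if (length(x) < 5) stop("need at least 5 paired differences")
  if (all(x == 0)) stop("all differences are zero")
  nz <- sum(x != 0)
  exact <- nz <= 25 && !any(duplicated(abs(x[x != 0])))
  ht <- suppressWarnings(
    stats::wilcox.test(x, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  list(W = unname(ht$statistic), p = ht$p.value, n = nz,
       method = if (exact) "exact" else "normal approximation")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values: monotone in rank order, component-wise at
#' least the raw p, capped at 1.
#'
#' @param pvals raw p values in `[0, 1]`.
#' @return Adjusted p values.
#' @export
fdr_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Pick the wave V peak and following trough
#'
#' The peak is the largest local maximum within the search window (ties
#' broken toward the earlier peak); the following trough is the minimum
#' within `trough_window` ms after the peak, the bounded-window rule used in
#' clinical ABR reading (a first-local-minimum rule is unstable on waveforms
#' with residual noise ripple). The peak must exceed `snr_gate` times the
#' pre-stimulus (-20 to 0 ms) RMS, else the measure is flagged not-found. A
#' response without pre-stimulus lags skips the gate.
#'
#' @param resp a [response_waveform()] covering the window.
#' @param window search window in ms.
#' @param trough_window how far after the peak to search for the trough, ms.
#' @param snr_gate peak-to-noise-floor factor (default 2).
#' @return A one-row [tibble::tibble()]: `found`, `peak_latency_ms`,
#'   `peak_amplitude_nv`, `trough_latency_ms`, `trough_amplitude_nv`,
#'   `p2t_amplitude_nv`.
#' @export
pick_wave_v <- function(resp, window = c(4, 12), trough_window = 6,
                        snr_gate = 2) {
  stopifnot(inherits(resp, "response_waveform"))
  l <- resp$lags_ms; a <- resp$amplitude_nv
  if (min(l) > window[1] || max(l) < window[2]) {
    stop("response does not cover the search window")
  }
  not_found <- tibble::tibble(found = FALSE, peak_latency_ms = NA_real_,
                              peak_amplitude_nv = NA_real_,
                              trough_latency_ms = NA_real_,
                              trough_amplitude_nv = NA_real_,
                              p2t_amplitude_nv = NA_real_)
  inside <- which(l >= window[1] & l <= window[2])
  inside <- inside[inside > 1 & inside < length(a)]
  is_max <- a[inside] > a[inside - 1] & a[inside] >= a[inside + 1]
  cand <- inside[is_max]
  if (!length(cand)) return(not_found)
  pk <- cand[which.max(a[cand])]          # which.max takes the earlier on ties
  pre <- l >= -20 & l <= 0
  if (any(pre)) {
    floor_rms <- sqrt(mean(a[pre]^2))
    if (a[pk] < snr_gate * floor_rms) return(not_found)
  }
  after <- which(l > l[pk] & l <= l[pk] + trough_window)
  if (!length(after)) return(not_found)
  tr <- after[which.min(a[after])]
  tibble::tibble(found = TRUE, peak_latency_ms = l[pk],
                 peak_amplitude_nv = a[pk], trough_latency_ms = l[tr],
                 trough_amplitude_nv = a[tr],
                 p2t_amplitude_nv = a[pk] - a[tr])
}

#' Summarize wave V measures across participants and conditions
#'
#' @param measures tibble with columns `participant`, `talker` (`"male"` /
#'   `"female"` for speech, or another stimulus label), `rate_f0` (Hz),
#'   `amplitude_nv`, `latency_ms`.
#' @return List of tibbles: `conditions` (per talker x rate_f0 mean +- SE of
#'   amplitude and latency) and `ratios` (per-participant male/female
#'   amplitude ratio at matched rate_f0, plus group mean +- SE per rate_f0).
#' @export
summarize_conditions <- function(measures) {
  m <- tibble::as_tibble(measures)
  need <- c("participant", "talker", "rate_f0", "amplitude_nv", "latency_ms")
  stopifnot(all(need %in% names(m)))
  se <- function(x) stats::sd(x) / sqrt(length(x))
  conditions <- m |>
    dplyr::group_by(.data$talker, .data$rate_f0) |>
    dplyr::summarise(
      n = dplyr::n(),
      amplitude_mean_nv = mean(.data$amplitude_nv),
      amplitude_se_nv = se(.data$amplitude_nv),
      latency_mean_ms = mean(.data$latency_ms),
      latency_se_ms = se(.data$latency_ms),
      .groups = "drop")
  ratios <- NULL
  if (all(c("male", "female") %in% m$talker)) {
    # pair male/female per participant: on target_f0 when the design shifted
    # both talkers to common targets, otherwise at their natural f0s
    keys <- c("participant", if ("target_f0" %in% names(m)) "target_f0")
    wide <- m |>
      dplyr::filter(.data$talker %in% c("male", "female")) |>
      dplyr::select(dplyr::all_of(c(keys, "talker", "amplitude_nv"))) |>
      tidyr_pivot(names_from = "talker", values_from = "amplitude_nv")
    if (anyNA(wide$male) || anyNA(wide$female)) {
      warning("missing cells; ratios computed on pairwise-complete rows")
      wide <- wide[!is.na(wide$male) & !is.na(wide$female), ]
    }
    per <- dplyr::mutate(wide, ratio = .data$male / .data$female)
    grp <- if ("target_f0" %in% keys) {
      dplyr::group_by(per, .data$target_f0)
    } else {
      per
    }
    ratios <- list(
      per_participant = per,
      group = dplyr::summarise(grp, n = dplyr::n(),
                               ratio_mean = mean(.data$ratio),
                               ratio_se = se(.data$ratio), .groups = "drop"))
  }
  list(conditions = conditions, ratios = ratios)
}

# minimal pivot_wider so tidyr is not a hard dependency
tidyr_pivot <- function(df, names_from, values_from) {
  keys <- setdiff(names(df), c(names_from, values_from))
  out <- unique(df[keys])
  for (lev in unique(df[[names_from]])) {
    sub <- df[df[[names_from]] == lev, c(keys, values_from)]
    names(sub)[names(sub) == values_from] <- lev
    out <- dplyr::left_join(out, sub, by = keys)
  }
  tibble::as_tibble(out)
}

#' Cross-condition vs split-half-null correlation comparison
#'
#' The complete comparison procedure for one cohort: per participant, the
#' male-vs-female waveform correlation over the window and the even-vs-odd
#' null correlation are computed; the paired differences (null minus cross)
#' are tested with the Wilcoxon signed-rank test.
#'
#' @param subject_fits list over participants; each element a list with
#'   `cross` (r between the two condition waveforms) and `null` (r between
#'   the balanced even/odd waveforms), e.g. from [fit_subject_correlations()].
#' @param alternative passed to [signed_rank()].
#' @return List with tibble `per_participant`, `W`, `p`.
#' @export
compare_correlations <- function(subject_fits, alternative = "two.sided") {
  tab <- tibble::tibble(
    participant = seq_along(subject_fits),
    r_cross = vapply(subject_fits, function(s) s$cross, 1),
    r_null = vapply(subject_fits, function(s) s$null, 1))
  ht <- signed_rank(tab$r_null - tab$r_cross, alternative = alternative)
  list(per_participant = tab, W = ht$W, p = ht$p)
}

#' Per-participant cross-condition and null correlations from epochs
#'
#' Derives the two condition waveforms and the balanced even/odd split from
#' one participant's epochs and returns both correlations over the window.
#'
#' @param epochs list of [trial_epoch()]s for the two conditions.
#' @param conditions condition label per epoch (two levels).
#' @param window correlation window in ms.
#' @param method,weights passed to [derive_response()].
#' @param reg_epsilon deconvolution regularization (see [derive_response()]).
#' @return List with `cross` and `null` correlation coefficients.
#' @export
fit_subject_correlations <- function(epochs, conditions, window = c(2, 12),
                                     method = "deconv",
                                     weights = "inverse_variance",
                                     reg_epsilon = 1e-3) {
  lev <- unique(conditions)
  stopifnot(length(lev) == 2)
  lag_range <- c(-20, 60)
  ts <- trial_spectra(epochs, method = method)
  sr <- epochs[[1]]$sample_rate
  resp_for <- function(ix) {
    combine_trial_spectra(ts, sr, weights = weights, lag_range = lag_range,
                          trials = ix, reg_epsilon = reg_epsilon)
  }
  ix1 <- which(conditions == lev[1]); ix2 <- which(conditions == lev[2])
  r_cross <- window_pearson(resp_for(ix1), resp_for(ix2), window)
  even_ix <- integer(0); odd_ix <- integer(0)
  for (ix in list(ix1, ix2)) {
    if (length(ix) %% 2 == 1) ix <- ix[-length(ix)]
    pos <- seq_along(ix)
    even_ix <- c(even_ix, ix[pos %% 2 == 0])
    odd_ix <- c(odd_ix, ix[pos %% 2 == 1])
  }
  r_null <- window_pearson(resp_for(even_ix), resp_for(odd_ix), window)
  list(cross = r_cross, null = r_null)
}
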