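#' Write an audio stimulus as a WAV file
#'
#' Minimal RIFF/WAVE writer: IEEE float32 (default) or 16-bit PCM, mono,
#' little-endian.
#'
#' @param audio an [audio_stimulus()].
#' @param path output path.
#' @param format `"float32"` or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  x <- audio$samples
  sr <- as.integer(audio$sample_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- if (format == "float32") 32L else 16L
  fmt_code <- if (format == "float32") 3L else 1L
  data_bytes <- length(x) * bits / 8
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36 + data_bytes)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16); w16(fmt_code); w16(1)           # mono
  w32(sr); w32(sr * bits / 8); w16(bits / 8); w16(bits)
  writeChar("data", con, eos = NULL)
  w32(data_bytes)
  if (format == "float32") {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(-1, pmin(1, x)) * 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file into an audio stimulus
#'
#' Reads mono or multi-channel (averaged to mono) PCM16/PCM32/float32 WAV.
#'
#' @param path WAV path.
#' @param kind stimulus kind label.
#' @return An [audio_stimulus()].
#' @export
read_wav <- function(path, kind = "speech") {
  con <- file(path, "rb")
  on.exit(close(con))
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  r32()
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt_code <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) stop("no data chunk found")
    size <- r32()
    if (id == "fmt ") {
      fmt_code <- r16(); n_ch <- r16(); sr <- r32(); r32(); r16()
      bits <- r16()
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (is.null(fmt_code)) stop("data chunk before fmt chunk")
      n <- size / (bits / 8)
      x <- if (fmt_code == 3) {
        readBin(con, "numeric", n = n, size = 4, endian = "little")
      } else if (bits == 16) {
        readBin(con, "integer", n = n, size = 2, endian = "little") / 32767
      } else {
        readBin(con, "integer", n = n, size = 4, endian = "little") / 2147483647
      }
      if (n_ch > 1) x <- colMeans(matrix(x, n_ch))
      return(audio_stimulus(x, sr, kind = kind))
    } else {
      readBin(con, "raw", size)
    }
  }
}

#' Write a pulse train as two-column text or JSON
#'
#' Text format: two whitespace-separated columns `time_s`, `polarity`
#' with a `#` header line. JSON carries `times_s`, `polarity`, `duration_s`,
#' `nominal_rate_hz`.
#'
#' @param train a [pulse_train()].
#' @param path output path; format chosen by `.json` extension.
#' @return `path`, invisibly.
#' @export
write_pulse_train <- function(train, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(times_s = train$times, polarity = train$polarity,
           duration_s = train$duration, nominal_rate_hz = train$nominal_rate),
      path, digits = NA, auto_unbox = TRUE)
  } else {
    writeLines(c("# time_s polarity",
                 sprintf("%.9f %d", train$times, as.integer(train$polarity))),
               path)
  }
  invisible(path)
}

#' Read a pulse train written by [write_pulse_train()]
#'
#' @param path input path (two-column text or JSON).
#' @param duration total duration in s; required for the text format.
#' @return A [pulse_train()].
#' @export
read_pulse_train <- function(path, duration = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(pulse_train(j$times_s, duration = j$duration_s,
                       polarity = if (length(j$polarity)) j$polarity else 1,
                       nominal_rate = j$nominal_rate_hz))
  }
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("time_s", "polarity"))
  if (is.null(duration)) stop("duration required for two-column text format")
  pulse_train(tab$time_s, duration = duration,
              polarity = if (nrow(tab)) tab$polarity else 1)
}

#' Write an EEG recording as a flat binary matrix with a JSON sidecar
#'
#' Samples are written as little-endian float64, channel-major (all samples
#' of channel 1, then channel 2, ...). The sidecar `<path>.json` records
#' `sample_rate_hz`, `channel_names`, `n_samples`, `trial_onsets_s`,
#' `dtype`, `byte_order` and `layout`.
#'
#' @param rec an [eeg_recording()].
#' @param path output path for the binary samples (sidecar at `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_eeg_bin <- function(rec, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(t(rec$samples)), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(sample_rate_hz = rec$sample_rate, channel_names = rec$channel_names,
         n_channels = nrow(rec$samples), n_samples = ncol(rec$samples),
         trial_onsets_s = rec$trial_onsets, dtype = "float64",
         byte_order = "little",
         layout = "channel-major (all samples of channel 1, then channel 2, ...)"),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an EEG recording written by [write_eeg_bin()]
#'
#' @param path path to the binary samples (expects sidecar `<path>.json`).
#' @return An [eeg_recording()].
#' @export
read_eeg_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  x <- readBin(con, "numeric", n = meta$n_channels * meta$n_samples,
               size = 8, endian = "little")
  close(con)
  eeg_recording(matrix(x, meta$n_channels, meta$n_samples, byrow = TRUE),
                meta$sample_rate_hz,
                trial_onsets = as.numeric(meta$trial_onsets_s),
                channel_names = meta$channel_names)
}

#' Write a response waveform as two-column text plus JSON metadata
#'
#' @param resp a [response_waveform()].
#' @param path output path (metadata sidecar at `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_response <- function(resp, path) {
  writeLines(c("# lag_ms amplitude_nV",
               sprintf("%.4f %.9g", resp$lags_ms, resp$amplitude_nv)), path)
  jsonlite::write_json(
    list(n_trials = resp$n_trials, weights_used = resp$weights_used,
         channels_averaged = resp$channels_averaged),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a response waveform written by [write_response()]
#'
#' @param path input path.
#' @return A [response_waveform()].
#' @export
read_response <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("lag_ms", "amplitude_nv"))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list(n_trials = 1L, weights_used = FALSE, channels_averaged = FALSE)
  response_waveform(tab$lag_ms, tab$amplitude_nv, n_trials = meta$n_trials,
                    weights_used = meta$weights_used,
                    channels_averaged = meta$channels_averaged)
}
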