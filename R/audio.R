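#' Construct an audio signal
#'
#' Light container for a mono waveform: the raw material of every stage of the
#' breathing-sound pipeline. Samples are real amplitudes, nominally in
#' \[-1, 1\]; the working sample rate throughout the package is 8 kHz.
#'
#' @param samples Numeric vector of amplitudes. Must be finite.
#' @param rate_hz Sampling rate in samples per second (default 8000).
#' @param subject_id Optional subject label carried through the pipeline.
#'
#' @return An object of class `audio_signal`: a list with elements `samples`,
#'   `rate_hz` and `subject_id`.
#' @export
#' @examples
#' s <- audio_signal(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)))
#' duration_s(s)
audio_signal <- function(samples, rate_hz = 8000, subject_id = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    rlang::abort("`rate_hz` must be a single positive number.")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    rlang::abort("`samples` must be finite (no NA/NaN/Inf).")
  }
  structure(
    list(samples = samples, rate_hz = rate_hz, subject_id = subject_id),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal> %s%.2f s at %d Hz (%d samples)\n",
    if (is.null(x$subject_id)) "" else paste0(x$subject_id, ": "),
    duration_s(x), as.integer(x$rate_hz), length(x$samples)
  ))
  invisible(x)
}

#' Duration of an audio signal in seconds
#'
#' @param signal An [audio_signal()].
#' @return Duration in seconds (`length(samples) / rate_hz`).
#' @export
duration_s <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  length(signal$samples) / signal$rate_hz
}

# Rational approximation p/q of a rate ratio for polyphase resampling.
.rate_ratio <- function(to, from) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(to, from)
  c(p = to / d, q = from / d)
}

#' Read a PCM WAV file
#'
#' Reads a RIFF/WAVE file, averages multiple channels to mono, and resamples
#' to `target_rate_hz` (polyphase resampling via [signal::resample()]) when the
#' file's rate differs. Supported encodings: PCM 8-bit unsigned, 16-bit and
#' 32-bit signed integer, and 32-bit IEEE float.
#'
#' Resampled length follows the polyphase contract
#' `round(n * p / q)` for rate ratio `p/q` in lowest terms.
#'
#' @param path Path to a WAV file.
#' @param target_rate_hz Desired sampling rate of the returned signal
#'   (default 8000).
#' @param subject_id Optional subject label to attach.
#'
#' @return An [audio_signal()] at `target_rate_hz`.
#' @export
read_wav <- function(path, target_rate_hz = 8000, subject_id = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    rlang::abort(sprintf("Not a RIFF/WAVE file: %s", path))
  }
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    rlang::abort(sprintf("Not a RIFF/WAVE file: %s", path))
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format    = sum(as.integer(body[1:2]) * c(1L, 256L)),
        channels  = sum(as.integer(body[3:4]) * c(1L, 256L)),
        rate      = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits      = sum(as.integer(body[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    rlang::abort(sprintf("Malformed WAV (missing fmt/data chunk): %s", path))
  }

  bytes_per <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes_per
  x <- switch(
    as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n_total, size = 1,
                               signed = FALSE)) - 128) / 128,
    "16" = as.numeric(readBin(data_raw, "integer", n_total, size = 2,
                              signed = TRUE, endian = "little")) / 32768,
    "32" = if (fmt$format == 3L) {
      as.numeric(readBin(data_raw, "double", n_total, size = 4,
                         endian = "little"))
    } else {
      as.numeric(readBin(data_raw, "integer", n_total, size = 4,
                         endian = "little")) / 2147483648
    },
    rlang::abort(sprintf("Unsupported WAV bit depth: %d", fmt$bits))
  )

  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  if (fmt$rate != target_rate_hz) {
    r <- .rate_ratio(target_rate_hz, fmt$rate)
    x <- as.numeric(signal::resample(x, r[["p"]], r[["q"]]))
  }
  audio_signal(x, target_rate_hz, subject_id = subject_id)
}

#' Write an audio signal as 16-bit PCM WAV
#'
#' Samples are clipped to \[-1, 1\] before quantization.
#'
#' @param signal An [audio_signal()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- pmin(pmax(signal$samples, -1), 1)
  pcm <- as.integer(pmin(pmax(round(x * 32768), -32768), 32767))
  n_bytes <- length(pcm) * 2L
  rate <- as.integer(signal$rate_hz)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

.stage_codes <- c("W", "N1", "N2", "N3", "REM")

#' Parse sleep-stage annotations
#'
#' Reads a UTF-8 CSV with header `subject_id,start_s,end_s,stage` holding the
#' time-stamped sleep-stage scoring of each recording (AASM stage codes W, N1,
#' N2, N3, REM). Intervals are validated (positive length, known stage, no
#' overlap within a subject) and returned sorted by subject and start time.
#'
#' @param path Path to the annotation CSV.
#' @return A tibble with columns `subject_id`, `start_s`, `end_s`, `stage`.
#' @export
parse_stage_annotations <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA)
  required <- c("subject_id", "start_s", "end_s", "stage")
  if (nrow(df) == 0L && !all(required %in% names(df))) {
    # an empty file (header only or fully empty) yields an empty table
    return(tibble::tibble(
      subject_id = character(), start_s = numeric(),
      end_s = numeric(), stage = character()
    ))
  }
  if (!all(required %in% names(df))) {
    rlang::abort(sprintf(
      "Annotation CSV must have columns %s", paste(required, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(df[required])
  out$subject_id <- as.character(out$subject_id)
  out$start_s <- as.numeric(out$start_s)
  out$end_s <- as.numeric(out$end_s)
  out$stage <- as.character(out$stage)
  validate_stage_intervals(out)
}

#' Validate a table of sleep-stage intervals
#'
#' @param intervals Data frame with `subject_id`, `start_s`, `end_s`, `stage`.
#' @return The validated, sorted tibble.
#' @export
validate_stage_intervals <- function(intervals) {
  out <- tibble::as_tibble(intervals)
  if (nrow(out) == 0L) return(out)
  bad_stage <- setdiff(unique(out$stage), .stage_codes)
  if (length(bad_stage) > 0L) {
    rlang::abort(sprintf(
      "Unknown stage code(s): %s (expected %s)",
      paste(bad_stage, collapse = ", "), paste(.stage_codes, collapse = ", ")
    ))
  }
  if (any(!is.finite(out$start_s)) || any(!is.finite(out$end_s))) {
    rlang::abort("Interval bounds must be finite numbers.")
  }
  if (any(out$start_s < 0) || any(out$end_s <= out$start_s)) {
    rlang::abort("Intervals must satisfy 0 <= start_s < end_s.")
  }
  out <- dplyr::arrange(out, .data$subject_id, .data$start_s)
  overlap <- out |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      bad = any(.data$start_s[-1] < .data$end_s[-dplyr::n()]) %in% TRUE,
      .groups = "drop"
    )
  if (any(overlap$bad)) {
    rlang::abort(sprintf(
      "Overlapping intervals for subject(s): %s",
      paste(overlap$subject_id[overlap$bad], collapse = ", ")
    ))
  }
  out
}

#' Extract the stage-restricted part of a recording
#'
#' Concatenates, in temporal order, the sample spans whose sleep stage is in
#' `keep`. The default keeps stage 2 and 3 NREM sleep, where breathing is
#' regular and movement noise minimal. Interval bounds map to half-open sample
#' ranges `[round(start_s * rate), round(end_s * rate))`, so adjoining
#' intervals never double-count a sample and the output duration equals the
#' sum of kept interval durations exactly in sample arithmetic.
#'
#' @param signal An [audio_signal()].
#' @param intervals Stage intervals for this recording (tibble as returned by
#'   [parse_stage_annotations()]); `subject_id` is ignored here.
#' @param keep Character vector of stage codes to keep (default `c("N2","N3")`).
#'
#' @return An [audio_signal()] holding the concatenated kept spans.
#' @export
extract_stage_segments <- function(signal, intervals, keep = c("N2", "N3")) {
  stopifnot(inherits(signal, "audio_signal"))
  intervals <- validate_stage_intervals(intervals)
  n <- length(signal$samples)
  kept <- intervals[intervals$stage %in% keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    rlang::abort(sprintf(
      "No intervals with stage in {%s}: nothing to extract.",
      paste(keep, collapse = ", ")
    ))
  }
  if (any(kept$end_s > n / signal$rate_hz + 1e-9)) {
    rlang::abort("Stage intervals extend beyond the end of the recording.")
  }
  kept <- kept[order(kept$start_s), , drop = FALSE]
  idx <- unlist(lapply(seq_len(nrow(kept)), function(i) {
    a <- round(kept$start_s[i] * signal$rate_hz)
    b <- round(kept$end_s[i] * signal$rate_hz)
    if (b > a) seq.int(a + 1L, b) else integer()
  }))
  audio_signal(signal$samples[idx], signal$rate_hz, subject_id = signal$subject_id)
}

#' Slice a signal into Hanning-weighted analysis frames
#'
#' Frames of `window_s` seconds with fractional `overlap` (hop =
#' `window_s * (1 - overlap)`), each multiplied by a periodic Hanning window.
#' The frame count is `floor((N - L) / H) + 1`; a trailing remainder shorter
#' than one window is discarded rather than zero-padded, so per-frame energy
#' statistics stay unbiased.
#'
#' @param signal An [audio_signal()].
#' @param window_s Window length in seconds (default 0.5).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.8, i.e. 0.1 s hop).
#'
#' @return A numeric matrix, one column per frame (rows = window samples),
#'   with attributes `window_s`, `hop_s`, `rate_hz` and `window` (the Hanning
#'   weights applied).
#' @export
frame_signal <- function(signal, window_s = 0.5, overlap = 0.8) {
  stopifnot(inherits(signal, "audio_signal"))
  if (overlap < 0 || overlap >= 1) rlang::abort("`overlap` must be in [0, 1).")
  L <- round(window_s * signal$rate_hz)
  if (L < 2) rlang::abort("Window must span at least 2 samples.")
  H <- round(L * (1 - overlap))
  if (H < 1) rlang::abort("Hop shorter than one sample; reduce `overlap`.")
  N <- length(signal$samples)
  if (N < L) rlang::abort("Signal shorter than one analysis window.")
  n_frames <- (N - L) %/% H + 1L
  w <- hanning_periodic(L)
  starts <- (seq_len(n_frames) - 1L) * H
  frames <- vapply(
    starts,
    function(s) signal$samples[(s + 1L):(s + L)] * w,
    numeric(L)
  )
  frames <- matrix(frames, nrow = L)
  attr(frames, "window_s") <- L / signal$rate_hz
  attr(frames, "hop_s") <- H / signal$rate_hz
  attr(frames, "rate_hz") <- signal$rate_hz
  attr(frames, "window") <- w
  frames
}

# Periodic Hanning window (sums to a constant under 50% overlap-add).
hanning_periodic <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}
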