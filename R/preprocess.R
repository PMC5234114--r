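#' @keywords internal
# STFT of a padded signal: periodic Hanning, hop = nfft/2. The signal is
# pre-padded with one hop of zeros so every original sample sits under exactly
# two windows whose weights sum to 1 (periodic-Hann constant-overlap-add);
# istft_ola() then reconstructs the interior exactly.
stft_frames <- function(x, nfft) {
  hop <- nfft %/% 2L
  n <- length(x)
  xp <- c(numeric(hop), x, numeric(nfft))
  n_frames <- (length(xp) - nfft) %/% hop + 1L
  w <- hanning_periodic(nfft)
  starts <- (seq_len(n_frames) - 1L) * hop
  fm <- vapply(starts, function(s) xp[(s + 1L):(s + nfft)] * w, numeric(nfft))
  stats::mvfft(matrix(fm, nrow = nfft))
}

#' @keywords internal
istft_ola <- function(spec, nfft, n_out) {
  hop <- nfft %/% 2L
  frames <- Re(stats::mvfft(spec, inverse = TRUE)) / nfft
  n_frames <- ncol(frames)
  y <- numeric(hop + n_out + nfft + hop)
  for (j in seq_len(n_frames)) {
    s <- (j - 1L) * hop
    y[(s + 1L):(s + nfft)] <- y[(s + 1L):(s + nfft)] + frames[, j]
  }
  y[(hop + 1L):(hop + n_out)]
}

#' Estimate a stationary-noise magnitude profile
#'
#' Background noise in unattended room recordings (hiss, hum, ventilation) is
#' approximately stationary, while breathing and snoring are intermittent.
#' The profile is therefore estimated from the recording itself: the mean
#' one-sided STFT magnitude spectrum over the `quantile` lowest-energy
#' analysis frames, which excludes frames containing breath sounds.
#'
#' @param signal An [audio_signal()].
#' @param quantile Fraction in (0, 1] of lowest-energy frames to average
#'   (default 0.1).
#' @param nfft FFT size (default 512); analysis uses a periodic Hanning window
#'   with 50% overlap.
#'
#' @return An object of class `noise_profile`: list with `magnitude_spectrum`
#'   (length `nfft/2 + 1`), `nfft`, `rate_hz`.
#' @export
estimate_noise_profile <- function(signal, quantile = 0.1, nfft = 512) {
  stopifnot(inherits(signal, "audio_signal"))
  if (!is.numeric(quantile) || quantile <= 0 || quantile > 1) {
    rlang::abort("`quantile` must be in (0, 1].")
  }
  if (length(signal$samples) <= nfft) {
    rlang::abort("Signal must be longer than `nfft` samples.")
  }
  spec <- stft_frames(signal$samples, nfft)
  mag <- Mod(spec)
  frame_energy <- colSums(mag^2)
  n_keep <- max(1L, ceiling(quantile * length(frame_energy)))
  keep <- order(frame_energy)[seq_len(n_keep)]
  prof <- rowMeans(mag[seq_len(nfft %/% 2L + 1L), keep, drop = FALSE])
  structure(
    list(magnitude_spectrum = prof, nfft = nfft, rate_hz = signal$rate_hz),
    class = "noise_profile"
  )
}

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf(
    "<noise_profile> nfft=%d at %d Hz, mean magnitude %.3g\n",
    x$nfft, as.integer(x$rate_hz), mean(x$magnitude_spectrum)
  ))
  invisible(x)
}

#' Spectral subtraction denoising
#'
#' Boll-style magnitude-domain spectral subtraction: for every STFT frame the
#' noise magnitude profile is subtracted (scaled by `oversubtraction`) and the
#' result floored at `floor` times the noise magnitude to suppress musical
#' noise; the original phase is kept and the signal reconstructed by
#' overlap-add. Output magnitudes never exceed input magnitudes, so the
#' procedure cannot add energy, and output length equals input length.
#'
#' @param signal An [audio_signal()].
#' @param profile A `noise_profile` from [estimate_noise_profile()], estimated
#'   at the same sample rate.
#' @param oversubtraction Noise scaling factor (default 2: mild Berouti-style oversubtraction, which suppresses the Rayleigh-distributed residual that plain mean-magnitude subtraction leaves behind).
#' @param floor Spectral floor as a fraction of the noise magnitude
#'   (default 0.01).
#'
#' @return A denoised [audio_signal()] of identical length.
#' @export
spectral_subtract <- function(signal, profile, oversubtraction = 2.0,
                              floor = 0.01) {
  stopifnot(inherits(signal, "audio_signal"), inherits(profile, "noise_profile"))
  if (profile$rate_hz != signal$rate_hz) {
    rlang::abort("Noise profile and signal sample rates differ.")
  }
  if (oversubtraction < 0) rlang::abort("`oversubtraction` must be >= 0.")
  nfft <- profile$nfft
  n <- length(signal$samples)
  if (n < nfft) rlang::abort("Signal shorter than one FFT frame.")

  # mirror the one-sided profile onto the full two-sided spectrum
  half <- profile$magnitude_spectrum
  noise <- c(half, rev(half[2:(nfft %/% 2L)]))

  spec <- stft_frames(signal$samples, nfft)
  mag <- Mod(spec)
  target <- pmax(mag - oversubtraction * noise, floor * noise)
  target <- pmin(target, mag)  # never amplify a bin
  gain <- ifelse(mag > 0, target / mag, 0)
  audio_signal(istft_ola(spec * gain, nfft, n), signal$rate_hz,
               subject_id = signal$subject_id)
}

#' Denoise a recording with a self-estimated noise profile
#'
#' Convenience wrapper: [estimate_noise_profile()] on the recording itself,
#' then [spectral_subtract()].
#'
#' @inheritParams estimate_noise_profile
#' @inheritParams spectral_subtract
#' @return A denoised [audio_signal()].
#' @export
denoise <- function(signal, quantile = 0.1, nfft = 512,
                    oversubtraction = 2.0, floor = 0.01) {
  prof <- estimate_noise_profile(signal, quantile = quantile, nfft = nfft)
  spectral_subtract(signal, prof, oversubtraction = oversubtraction,
                    floor = floor)
}
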