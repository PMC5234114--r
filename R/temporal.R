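#' Per-frame energy summaries
#'
#' Turns Hanning-weighted frames (from [frame_signal()]) into the three
#' per-frame quantities the level quantizer needs: mean squared-sample energy,
#' the maximum squared sample (the frame's energy peak), and the fill
#' proportion — the fraction of the frame's squared-sample energy carried by
#' samples above a silence floor. Low fill flags "ripple" frames whose energy
#' is an accumulation of many tiny values rather than an actual sound event.
#'
#' @param frames Matrix of weighted frames from [frame_signal()].
#' @param silence_floor Squared-sample threshold below which samples count as
#'   silence for the fill proportion (default 0: every nonzero sample counts).
#'
#' @return A tibble with columns `energy`, `max_sample_energy`,
#'   `fill_proportion`, carrying `hop_s` and `window_s` attributes.
#' @export
compute_frame_energy <- function(frames, silence_floor = 0) {
  stopifnot(is.matrix(frames), ncol(frames) >= 1L)
  sq <- frames^2
  total <- colSums(sq)
  above <- colSums(sq * (sq > silence_floor))
  out <- tibble::tibble(
    energy = total / nrow(frames),
    max_sample_energy = apply(sq, 2L, max),
    fill_proportion = ifelse(total > 0, above / total, 0)
  )
  attr(out, "hop_s") <- attr(frames, "hop_s")
  attr(out, "window_s") <- attr(frames, "window_s")
  out
}

#' Create a dynamic threshold state
#'
#' The two energy thresholds separating silence / ordinary breathing / loud
#' snoring are not fixed: they track the recording's own "most frequent energy
#' peak range" — the modal bin of a histogram of log10 frame peak energies —
#' scaled by predefined ratios, and are smoothed across successive blocks so
#' they adapt slowly to drifting recording conditions.
#'
#' @param ratio_low Multiplier on the modal peak energy giving the
#'   silence/breathing threshold (default 2).
#' @param ratio_high Multiplier giving the breathing/loud-snore threshold
#'   (default 20).
#' @param smoothing Exponential smoothing factor in `[0, 1]` applied to the
#'   modal estimate across blocks (default 0.9; the first block is taken as
#'   is).
#' @param n_bins Histogram bins for the log10 peak-energy mode (default 64).
#'
#' @return An object of class `threshold_state`.
#' @export
threshold_state <- function(ratio_low = 2, ratio_high = 20, smoothing = 0.9,
                            n_bins = 64L) {
  if (ratio_low <= 0 || ratio_high <= ratio_low) {
    rlang::abort("Need 0 < ratio_low < ratio_high.")
  }
  if (smoothing < 0 || smoothing > 1) rlang::abort("`smoothing` must be in [0, 1].")
  structure(
    list(
      mode_estimate = NA_real_, lower_thr = NA_real_, upper_thr = NA_real_,
      ratio_low = ratio_low, ratio_high = ratio_high,
      smoothing = smoothing, n_bins = as.integer(n_bins)
    ),
    class = "threshold_state"
  )
}

#' Update dynamic thresholds from a block of frames
#'
#' Estimates the modal peak energy of the block (modal bin center of a
#' `n_bins`-bin histogram of `log10(max_sample_energy)` over nonzero frames,
#' back-transformed to energy units), blends it with the previous estimate by
#' the smoothing factor, and refreshes `lower_thr = ratio_low * mode` and
#' `upper_thr = ratio_high * mode`. An all-zero block leaves the state
#' unchanged (no mode is defined).
#'
#' @param state A `threshold_state`.
#' @param energies Tibble from [compute_frame_energy()] (or any data frame
#'   with a `max_sample_energy` column) holding one block of frames.
#'
#' @return The updated `threshold_state`.
#' @export
update_thresholds <- function(state, energies) {
  stopifnot(inherits(state, "threshold_state"))
  peaks <- energies$max_sample_energy
  if (length(peaks) == 0L) rlang::abort("Empty energy block.")
  peaks <- peaks[peaks > 0]
  if (length(peaks) == 0L) return(state)

  lp <- log10(peaks)
  if (diff(range(lp)) == 0) {
    block_mode <- 10^lp[1]
  } else {
    breaks <- seq(min(lp), max(lp), length.out = state$n_bins + 1L)
    h <- graphics::hist(lp, breaks = breaks, plot = FALSE)
    block_mode <- 10^h$mids[which.max(h$counts)]
  }
  state$mode_estimate <- if (is.na(state$mode_estimate)) {
    block_mode
  } else {
    state$smoothing * state$mode_estimate + (1 - state$smoothing) * block_mode
  }
  state$lower_thr <- state$ratio_low * state$mode_estimate
  state$upper_thr <- state$ratio_high * state$mode_estimate
  state
}

#' Construct a level series
#'
#' @param levels Integer vector with values in 1..4.
#' @param hop_s Seconds between successive frames.
#' @return An object of class `level_series`.
#' @export
level_series <- function(levels, hop_s) {
  levels <- as.integer(levels)
  if (length(levels) && (min(levels) < 1L || max(levels) > 4L)) {
    rlang::abort("Levels must be integers in 1..4.")
  }
  structure(list(levels = levels, hop_s = hop_s), class = "level_series")
}

#' @export
print.level_series <- function(x, ...) {
  cat(sprintf(
    "<level_series> %d frames at %.3g s hop; level counts: %s\n",
    length(x$levels), x$hop_s,
    paste(sprintf("%d:%d", 1:4, tabulate(x$levels, 4L)), collapse = " ")
  ))
  invisible(x)
}

#' Quantize frame energies into three levels
#'
#' Level 1 (silence) if the frame's peak energy is at or below the lower
#' threshold, or its fill proportion is below `proportion_threshold` (ripple
#' suppression); otherwise level 2 (ordinary breathing, simple snores) if the
#' peak is at or below the upper threshold; otherwise level 3 (loud,
#' obstruction-related snoring). Threshold ties fall to the lower band.
#'
#' @param energies Tibble from [compute_frame_energy()].
#' @param state A `threshold_state` with defined thresholds (see
#'   [update_thresholds()]).
#' @param proportion_threshold Minimum fill proportion for a non-silent label
#'   (default 0.5).
#'
#' @return A [level_series()] with values in 1..3.
#' @export
quantize_levels <- function(energies, state, proportion_threshold = 0.5) {
  stopifnot(inherits(state, "threshold_state"))
  if (is.na(state$lower_thr)) {
    rlang::abort("Thresholds undefined; call update_thresholds() first.")
  }
  lv <- ifelse(
    energies$max_sample_energy <= state$lower_thr |
      energies$fill_proportion < proportion_threshold,
    1L,
    ifelse(energies$max_sample_energy <= state$upper_thr, 2L, 3L)
  )
  level_series(lv, attr(energies, "hop_s") %||% NA_real_)
}

#' Mark OSA-candidate silences as level 4
#'
#' A maximal run of silence (level 1) lasting strictly longer than `min_gap_s`
#' and immediately flanked on both sides by breathing-sound frames (levels 2
#' or 3) is the acoustic signature of an apneic pause: breathing stops, then
#' resumes. Every frame of such a run is relabeled level 4. Runs touching the
#' start or end of the recording keep level 1 (no flank, no evidence that
#' breathing ever stopped or resumed).
#'
#' @param levels A [level_series()] containing only levels 1..3.
#' @param min_gap_s Minimum silent duration in seconds, strict (default 20).
#'
#' @return A [level_series()] with candidate runs relabeled 4; frame count
#'   unchanged.
#' @export
mark_osa_candidates <- function(levels, min_gap_s = 20) {
  stopifnot(inherits(levels, "level_series"))
  lv <- levels$levels
  if (any(lv == 4L)) rlang::abort("Input already contains level 4.")
  if (length(lv) < 1L) return(levels)
  r <- rle(lv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] != 1L) next
    if (i == 1L || i == length(r$values)) next
    if (r$lengths[i] * levels$hop_s <= min_gap_s) next
    if (r$values[i - 1L] %in% c(2L, 3L) && r$values[i + 1L] %in% c(2L, 3L)) {
      lv[starts[i]:ends[i]] <- 4L
    }
  }
  level_series(lv, levels$hop_s)
}

#' Transition probability matrix of a level series
#'
#' Counts all consecutive-frame transitions between the four levels and
#' normalizes globally, so the 16 entries sum to 1 and each entry is the
#' probability of observing that particular transition among all transitions
#' of the night. The diagonal entry (1,1) is then the silence dwell
#' probability and (4,4) the OSA-candidate dwell probability.
#'
#' @param levels A [level_series()] with at least 2 frames.
#' @param normalization `"global"` (default: all 16 entries sum to 1) or
#'   `"row"` (row-stochastic: each occupied row sums to 1, making entries
#'   conditional transition rates instead of joint probabilities).
#' @return An object of class `transition_matrix`: a 4x4 probability matrix
#'   (`probs`) plus the raw counts (`counts`).
#' @export
transition_matrix <- function(levels, normalization = c("global", "row")) {
  stopifnot(inherits(levels, "level_series"))
  normalization <- match.arg(normalization)
  lv <- levels$levels
  if (length(lv) < 2L) rlang::abort("Need at least 2 frames for transitions.")
  counts <- matrix(0L, 4L, 4L, dimnames = list(from = 1:4, to = 1:4))
  idx <- cbind(lv[-length(lv)], lv[-1L])
  for (k in seq_len(nrow(idx))) {
    counts[idx[k, 1L], idx[k, 2L]] <- counts[idx[k, 1L], idx[k, 2L]] + 1L
  }
  probs <- if (normalization == "global") {
    counts / sum(counts)
  } else {
    sweep(counts, 1L, pmax(rowSums(counts), 1L), "/")
  }
  structure(
    list(counts = counts, probs = probs, normalization = normalization),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> global transition probabilities\n")
  print(round(x$probs, 4))
  invisible(x)
}

#' Flatten a transition matrix into the 16 temporal features
#'
#' Row-major order, named `t_(i x j)` for the transition from level i to
#' level j, matching the field's "(1 x 1)", "(3 x 4)", "(4 x 1)" notation.
#'
#' @param tm A `transition_matrix`.
#' @return A named numeric vector of length 16.
#' @export
temporal_feature_vector <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  v <- as.numeric(t(tm$probs))  # row-major
  names(v) <- as.character(outer(
    1:4, 1:4, function(i, j) sprintf("t_(%d x %d)", i, j)
  ) |> t())
  v
}

#' Full time-domain feature pipeline
#'
#' Frames the signal (0.5 s Hanning windows, 80% overlap), computes frame
#' energies, runs the dynamic-threshold three-level quantization block by
#' block (thresholds updated once per `block_s` of audio), relabels
#' OSA-candidate silences as level 4, and returns the 16 transition
#' probability features.
#'
#' @param signal An [audio_signal()].
#' @param window_s,overlap Framing parameters (defaults 0.5 s, 0.8).
#' @param block_s Threshold-update block length in seconds (default 60).
#' @param ratio_low,ratio_high,smoothing Threshold parameters, see
#'   [threshold_state()].
#' @param proportion_threshold Fill-proportion cutoff (default 0.5).
#' @param min_gap_s OSA-candidate minimum silence, strict (default 20).
#' @param normalization Transition-matrix normalization, `"global"` or
#'   `"row"` (see [transition_matrix()]).
#' @param silence_floor_frac Fill-proportion silence floor as a fraction of
#'   the current lower threshold (default 0.25: high enough that a lone noise transient in an otherwise silent frame leaves its energy fill below the 50% proportion rule, which is what suppresses ripple frames).
#'
#' @return An object of class `osa_temporal`: list with `features` (named
#'   16-vector), `levels` (the final [level_series()]), `tm` (the
#'   `transition_matrix`) and `thresholds` (per-block tibble).
#' @export
temporal_features <- function(signal, window_s = 0.5, overlap = 0.8,
                              block_s = 60, ratio_low = 2, ratio_high = 20,
                              smoothing = 0.9, proportion_threshold = 0.5,
                              min_gap_s = 20, silence_floor_frac = 0.25,
                              normalization = "global") {
  frames <- frame_signal(signal, window_s = window_s, overlap = overlap)
  hop_s <- attr(frames, "hop_s")
  e <- compute_frame_energy(frames)
  n <- nrow(e)
  per_block <- max(1L, round(block_s / hop_s))
  block_id <- (seq_len(n) - 1L) %/% per_block

  state <- threshold_state(ratio_low = ratio_low, ratio_high = ratio_high,
                           smoothing = smoothing)
  lv <- integer(n)
  thr_log <- list()
  for (b in unique(block_id)) {
    sel <- which(block_id == b)
    state <- update_thresholds(state, e[sel, , drop = FALSE])
    if (is.na(state$lower_thr)) {
      lv[sel] <- 1L  # silent block before any mode was ever seen
      next
    }
    eb <- compute_frame_energy(frames[, sel, drop = FALSE],
                               silence_floor = silence_floor_frac * state$lower_thr)
    attr(eb, "hop_s") <- hop_s
    lv[sel] <- quantize_levels(eb, state,
                               proportion_threshold = proportion_threshold)$levels
    thr_log[[length(thr_log) + 1L]] <- tibble::tibble(
      block = b, lower_thr = state$lower_thr, upper_thr = state$upper_thr,
      mode_estimate = state$mode_estimate
    )
  }
  levels <- mark_osa_candidates(level_series(lv, hop_s), min_gap_s = min_gap_s)
  tm <- transition_matrix(levels, normalization = normalization)
  structure(
    list(
      features = temporal_feature_vector(tm),
      levels = levels, tm = tm,
      thresholds = dplyr::bind_rows(thr_log)
    ),
    class = "osa_temporal"
  )
}

#' @export
print.osa_temporal <- function(x, ...) {
  cat("<osa_temporal> 16 transition features\n")
  print(round(x$features, 4))
  invisible(x)
}
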