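#' Synthesize one subject's sleep-breathing recording
#'
#' Builds a labeled test signal with the acoustic structure the feature
#' pipeline targets:
#' \itemize{
#'   \item breathing: band-passed (100-1000 Hz) noise amplitude-modulated by
#'     an inhale-burst envelope with period `breath_period_s`, giving the
#'     breath-rate cyclostationarity;
#'   \item snoring: a randomly chosen fraction of breaths carry a harmonic
#'     pulse train at `snore_f0_hz` (6 harmonics, 1/h rolloff) gated by the
#'     same envelope, louder than ordinary breathing;
#'   \item apneas: silent gaps with durations uniform in `apnea_range_s`,
#'     their count Poisson-distributed to match `target_ahi`, separated by at
#'     least two breath cycles of breathing;
#'   \item background: stationary white noise plus 60 Hz hum and harmonics,
#'     mixed at `noise_snr_db` below the breathing RMS, persisting through
#'     the apnea gaps.
#' }
#' The whole recording is annotated as stage N2. Identical spec + seed gives
#' bit-identical audio.
#'
#' @param target_ahi Target apnea rate in events/hour (>= 0).
#' @param duration_min Recording length in minutes (default 10).
#' @param breath_period_s Breath cycle period in seconds (default 4).
#' @param snore_fraction Fraction of breaths that snore (default 0.5).
#' @param snore_f0_hz Snore fundamental frequency (default 80).
#' @param noise_snr_db Breathing-to-background SNR in dB (default 15).
#' @param apnea_range_s Apnea duration range in seconds (default `c(15, 40)`,
#'   straddling the 20 s OSA-candidate threshold so both rule branches occur).
#' @param rate_hz Sample rate (default 8000).
#' @param seed Integer seed.
#' @param subject_id Optional label.
#'
#' @return A list of class `synth_subject`: `signal` ([audio_signal()]),
#'   `stages` (tibble), `events` (tibble: start_s, end_s, kind in
#'   apnea/breath/snore), `ahi` (realized events/hour), `target_ahi`, `seed`.
#' @export
synth_subject <- function(target_ahi, duration_min = 10, breath_period_s = 4,
                          snore_fraction = 0.5, snore_f0_hz = 80,
                          noise_snr_db = 15, apnea_range_s = c(15, 40),
                          rate_hz = 8000, seed = 1L, subject_id = NULL) {
  if (target_ahi < 0) rlang::abort("`target_ahi` must be >= 0.")
  if (duration_min <= 0) rlang::abort("`duration_min` must be > 0.")
  if (snore_fraction < 0 || snore_fraction > 1) {
    rlang::abort("`snore_fraction` must be in [0, 1].")
  }
  T_s <- duration_min * 60
  n <- round(T_s * rate_hz)
  min_spacer_s <- 2 * breath_period_s

  withr::with_seed(as.integer(seed), {
    n_apnea <- if (target_ahi == 0) 0L else stats::rpois(1L, target_ahi * T_s / 3600)
    gap_dur <- if (n_apnea > 0) {
      stats::runif(n_apnea, apnea_range_s[1], apnea_range_s[2])
    } else {
      numeric(0)
    }
    breathing_total <- T_s - sum(gap_dur)
    if (breathing_total < (n_apnea + 1) * min_spacer_s) {
      rlang::abort(sprintf(
        "Infeasible target_ahi %.1f for a %.0f min recording: gaps exceed duration.",
        target_ahi, duration_min
      ))
    }
    # split the breathing time into n_apnea + 1 chunks, each >= the spacer
    u <- stats::runif(n_apnea + 1L)
    free <- breathing_total - (n_apnea + 1L) * min_spacer_s
    chunks <- min_spacer_s + free * u / sum(u)
    gap_start <- cumsum(chunks)[seq_len(n_apnea)] +
      c(0, cumsum(gap_dur))[seq_len(n_apnea)]
    gap_end <- gap_start + gap_dur

    t <- (seq_len(n) - 1) / rate_hz
    phase <- (t %% breath_period_s) / breath_period_s
    duty <- 0.4
    env <- ifelse(phase < duty, sin(pi * phase / duty)^2, 0) + 0.03

    # per-cycle snore flags
    cycle <- floor(t / breath_period_s)
    n_cycles <- max(cycle) + 1L
    snoring <- stats::runif(n_cycles) < snore_fraction

    bp <- signal::butter(4, c(100, 1000) / (rate_hz / 2), type = "pass")
    carrier <- as.numeric(signal::filter(bp, stats::rnorm(n)))
    breath <- env * carrier

    f0 <- snore_f0_hz
    harm <- numeric(n)
    ph <- stats::runif(6, 0, 2 * pi)
    for (h in 1:6) {
      harm <- harm + sin(2 * pi * h * f0 * t + ph[h]) / h
    }
    snore_gain <- 2.5 * snoring[cycle + 1L]
    snore <- (env - 0.03) * harm * snore_gain  # gated by the burst only

    x <- breath + snore

    in_gap <- rep(FALSE, n)
    for (g in seq_len(n_apnea)) {
      a <- max(1L, round(gap_start[g] * rate_hz) + 1L)
      b <- min(n, round(gap_end[g] * rate_hz))
      in_gap[a:b] <- TRUE
    }
    x[in_gap] <- 0

    rms_breath <- sqrt(mean(x[!in_gap]^2))
    noise_rms <- rms_breath / 10^(noise_snr_db / 20)
    hum <- 0.25 * sin(2 * pi * 60 * t) + 0.1 * sin(2 * pi * 120 * t) +
      0.05 * sin(2 * pi * 180 * t)
    bg <- stats::rnorm(n) + hum
    bg <- bg * noise_rms / sqrt(mean(bg^2))
    x <- x + bg
    x <- 0.9 * x / max(abs(x))

    cyc_start <- (seq_len(n_cycles) - 1) * breath_period_s
    breath_events <- tibble::tibble(
      start_s = cyc_start,
      end_s = pmin(cyc_start + breath_period_s, T_s),
      kind = ifelse(snoring, "snore", "breath")
    )
    # drop breath events swallowed by an apnea gap
    overlaps_gap <- function(s, e) {
      if (n_apnea == 0L) return(rep(FALSE, length(s)))
      vapply(seq_along(s), function(i) {
        any(s[i] >= gap_start - 1e-9 & e[i] <= gap_end + 1e-9)
      }, logical(1))
    }
    breath_events <- breath_events[
      !overlaps_gap(breath_events$start_s, breath_events$end_s), ]
    events <- dplyr::bind_rows(
      tibble::tibble(start_s = gap_start, end_s = gap_end, kind = "apnea"),
      breath_events
    ) |> dplyr::arrange(.data$start_s)

    structure(
      list(
        signal = audio_signal(x, rate_hz, subject_id = subject_id),
        stages = tibble::tibble(
          subject_id = subject_id %||% "s1", start_s = 0, end_s = T_s,
          stage = "N2"
        ),
        events = events,
        ahi = n_apnea / (T_s / 3600),
        target_ahi = target_ahi,
        seed = as.integer(seed)
      ),
      class = "synth_subject"
    )
  })
}

#' @export
print.synth_subject <- function(x, ...) {
  cat(sprintf(
    "<synth_subject> %s%.1f min, realized AHI %.1f (%d apneas)\n",
    if (is.null(x$signal$subject_id)) "" else paste0(x$signal$subject_id, ": "),
    duration_s(x$signal) / 60, x$ahi, sum(x$events$kind == "apnea")
  ))
  invisible(x)
}

.class_bands <- list(
  normal = c(0, 5), mild = c(5, 15), moderate = c(15, 30), severe = c(30, 60)
)

#' Generate a labeled synthetic cohort
#'
#' `n_per_class` subjects per severity class. Each subject's target AHI is
#' drawn uniformly within its class band (normal \[0,5), mild \[5,15),
#' moderate \[15,30), severe \[30,60\]); because the realized event count is
#' Poisson, a draw is regenerated (with a derived seed) until the realized
#' AHI actually falls in the intended class, so every label satisfies
#' `ahi_to_severity(ahi)`. Deterministic under `seed`.
#'
#' Because the realized AHI is quantized to multiples of `60 / duration_min`
#' events/hour, recordings shorter than about 5 minutes cannot land in the
#' mild band at all; use durations of 5 minutes or more.
#'
#' @param n_per_class Subjects per severity class (default 5).
#' @param duration_min Recording length per subject in minutes (default 10).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [synth_subject()].
#'
#' @return An object of class `osa_cohort`: `subjects` (list of
#'   `synth_subject`) and `truth` (tibble: subject_id, ahi, severity,
#'   apnea_count).
#' @export
generate_cohort <- function(n_per_class = 5, duration_min = 10, seed = 1L, ...) {
  if (n_per_class < 1) rlang::abort("`n_per_class` must be >= 1.")
  seed <- as.integer(seed)
  subjects <- list()
  truth <- list()
  i <- 0L
  for (cls in names(.class_bands)) {
    band <- .class_bands[[cls]]
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      sid <- sprintf("s%03d", i)
      sub <- NULL
      for (attempt in 1:100) {
        sub_seed <- (abs(seed) * 1009L + i * 97L + attempt) %% 2147483647L
        target <- withr::with_seed(sub_seed, stats::runif(1, band[1], band[2]))
        cand <- tryCatch(
          synth_subject(target, duration_min = duration_min,
                        seed = sub_seed + 1L, subject_id = sid, ...),
          error = function(e) NULL
        )
        if (!is.null(cand) &&
            as.character(ahi_to_severity(cand$ahi)) == cls) {
          sub <- cand
          break
        }
      }
      if (is.null(sub)) {
        rlang::abort(sprintf(
          "Could not realize a %s-class subject in 100 attempts.", cls
        ))
      }
      subjects[[sid]] <- sub
      truth[[sid]] <- tibble::tibble(
        subject_id = sid, ahi = sub$ahi, severity = cls,
        apnea_count = sum(sub$events$kind == "apnea")
      )
    }
  }
  structure(
    list(subjects = subjects, truth = dplyr::bind_rows(truth)),
    class = "osa_cohort"
  )
}

#' @export
print.osa_cohort <- function(x, ...) {
  cat(sprintf("<osa_cohort> %d subjects\n", length(x$subjects)))
  print(dplyr::count(x$truth, .data$severity))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' WAV per subject, one combined stage-annotation CSV, and a truth table CSV
#' (`subject_id, ahi, severity, apnea_count`).
#'
#' @param cohort An `osa_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "osa_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  for (sid in names(cohort$subjects)) {
    sub <- cohort$subjects[[sid]]
    write_wav(sub$signal, file.path(dir, paste0(sid, ".wav")))
    stages[[sid]] <- sub$stages
  }
  utils::write.csv(dplyr::bind_rows(stages), file.path(dir, "stages.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
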