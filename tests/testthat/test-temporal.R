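make_energies <- function(max_e, fill = 1, hop_s = 0.1) {
  out <- tibble::tibble(
    energy = max_e / 8, max_sample_energy = max_e,
    fill_proportion = rep_len(fill, length(max_e))
  )
  attr(out, "hop_s") <- hop_s
  out
}

thr_fixed <- function(lower, upper) {
  st <- threshold_state()
  st$mode_estimate <- lower / st$ratio_low
  st$lower_thr <- lower
  st$upper_thr <- upper
  st
}

test_that("frame energy matches closed forms", {
  # all-zero frames
  z <- frame_signal(audio_signal(numeric(8000)))
  ez <- compute_frame_energy(z)
  expect_true(all(ez$energy == 0))
  expect_true(all(ez$fill_proportion == 0))

  # unit DC input: every frame energy = mean(w^2) for the Hanning window
  d <- frame_signal(audio_signal(rep(1, 16000)))
  ed <- compute_frame_energy(d)
  w <- osasev:::hanning_periodic(4000)
  expect_equal(ed$energy, rep(mean(w^2), ncol(d)), tolerance = 1e-12)

  # a single spike in a silent frame: all energy above any sub-spike floor
  x <- numeric(4000)
  x[2000] <- 0.5
  fr <- frame_signal(audio_signal(x), window_s = 0.5, overlap = 0)
  es <- compute_frame_energy(fr, silence_floor = 1e-6)
  expect_equal(es$fill_proportion[1], 1)
  expect_equal(es$max_sample_energy[1], (0.5 * w[2000])^2)
})

test_that("threshold updates follow the smoothing recurrence", {
  st <- threshold_state(smoothing = 0.7)
  # first block: mode taken as is; thresholds at the predefined ratios
  e1 <- make_energies(rep(1e-3, 100))
  st1 <- update_thresholds(st, e1)
  expect_equal(st1$mode_estimate, 1e-3, tolerance = 1e-9)
  expect_equal(st1$lower_thr, st$ratio_low * st1$mode_estimate)
  expect_equal(st1$upper_thr, st$ratio_high * st1$mode_estimate)

  # identical block: fixed point
  st2 <- update_thresholds(st1, e1)
  expect_equal(st2$mode_estimate, st1$mode_estimate)

  # different modal energy blends by the smoothing factor
  e2 <- make_energies(rep(5e-3, 100))
  st3 <- update_thresholds(st1, e2)
  expect_equal(st3$mode_estimate, 0.7 * 1e-3 + 0.3 * 5e-3, tolerance = 1e-9)

  # an all-zero block leaves the state untouched
  st4 <- update_thresholds(st3, make_energies(rep(0, 50)))
  expect_identical(st4, st3)
})

test_that("level quantization implements the two-threshold + fill rule", {
  st <- thr_fixed(1, 10)
  cases <- tibble::tribble(
    ~max_e, ~fill, ~level,
    0.5,    0.9,   1L,  # below lower threshold: silence
    5,      0.8,   2L,  # between thresholds, filled: breathing
    5,      0.3,   1L,  # above lower threshold but low fill: ripple -> silence
    50,     0.9,   3L,  # above upper threshold: loud snore
    1,      0.9,   1L,  # tie at lower threshold falls to silence
    10,     0.9,   2L   # tie at upper threshold falls to breathing
  )
  e <- make_energies(cases$max_e, cases$fill)
  expect_identical(quantize_levels(e, st)$levels, cases$level)
})

test_that("quantization is monotone in peak energy at adequate fill", {
  st <- thr_fixed(1, 10)
  withr::with_seed(8, {
    for (rep in 1:50) {
      e1 <- runif(1, 0, 20)
      e2 <- e1 + runif(1, 0, 20)
      l1 <- quantize_levels(make_energies(e1, 0.9), st)$levels
      l2 <- quantize_levels(make_energies(e2, 0.9), st)$levels
      expect_gte(l2, l1)
    }
  })
})

test_that("OSA-candidate relabeling needs > 20 s and both flanks", {
  hop <- 0.1
  # 251 frames of silence (25.1 s) between breathing: relabeled in full
  lv <- level_series(c(2L, rep(1L, 251), 3L), hop)
  out <- mark_osa_candidates(lv)
  expect_identical(out$levels, c(2L, rep(4L, 251), 3L))
  expect_length(out$levels, length(lv$levels))

  # exactly 20.0 s: strict inequality, unchanged
  lv20 <- level_series(c(2L, rep(1L, 200), 3L), hop)
  expect_identical(mark_osa_candidates(lv20)$levels, lv20$levels)

  # a long silence at the recording start has no left flank
  lv_edge <- level_series(c(rep(1L, 250), 2L, 3L), hop)
  expect_identical(mark_osa_candidates(lv_edge)$levels, lv_edge$levels)

  # relabeling only ever turns level 1 into level 4
  expect_true(all(lv$levels[out$levels == 4L] == 1L))

  expect_error(mark_osa_candidates(out), "level 4")
})

test_that("transition matrix equals the brute-force pair-count oracle", {
  expect_error(transition_matrix(level_series(1L, 0.1)), "at least 2")

  tm <- transition_matrix(level_series(c(1L, 1L, 1L), 0.1))
  expect_equal(tm$probs[1, 1], 1)
  expect_equal(sum(tm$probs), 1)

  tm2 <- transition_matrix(level_series(c(1L, 2L, 3L, 4L, 1L), 0.1))
  expect_equal(tm2$probs[1, 2], 0.25)
  expect_equal(tm2$probs[2, 3], 0.25)
  expect_equal(tm2$probs[3, 4], 0.25)
  expect_equal(tm2$probs[4, 1], 0.25)

  withr::with_seed(23, {
    for (rep in 1:200) {
      lv <- sample(1:4, sample(2:60, 1), replace = TRUE)
      got <- transition_matrix(level_series(lv, 0.1))$probs
      expect_equal(unname(unclass(got)), oracle_transitions(lv))
      expect_equal(sum(got), 1, tolerance = 1e-12)
    }
  })
})

test_that("row-stochastic normalization makes occupied rows sum to 1", {
  lv <- level_series(c(1L, 1L, 2L, 1L, 2L, 2L, 3L), 0.1)
  tm <- transition_matrix(lv, normalization = "row")
  occupied <- rowSums(tm$counts) > 0
  expect_true(all(abs(rowSums(tm$probs)[occupied] - 1) < 1e-12))
  expect_true(all(tm$probs[!occupied, ] == 0))
})

test_that("the 16 temporal features are named by ordered level pairs", {
  tm <- transition_matrix(level_series(rep(c(1L, 2L), 10), 0.1))
  v <- temporal_feature_vector(tm)
  expect_length(v, 16)
  expect_identical(
    names(v),
    as.character(t(outer(1:4, 1:4, function(i, j) sprintf("t_(%d x %d)", i, j))))
  )
  expect_equal(v[["t_(1 x 2)"]], tm$probs[1, 2])
  expect_equal(sum(v), 1, tolerance = 1e-12)
})
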