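# small signal builders shared across test files

white_signal <- function(seconds, rate = 8000, sd = 1, seed = NULL) {
  gen <- function() osasev::audio_signal(stats::rnorm(seconds * rate, sd = sd), rate)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# amplitude-modulated noise: classic second-order cyclostationary test signal
am_signal <- function(seconds = 60, period_s = 4, rate = 8000, seed = 1) {
  withr::with_seed(seed, {
    t <- (0:(seconds * rate - 1)) / rate
    osasev::audio_signal((1 + cos(2 * pi * t / period_s)) * stats::rnorm(length(t)),
                         rate)
  })
}

# moment statistics computed the long way, as an independent oracle
oracle_stats <- function(v) {
  m <- sum(v) / length(v)
  ctr <- v - m
  m2 <- sum(ctr^2) / length(v)
  m3 <- sum(ctr^3) / length(v)
  m4 <- sum(ctr^4) / length(v)
  c(
    max = max(v), min = min(v), median = sort(v)[ceiling(length(v) / 2)] / 2 +
      sort(v)[length(v) %/% 2 + 1] / 2,
    sd = sqrt(sum(ctr^2) / (length(v) - 1)),
    var = sum(ctr^2) / (length(v) - 1),
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0
  )
}

# brute-force transition-pair counter (oracle for transition_matrix)
oracle_transitions <- function(lv) {
  counts <- matrix(0, 4, 4)
  for (i in seq_len(length(lv) - 1)) {
    counts[lv[i], lv[i + 1]] <- counts[lv[i], lv[i + 1]] + 1
  }
  counts / sum(counts)
}

# exhaustive Otsu: quantize to the histogram's bin midpoints, then try every
# bin boundary and maximize the between-class variance from first principles
oracle_otsu <- function(v, n_bins = 256) {
  breaks <- seq(min(v), max(v), length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1), n_bins)
  q <- mids[bin]
  best <- -Inf
  best_thr <- NA_real_
  for (i in 2:n_bins) {
    b <- breaks[i]
    lo <- q[bin < i]
    hi <- q[bin >= i]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-15) {
      best <- sb
      best_thr <- b
    }
  }
  best_thr
}
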