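#' Cyclic spectral density of a 60-second window
#'
#' Estimates the magnitude of the cyclic spectral density S(alpha, f): the
#' two-dimensional Fourier transform of the time-varying (instantaneous)
#' autocorrelation C(t, tau) = x(t + tau/2) x(t - tau/2). A stationary signal
#' concentrates all its mass on the alpha = 0 line; a signal whose statistics
#' repeat periodically — breathing at 0.25 Hz, snoring pulse trains — shows
#' ridges at the corresponding cyclic frequencies alpha.
#'
#' The estimator discretizes C on a grid of `n_alpha` time points (hop
#' `floor(N / n_alpha)` samples, ~67.5 ms for a 60 s window at 8 kHz) and
#' `2 * (n_f - 1) + 1` symmetric lags. At each grid point the lag product is
#' averaged over one hop of samples (boxcar smoothing), a Hanning taper is
#' applied over lags, and FFTs over tau (one-sided, `n_f` bins) and over t
#' (`n_alpha` bins) yield the magnitude grid. The alpha axis keeps all
#' `n_alpha` FFT bins of the real-input transform, so its upper half mirrors
#' the lower half; argmax queries resolve ties toward the lower alpha.
#'
#' @param window An [audio_signal()] segment, nominally 60 s.
#' @param n_f Number of spectral-frequency bins (default 54).
#' @param n_alpha Number of cyclic-frequency bins / time grid points
#'   (default 889).
#'
#' @return An object of class `csd_grid`: `magnitudes` (`n_f x n_alpha`),
#'   `f_grid` (Hz), `alpha_grid` (Hz), `window_s`.
#' @export
cyclic_spectral_density <- function(window, n_f = 54, n_alpha = 889) {
  stopifnot(inherits(window, "audio_signal"))
  x <- window$samples
  rate <- window$rate_hz
  n_lags <- 2L * (n_f - 1L) + 1L   # symmetric lag count (107 under defaults)
  max_lag <- n_f - 1L
  hop <- length(x) %/% n_alpha
  if (hop < 1L || length(x) < n_alpha + 2L * max_lag) {
    rlang::abort(sprintf(
      "Window too short: need >= %d samples for an %d x %d grid.",
      n_alpha + 2L * max_lag, n_f, n_alpha
    ))
  }

  # time grid centers (sample indices, 1-based), mirrored so that center i and
  # center n_alpha + 1 - i sum to N + 1: the grid then maps onto itself under
  # time reversal and |S| of a reversed signal is bit-identical
  n <- length(x)
  h_real <- n / n_alpha
  lower <- seq_len((n_alpha + 1L) %/% 2L)
  c_low <- round((lower - 0.5) * h_real)
  centers <- integer(n_alpha)
  centers[lower] <- c_low
  centers[n_alpha + 1L - lower] <- n + 1L - c_low
  centers <- pmin(pmax(centers, max_lag + 1L), n - max_lag)
  half <- hop %/% 2L

  csum_at <- function(y, c_lo, c_hi) {
    # boxcar mean of y over [c_lo, c_hi] per center, via cumulative sums
    cs <- c(0, cumsum(y))
    (cs[c_hi + 1L] - cs[c_lo]) / (c_hi - c_lo + 1L)
  }
  c_lo <- pmax(centers - half, 1L)
  c_hi <- pmin(centers + half, n)

  # C(t, m) for m = 0..max_lag; even in m, so one side suffices
  Ct <- matrix(0, nrow = n_alpha, ncol = n_f)
  for (m in 0:max_lag) {
    lo <- 1L + m
    hi <- n - m
    y <- numeric(n)
    y[lo:hi] <- x[(lo + m):(hi + m)] * x[(lo - m):(hi - m)]
    Ct[, m + 1L] <- csum_at(y, pmax(c_lo, lo), pmin(c_hi, hi))
  }

  # FFT over tau: real cosine transform of the symmetric lag sequence with a
  # Hanning taper h(m); S_f(t, k) = h0*C0 + sum_m 2 h_m C_m cos(2 pi m k / n_lags)
  taper <- hanning_periodic(n_lags)[(max_lag + 1L):n_lags]  # peak at m = 0
  coef <- c(taper[1L], 2 * taper[-1L])
  m_idx <- 0:max_lag
  k_idx <- 0:(n_f - 1L)
  cosmat <- outer(m_idx, k_idx, function(m, k) cos(2 * pi * m * k / n_lags))
  Sf <- Ct %*% (coef * cosmat)          # n_alpha x n_f, real

  # FFT over t -> cyclic frequency alpha; normalized so alpha = 0 is the mean
  A <- stats::mvfft(Sf) / n_alpha        # n_alpha x n_f, complex
  mags <- t(Mod(A))                      # n_f x n_alpha
  # real input: bins k and n_alpha - k are conjugates, so their magnitudes are
  # analytically equal; average out FFT rounding so the symmetry is exact
  if (n_alpha > 2L) {
    lo <- 2:((n_alpha + 1L) %/% 2L)
    hi <- n_alpha + 2L - lo
    avg <- (mags[, lo, drop = FALSE] + mags[, hi, drop = FALSE]) / 2
    mags[, lo] <- avg
    mags[, hi] <- avg
  }

  t_rate <- rate / hop                   # sampling rate along the t grid
  structure(
    list(
      magnitudes = mags,
      f_grid = k_idx * rate / (2 * n_lags),
      alpha_grid = (seq_len(n_alpha) - 1L) * t_rate / n_alpha,
      window_s = length(x) / rate
    ),
    class = "csd_grid"
  )
}

#' @export
print.csd_grid <- function(x, ...) {
  cat(sprintf(
    "<csd_grid> %d x %d (f x alpha), f <= %.0f Hz, alpha step %.4f Hz\n",
    nrow(x$magnitudes), ncol(x$magnitudes),
    max(x$f_grid), x$alpha_grid[2]
  ))
  invisible(x)
}

#' Cyclic-frequency marginal of a CSD grid
#'
#' Sums the magnitude grid over spectral frequency f, giving the total
#' cyclostationary energy per cyclic frequency alpha. By default only the
#' unique (lower) half of the alpha axis is returned, since the upper half of
#' the real-input transform mirrors it.
#'
#' @param grid A `csd_grid`.
#' @param unique_half Restrict to the non-mirrored alpha range (default TRUE).
#' @return A tibble with columns `alpha` (Hz) and `magnitude`.
#' @export
csd_alpha_marginal <- function(grid, unique_half = TRUE) {
  stopifnot(inherits(grid, "csd_grid"))
  n <- ncol(grid$magnitudes)
  idx <- if (unique_half) seq_len(n %/% 2L + 1L) else seq_len(n)
  tibble::tibble(
    alpha = grid$alpha_grid[idx],
    magnitude = colSums(grid$magnitudes[, idx, drop = FALSE])
  )
}

#' Start a running CSD mean
#'
#' @param n_f,n_alpha Grid dimensions (defaults 54, 889).
#' @param window_s Window length the grids come from (default 60).
#' @return An object of class `running_csd_mean` with `rms` (zeros), `k = 0`.
#' @export
new_running_mean <- function(n_f = 54, n_alpha = 889, window_s = 60) {
  structure(
    list(rms = matrix(0, n_f, n_alpha), k = 0L, window_s = window_s),
    class = "running_csd_mean"
  )
}

#' Update a running CSD mean with one window's grid
#'
#' Incremental (real-time) mean: `rms <- rms + (S - rms) / k`. After k
#' updates, `rms` equals the arithmetic mean of all k grids, so a full night
#' is summarized in one grid without holding every window in memory.
#'
#' @param state A `running_csd_mean`.
#' @param csd A `csd_grid` of matching shape.
#' @return The updated `running_csd_mean`.
#' @export
update_running_mean <- function(state, csd) {
  stopifnot(inherits(state, "running_csd_mean"), inherits(csd, "csd_grid"))
  if (!all(dim(state$rms) == dim(csd$magnitudes))) {
    rlang::abort("CSD grid shape does not match the running-mean state.")
  }
  k <- state$k + 1L
  state$rms <- state$rms + (csd$magnitudes - state$rms) / k
  state$k <- k
  state
}

#' Running-mean CSD of a whole recording
#'
#' Slices the signal into consecutive non-overlapping `window_s` windows,
#' computes each window's CSD and folds it into the running mean. A trailing
#' remainder shorter than one window is dropped.
#'
#' @param signal An [audio_signal()].
#' @param window_s Window length in seconds (default 60).
#' @param n_f,n_alpha Grid dimensions (defaults 54, 889).
#' @return A `running_csd_mean` with `k` = number of whole windows.
#' @export
running_csd <- function(signal, window_s = 60, n_f = 54, n_alpha = 889) {
  stopifnot(inherits(signal, "audio_signal"))
  L <- round(window_s * signal$rate_hz)
  n_win <- length(signal$samples) %/% L
  if (n_win < 1L) rlang::abort("Recording shorter than one CSD window.")
  state <- new_running_mean(n_f, n_alpha, window_s)
  for (k in seq_len(n_win)) {
    seg <- audio_signal(
      signal$samples[((k - 1L) * L + 1L):(k * L)], signal$rate_hz
    )
    state <- update_running_mean(
      state, cyclic_spectral_density(seg, n_f = n_f, n_alpha = n_alpha)
    )
  }
  state
}

#' Otsu threshold masking of a magnitude matrix
#'
#' The mean CSD grid is mostly near-zero background with sparse
#' cyclostationary ridges. Otsu's method — the threshold maximizing the
#' between-class variance of a 256-bin histogram of the entries — separates
#' the two populations; entries below the threshold are zeroed, the shape is
#' preserved. A constant matrix has no two classes to separate and is
#' returned unchanged with `degenerate = TRUE`.
#'
#' @param m Non-negative numeric matrix.
#' @param n_bins Histogram bins (default 256).
#' @return A list: `threshold`, `masked` (same shape), `degenerate`.
#' @export
otsu_mask <- function(m, n_bins = 256L) {
  stopifnot(is.matrix(m) || is.numeric(m))
  v <- as.numeric(m)
  if (any(v < 0)) rlang::abort("Magnitudes must be non-negative.")
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    return(list(threshold = lo, masked = m, degenerate = TRUE))
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_total <- mu[n_bins]
  # between-class variance at every cut after bin i
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_total * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  cut <- which.max(sigma_b)
  threshold <- breaks[cut + 1L]
  masked <- m
  masked[m < threshold] <- 0
  list(threshold = threshold, masked = masked, degenerate = FALSE)
}

#' Fit a shared NMF basis across subjects
#'
#' The transposed mean-CSD grids of all subjects are concatenated column-wise
#' into `V` (`n_alpha` rows, `n_f * n_subjects` columns) and factored as
#' `V ~ W H` by non-negative matrix factorization under the Frobenius (RMS
#' residual) objective with multiplicative updates. Working on the transposed
#' grids puts the cyclic-frequency axis in the rows, so the rank-`rank` basis
#' `W` captures shared cyclostationary patterns of the cohort; each subject's
#' activation matrix is then obtained against this fixed basis with
#' [project_activations()].
#'
#' @param rms_list List of `running_csd_mean` objects (or bare matrices of a
#'   common `n_f x n_alpha` shape), typically Otsu-masked.
#' @param rank Factorization rank (default 45).
#' @param seed Integer seed for the multiplicative-update initialization.
#' @param max_iter,tol Stopping rule: at most `max_iter` iterations or
#'   relative objective change below `tol` (defaults 500, 1e-6).
#'
#' @return An object of class `nmf_basis`: `W` (`n_alpha x rank`), `rank`,
#'   `seed`, `fit_residual` (relative Frobenius residual), `n_f`, `n_alpha`.
#' @export
fit_shared_basis <- function(rms_list, rank = 45, seed = 1L,
                             max_iter = 500L, tol = 1e-6) {
  mats <- lapply(rms_list, function(r) {
    if (inherits(r, "running_csd_mean")) r$rms else as.matrix(r)
  })
  if (length(mats) < 1L) rlang::abort("Need at least one mean-CSD matrix.")
  shp <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) all(dim(m) == shp), logical(1)))) {
    rlang::abort("All mean-CSD matrices must share one shape.")
  }
  if (any(vapply(mats, function(m) any(m < 0), logical(1)))) {
    rlang::abort("Mean-CSD matrices must be non-negative.")
  }
  V <- do.call(cbind, lapply(mats, t))   # n_alpha x (n_f * n_subjects)
  if (rank > min(dim(V))) {
    rlang::abort(sprintf(
      "rank (%d) exceeds min dimension of the merged matrix (%d).",
      rank, min(dim(V))
    ))
  }
  fit <- nmf_mu(V, rank = rank, seed = seed, max_iter = max_iter, tol = tol)
  structure(
    list(
      W = fit$W, rank = as.integer(rank), seed = as.integer(seed),
      fit_residual = fit$residual,
      objective = fit$objective, n_f = shp[1L], n_alpha = shp[2L]
    ),
    class = "nmf_basis"
  )
}

#' @export
print.nmf_basis <- function(x, ...) {
  cat(sprintf(
    "<nmf_basis> rank %d over %d alpha bins (grid %d x %d), rel. residual %.3g\n",
    x$rank, nrow(x$W), x$n_f, x$n_alpha, x$fit_residual
  ))
  invisible(x)
}

#' Project a subject's mean CSD onto a fixed basis
#'
#' Solves for the non-negative activation matrix `H` minimizing
#' `||t(rms) - W H||_F` with the shared basis `W` held fixed (H-only
#' multiplicative updates). `H` is the subject's `rank x n_f`
#' cyclostationarity fingerprint.
#'
#' @param basis An `nmf_basis`.
#' @param rms A `running_csd_mean` (or matrix) with the basis's grid shape.
#' @param max_iter,tol Stopping rule (defaults 500, 1e-6).
#' @return A non-negative `rank x n_f` matrix of class `activation_matrix`.
#' @export
project_activations <- function(basis, rms, max_iter = 500L, tol = 1e-6) {
  stopifnot(inherits(basis, "nmf_basis"))
  m <- if (inherits(rms, "running_csd_mean")) rms$rms else as.matrix(rms)
  if (nrow(m) != basis$n_f || ncol(m) != basis$n_alpha) {
    rlang::abort(sprintf(
      "Grid shape %d x %d does not match the basis grid %d x %d.",
      nrow(m), ncol(m), basis$n_f, basis$n_alpha
    ))
  }
  fit <- nmf_mu(t(m), rank = basis$rank, seed = basis$seed,
                fixed_W = basis$W, max_iter = max_iter, tol = tol)
  structure(fit$H, class = c("activation_matrix", "matrix"))
}

# moment statistics with the package's fixed conventions:
# sd/var use n-1; skewness g1 = m3 / m2^(3/2); kurtosis = m4 / m2^2
# (Pearson, non-excess); a constant vector gets skewness = kurtosis = 0.
.seven_stats <- function(v, include_mean = FALSE) {
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  if (m2 > 0) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  } else {
    skew <- 0
    kurt <- 0
  }
  out <- c(
    max = max(v), min = min(v), median = stats::median(v),
    sd = stats::sd(v), var = stats::var(v),
    kurtosis = kurt, skewness = skew
  )
  if (include_mean) out <- c(out, mean = m)
  out
}

#' Summarize an activation matrix into the cyclostationary feature vector
#'
#' For each of the `rank` rows (base alpha, observing the spectral f axis)
#' and each of the `n_f` columns (base f, observing the dimension-reduced
#' alpha axis) computes seven statistics — maximum, minimum, median, standard
#' deviation, variance, kurtosis, skewness — giving `rank * 7 + n_f * 7`
#' features (693 under the default 45 x 54 shape). Names follow
#' `c_<base>_<obs>_<statistic>_<sequence>`, so e.g. `c_alpha_f_max_40` is the
#' maximum over f observed at the 40th dimension-reduced alpha index.
#'
#' Constant rows/columns have zero variance; their skewness and kurtosis are
#' defined as 0.
#'
#' @param H An `activation_matrix` (or any non-negative matrix).
#' @param include_mean Also emit the mean as an eighth statistic per row and
#'   column (default FALSE, keeping the canonical seven-statistic set).
#' @return A named numeric vector (length 693 under defaults).
#' @export
summarize_statistics <- function(H, include_mean = FALSE) {
  H <- unclass(H)
  stopifnot(is.matrix(H))
  stat_names <- c("max", "min", "median", "sd", "var", "kurtosis", "skewness")
  if (include_mean) stat_names <- c(stat_names, "mean")
  rows <- lapply(seq_len(nrow(H)), function(i) {
    s <- .seven_stats(H[i, ], include_mean)
    stats::setNames(s, sprintf("c_alpha_f_%s_%d", stat_names, i))
  })
  cols <- lapply(seq_len(ncol(H)), function(j) {
    s <- .seven_stats(H[, j], include_mean)
    stats::setNames(s, sprintf("c_f_alpha_%s_%d", stat_names, j))
  })
  unlist(c(rows, cols))
}

#' Full cyclostationary feature pipeline for one subject
#'
#' Running-mean CSD over 60 s windows, Otsu masking, projection onto a shared
#' basis, and the statistical summary.
#'
#' @param rms A `running_csd_mean` for the subject (see [running_csd()]).
#' @param basis A shared `nmf_basis` (see [fit_shared_basis()]).
#' @param apply_otsu Mask the grid before projection (default TRUE).
#' @return Named feature vector from [summarize_statistics()].
#' @export
cyclo_features <- function(rms, basis, apply_otsu = TRUE) {
  m <- if (inherits(rms, "running_csd_mean")) rms$rms else as.matrix(rms)
  if (apply_otsu) m <- otsu_mask(m)$masked
  H <- project_activations(basis, m)
  summarize_statistics(H)
}

#' Persist / restore a fitted NMF basis
#'
#' Plain-text (RDS-free) storage: a JSON header with shape, rank and seed
#' followed by the basis matrix, so a cohort's basis can be reused later.
#'
#' @param basis An `nmf_basis`.
#' @param path Output file path.
#' @return `path` invisibly (`write_basis`); an `nmf_basis` (`read_basis`).
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "nmf_basis"))
  payload <- list(
    rank = basis$rank, seed = basis$seed, fit_residual = basis$fit_residual,
    n_f = basis$n_f, n_alpha = basis$n_alpha, W = basis$W
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      W = matrix(p$W, ncol = p$rank), rank = p$rank, seed = p$seed,
      fit_residual = p$fit_residual, n_f = p$n_f, n_alpha = p$n_alpha
    ),
    class = "nmf_basis"
  )
}
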