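test_that("CSD grid has the documented shape and zero maps to zero", {
  z <- audio_signal(numeric(60 * 8000))
  g <- cyclic_spectral_density(z)
  expect_identical(dim(g$magnitudes), c(54L, 889L))
  expect_true(all(g$magnitudes == 0))
  expect_error(cyclic_spectral_density(audio_signal(numeric(500))), "too short")
})

test_that("stationary white noise has no cyclic components", {
  ratios <- vapply(1:3, function(seed) {
    g <- cyclic_spectral_density(white_signal(60, seed = seed))
    mean(g$magnitudes[, -1]) / mean(g$magnitudes[, 1])
  }, numeric(1))
  expect_true(all(ratios <= 0.1))
})

test_that("AM noise puts its largest cyclic peak at the modulation rate", {
  for (seed in 1:3) {
    g <- cyclic_spectral_density(am_signal(60, period_s = 4, seed = seed))
    m <- csd_alpha_marginal(g)
    am_bin <- which.max(m$magnitude[-1]) + 1L
    expect_identical(am_bin, which.min(abs(m$alpha - 0.25)))
  }
})

test_that("time reversal leaves the CSD magnitude grid unchanged", {
  s <- am_signal(60, seed = 6)
  g1 <- cyclic_spectral_density(s)
  g2 <- cyclic_spectral_density(audio_signal(rev(s$samples), s$rate_hz))
  expect_equal(g1$magnitudes, g2$magnitudes, tolerance = 1e-6)
})

test_that("running mean equals the batch mean", {
  st <- new_running_mean(3, 5)
  expect_identical(st$k, 0L)
  grids <- withr::with_seed(13, {
    lapply(1:7, function(i) {
      structure(
        list(magnitudes = matrix(runif(15), 3, 5), f_grid = 1:3,
             alpha_grid = 1:5, window_s = 60),
        class = "csd_grid"
      )
    })
  })
  for (g in grids) st <- update_running_mean(st, g)
  batch <- Reduce(`+`, lapply(grids, `[[`, "magnitudes")) / 7
  expect_identical(st$k, 7L)
  expect_lt(max(abs(st$rms - batch)), 1e-10)

  # first window copies, constant input is a fixed point
  s1 <- update_running_mean(new_running_mean(3, 5), grids[[1]])
  expect_equal(s1$rms, grids[[1]]$magnitudes)
  s2 <- update_running_mean(s1, grids[[1]])
  expect_equal(s2$rms, grids[[1]]$magnitudes)

  bad <- grids[[1]]
  bad$magnitudes <- matrix(0, 2, 2)
  expect_error(update_running_mean(st, bad), "shape")
})

test_that("Otsu threshold matches exhaustive between-class variance search", {
  # two-point mass: all zeros stay zero, all tens survive
  m <- matrix(c(rep(0, 900), rep(10, 100)), 50, 20)
  r <- otsu_mask(m)
  expect_gt(r$threshold, 0)
  expect_lte(r$threshold, 10)
  expect_true(all(r$masked[m == 10] == 10))
  expect_true(all(r$masked[m == 0] == 0))

  # bimodal mixture: threshold lands between the modes
  withr::with_seed(19, {
    v <- c(rnorm(600, 1, 0.5), rnorm(400, 8, 0.5))
    v <- pmax(v, 0)
    mm <- matrix(v, 40, 25)
    rb <- otsu_mask(mm)
    expect_gt(rb$threshold, 1)
    expect_lt(rb$threshold, 8)
    expect_equal(rb$threshold, oracle_otsu(v))
  })

  # random matrices against the exhaustive oracle
  withr::with_seed(29, {
    for (rep in 1:10) {
      v <- rgamma(500, shape = 0.5)
      expect_equal(otsu_mask(matrix(v, 20, 25))$threshold, oracle_otsu(v))
    }
  })

  const <- otsu_mask(matrix(3, 4, 4))
  expect_true(const$degenerate)
  expect_identical(const$masked, matrix(3, 4, 4))
})

test_that("NMF recovers constructed low-rank structure", {
  withr::with_seed(41, {
    W0 <- matrix(runif(80 * 5), 80)
    H0 <- matrix(runif(5 * 60), 5)
    f <- nmf_mu(W0 %*% H0, rank = 5, seed = 2)
    expect_lte(f$residual, 1e-2)
    expect_true(all(f$W >= 0))
    expect_true(all(f$H >= 0))
    expect_true(all(diff(f$objective) <= 1e-8))

    # exact rank-1 case
    v1 <- runif(30)
    v2 <- runif(40)
    f1 <- nmf_mu(outer(v1, v2), rank = 1, seed = 3, tol = 1e-14,
                 max_iter = 3000)
    expect_lte(f1$residual, 1e-6)
  })
  expect_error(nmf_mu(matrix(-1, 2, 2), 1), "non-negative")
  expect_error(nmf_mu(matrix(1, 4, 4), 10), "rank")
})

test_that("NMF is reproducible under a fixed seed", {
  V <- withr::with_seed(7, matrix(runif(200), 20, 10))
  f1 <- nmf_mu(V, rank = 3, seed = 99)
  f2 <- nmf_mu(V, rank = 3, seed = 99)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
})

test_that("shared basis + projection recover constructed activations", {
  withr::with_seed(53, {
    W0 <- matrix(runif(889 * 6), 889)
    H0 <- matrix(runif(6 * 54), 6)
    V <- W0 %*% H0     # n_alpha x n_f, i.e. one subject's transposed grid
    basis <- structure(
      list(W = W0, rank = 6L, seed = 1L, fit_residual = 0,
           n_f = 54L, n_alpha = 889L),
      class = "nmf_basis"
    )
    H <- project_activations(basis, t(V))
    expect_true(all(H >= 0))
    expect_lte(
      sqrt(sum((V - W0 %*% H)^2)) / sqrt(sum(V^2)), 1e-2
    )

    # zero input projects to zero activations
    H0z <- project_activations(basis, matrix(0, 54, 889))
    expect_lt(max(H0z), 1e-8)

    expect_error(project_activations(basis, matrix(0, 10, 10)), "shape")
  })
})

test_that("fit_shared_basis validates input and reports its residual", {
  withr::with_seed(61, {
    mats <- lapply(1:3, function(i) matrix(runif(54 * 889), 54, 889))
    b <- fit_shared_basis(mats, rank = 4, seed = 5, max_iter = 60)
    expect_identical(dim(b$W), c(889L, 4L))
    expect_true(all(b$W >= 0))
    expect_true(b$fit_residual >= 0 && b$fit_residual <= 1)
    expect_error(fit_shared_basis(list(matrix(-1, 2, 2))), "non-negative")
    expect_error(fit_shared_basis(mats, rank = 10000), "rank")
  })
})

test_that("statistical summary emits 693 correctly named features", {
  H <- withr::with_seed(71, matrix(runif(45 * 54), 45, 54))
  v <- summarize_statistics(H)
  expect_length(v, 693)
  expect_identical(anyDuplicated(names(v)), 0L)
  expect_identical(sum(startsWith(names(v), "c_alpha_f_")), 45L * 7L)
  expect_identical(sum(startsWith(names(v), "c_f_alpha_")), 54L * 7L)

  # row statistics match the textbook moment formulas
  r <- H[10, ]
  expect_equal(v[["c_alpha_f_max_10"]], max(r))
  o <- oracle_stats(r)
  for (s in names(o)) {
    expect_equal(v[[sprintf("c_alpha_f_%s_10", s)]], unname(o[[s]]),
                 tolerance = 1e-12)
  }
  # column statistics likewise
  cl <- H[, 7]
  oc <- oracle_stats(cl)
  for (s in names(oc)) {
    expect_equal(v[[sprintf("c_f_alpha_%s_7", s)]], unname(oc[[s]]),
                 tolerance = 1e-12)
  }

  # a known sequence as one row
  H2 <- H
  H2[3, ] <- 1:54
  v2 <- summarize_statistics(H2)
  expect_equal(v2[["c_alpha_f_min_3"]], 1)
  expect_equal(v2[["c_alpha_f_median_3"]], 27.5)
  expect_equal(v2[["c_alpha_f_var_3"]], stats::var(1:54))

  # constant matrix: degenerate skewness/kurtosis convention
  vc <- summarize_statistics(matrix(2, 45, 54))
  expect_equal(unname(vc[["c_alpha_f_max_1"]]), 2)
  expect_equal(unname(vc[["c_alpha_f_sd_1"]]), 0)
  expect_equal(unname(vc[["c_alpha_f_skewness_1"]]), 0)
  expect_equal(unname(vc[["c_alpha_f_kurtosis_1"]]), 0)
})

test_that("moment conventions agree with e1071's type-1 estimators", {
  withr::with_seed(83, {
    v <- rgamma(54, 2)
    s <- osasev:::.seven_stats(v)
    expect_equal(unname(s["skewness"]), e1071::skewness(v, type = 1))
    expect_equal(unname(s["kurtosis"]), e1071::kurtosis(v, type = 1) + 3)
  })
})

test_that("basis files round-trip through plain text", {
  withr::with_seed(97, {
    mats <- lapply(1:2, function(i) matrix(runif(10 * 30), 10, 30))
    b <- fit_shared_basis(mats, rank = 3, seed = 2, max_iter = 40)
    b$n_f <- 10L; b$n_alpha <- 30L
    path <- withr::local_tempfile(fileext = ".json")
    write_basis(b, path)
    b2 <- read_basis(path)
    expect_equal(b2$W, b$W, tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(b2$rank, b$rank)
  })
})
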