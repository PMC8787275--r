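# The Welch / log-log-slope estimator chain: segment arithmetic, PSD
# normalization, exact recovery on noiseless spectra, class conversion,
# and the voxelwise map.

test_that("segment length follows the 8-window / 50%-overlap arithmetic", {
  expect_identical(welch_segment_length(900), 200L)
  expect_identical(welch_segment_length(4096), 910L)
  # total coverage never exceeds the series length
  for (n in c(144, 300, 900, 901, 1000, 4096)) {
    L <- welch_segment_length(n)
    step <- floor(L / 2)
    expect_lte(L + 7 * step, n)
  }
})

test_that("welch_psd returns a one-sided density with DC excluded", {
  x <- uniform_ts(synthesize_power_law(0, 900, seed = 1)$values, 1)
  sp <- welch_psd(x)
  expect_identical(attr(sp, "segment_length"), 200L)
  expect_length(sp$frequencies, 100)
  expect_equal(sp$frequencies[1], 0.005)       # resolution 1/(L*dt)
  expect_equal(max(sp$frequencies), 0.5)       # Nyquist
  expect_true(all(sp$power >= 0))
})

test_that("white-noise PSD integrates to the series variance (Parseval)", {
  set.seed(42)
  ints <- replicate(100, {
    sp <- welch_psd(uniform_ts(rnorm(900), 1))
    sum(sp$power) * 0.005
  })
  expect_lt(abs(mean(ints) - 1), 0.1)
})

test_that("a pure sinusoid peaks at its own frequency bin", {
  t <- 0:899
  sp <- welch_psd(uniform_ts(sin(2 * pi * 0.1 * t), 1))
  expect_equal(sp$frequencies[which.max(sp$power)], 0.1)
})

test_that("noiseless power-law spectra are recovered exactly", {
  f <- seq(0.005, 0.5, by = 0.005)
  for (beta in c(-0.5, 0.3, 1.5, 2.4)) {
    fit <- fit_scaling(power_spectrum(f, 3.7 * f^(-beta)))
    expect_equal(fit$beta, beta, tolerance = 1e-10)
    expect_equal(fit$hurst_extended, (beta + 1) / 2, tolerance = 1e-10)
    expect_equal(fit$intercept, log10(3.7), tolerance = 1e-10)
    expect_identical(fit$signal_class, if (beta < 1) "fGn" else "fBm")
    expect_gt(fit$r_squared, 1 - 1e-10)
  }
  flat <- fit_scaling(power_spectrum(f, rep(1, length(f))))
  expect_equal(flat$beta, 0, tolerance = 1e-12)
  expect_equal(flat$intercept, 0, tolerance = 1e-12)
})

test_that("the beta = 1 boundary is assigned to fBm", {
  # the class rule is evaluated on the fitted beta: exactly 1 is fBm
  fit <- fractalbold:::new_scaling_fit(
    beta = 1, intercept = 0, fit_band = c(0.01, 0.5),
    n_freq_bins = 99L, r_squared = 1
  )
  expect_identical(fit$signal_class, "fBm")
  expect_identical(fit$hurst_extended, 1)
  expect_identical(classical_hurst(1)$signal_class, "fBm")
  expect_identical(classical_hurst(1)$hurst, 0)
})

test_that("white Gaussian noise estimates H' near 0.5 end-to-end", {
  set.seed(7)
  h <- replicate(50, estimate_hurst(uniform_ts(rnorm(900), 1))$hurst_extended)
  expect_lt(abs(mean(h) - 0.5), 0.03)
})

test_that("fGn- and fBm-class inputs land on the right side of H' = 1", {
  h_fgn <- vapply(1:20, function(s) {
    estimate_hurst(synthesize_power_law(0.5, 900, seed = s))$hurst_extended
  }, numeric(1))
  h_fbm <- vapply(1:20, function(s) {
    estimate_hurst(synthesize_power_law(1.8, 900, seed = 100 + s))$hurst_extended
  }, numeric(1))
  expect_lt(abs(mean(h_fgn) - 0.75), 0.05)
  expect_true(all(h_fbm > 1))
})

test_that("classical conversion is class-dependent and offset by 2", {
  expect_equal(classical_hurst(0.2), list(hurst = 0.6, signal_class = "fGn"))
  expect_equal(classical_hurst(1.8), list(hurst = 0.4, signal_class = "fBm"))
  # same classical H from the two classes differs by beta of exactly 2
  for (H in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    beta_fgn <- 2 * H - 1
    beta_fbm <- 2 * H + 1
    expect_identical(classical_hurst(beta_fgn)$signal_class, "fGn")
    expect_identical(classical_hurst(beta_fbm)$signal_class, "fBm")
    expect_equal(classical_hurst(beta_fgn)$hurst, classical_hurst(beta_fbm)$hurst)
    expect_equal(beta_fbm - beta_fgn, 2, tolerance = 1e-12)
  }
})

test_that("amplitude scaling shifts only the intercept", {
  x <- synthesize_power_law(1.2, 900, seed = 3)
  f1 <- estimate_hurst(x)
  f2 <- estimate_hurst(uniform_ts(7 * x$values, x$sampling_interval))
  expect_equal(f2$beta, f1$beta, tolerance = 1e-10)
  expect_equal(f2$hurst_extended, f1$hurst_extended, tolerance = 1e-10)
  expect_identical(f2$signal_class, f1$signal_class)
  expect_equal(f2$intercept - f1$intercept, 2 * log10(7), tolerance = 1e-8)
})

test_that("H' = (beta + 1)/2 holds for every returned fit", {
  for (s in 1:10) {
    fit <- estimate_hurst(synthesize_power_law(runif(1, -0.5, 2.5), 900, seed = s))
    expect_identical(fit$hurst_extended, (fit$beta + 1) / 2)
    expect_identical(fit$signal_class, if (fit$beta < 1) "fGn" else "fBm")
  }
})

test_that("degenerate spectra and series are rejected", {
  expect_error(welch_psd(uniform_ts(rep(1, 900), 1)), "constant")
  expect_error(welch_psd(uniform_ts(rnorm(100), 1)), "too short")
  f <- seq(0.005, 0.5, by = 0.005)
  # nonpositive bins inside the band are excluded with a warning
  p <- f^-1
  p[30] <- 0
  expect_error(power_spectrum(f, -p), "nonnegative")
  expect_warning(fit <- fit_scaling(power_spectrum(f, p)), "nonpositive")
  expect_equal(fit$beta, 1, tolerance = 1e-10)
  # too few bins inside the band
  expect_error(fit_scaling(power_spectrum(f, p), f_min = 0.49), "4")
})

test_that("voxelwise map preserves between-region ordering and sentinels", {
  grid <- c(6L, 6L, 2L)
  nvox <- prod(grid)
  n <- 300
  labs <- array(rep(1:2, each = nvox / 2), grid)
  ord_ok <- 0
  for (s in 1:25) {
    set.seed(s)
    mat <- fractalbold:::synth_power_law_matrix(
      rep(c(0.6, 1.6), each = nvox / 2), n, 1, 1, nvox
    )
    data <- aperm(array(mat, c(n, grid)), c(2, 3, 4, 1))
    vol <- volume4d(data, tr = 1)
    atlas <- label_atlas(labs, legend = c(low = 1L, high = 2L))
    h <- voxelwise_hurst(vol, atlas)
    m1 <- mean(h[labs == 1])
    m2 <- mean(h[labs == 2])
    if (m2 > m1) ord_ok <- ord_ok + 1
  }
  expect_equal(ord_ok, 25)

  # out-of-mask voxels are NaN; constant voxels are NaN with a warning
  mask <- labs == 1
  vol2 <- volume4d(array(rnorm(nvox * n), c(grid, n)), tr = 1)
  vol2$data[1, 1, 1, ] <- 5
  expect_warning(h2 <- voxelwise_hurst(vol2, array(TRUE, grid)), "constant")
  expect_true(is.nan(h2[1, 1, 1]))
  h3 <- suppressWarnings(voxelwise_hurst(vol2, mask))
  expect_true(all(is.nan(h3[!mask])))
  expect_error(voxelwise_hurst(vol2, array(FALSE, grid)), "empty")
  expect_error(
    voxelwise_hurst(vol2, array(TRUE, c(3L, 3L, 3L))),
    "grid"
  )
})
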