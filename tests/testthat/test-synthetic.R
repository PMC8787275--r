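# The generators: spectral fidelity of the power-law synthesizer against a
# naive periodogram oracle, seed determinism, phantom structure, motion
# and stimulus contracts.

test_that("identical spec and seed give bit-identical output", {
  a <- synthesize_power_law(1.3, 256, seed = 99)
  b <- synthesize_power_law(1.3, 256, seed = 99)
  expect_identical(a, b)
  m1 <- synthesize_motion(100, 0.12, seed = 5)
  m2 <- synthesize_motion(100, 0.12, seed = 5)
  expect_identical(m1, m2)
  s1 <- synthesize_stimulus(n_frames_video = 64, seed = 3)
  s2 <- synthesize_stimulus(n_frames_video = 64, seed = 3)
  expect_identical(s1, s2)
  d <- phantom_design(n_subjects = 1, n_frames = 256, seed = 4)
  expect_identical(
    phantom_run_volume(d, 1, "rest", 1),
    phantom_run_volume(d, 1, "rest", 1)
  )
})

test_that("synthesized series are zero-mean with the requested variance", {
  x <- synthesize_power_law(1.5, 900, variance = 2.5, seed = 1)
  expect_equal(mean(x$values), 0, tolerance = 1e-12)
  expect_equal(var(x$values), 2.5, tolerance = 1e-10)
})

test_that("beta = 0 synthesis is uncorrelated white noise", {
  set.seed(10)
  ac1 <- vapply(1:50, function(s) {
    x <- synthesize_power_law(0, 900, seed = s)
    stats::acf(x$values, lag.max = 1, plot = FALSE)$acf[2]
  }, numeric(1))
  expect_lt(abs(mean(ac1)), 0.02)
})

test_that("spectral fidelity: naive periodogram recovers the target index", {
  # independent oracle: full-length raw periodogram + OLS (no Welch code)
  for (beta in c(-0.5, 0, 0.5, 1, 1.5, 2)) {
    est <- vapply(1:200, function(s) {
      x <- synthesize_power_law(beta, 4096, seed = 10000 * (beta + 1) + s)
      naive_periodogram_beta(x$values, 1)
    }, numeric(1))
    expect_lt(abs(mean(est) - beta), 0.1)
  }
})

test_that("generator input validation", {
  expect_error(synthesize_power_law(5, 900), "range")
  expect_error(synthesize_power_law(1, 32), "64")
  expect_error(synthesize_power_law(1, 900, variance = 0), "positive")
  expect_error(phantom_design(n_subjects = 0), "n_subjects")
  expect_error(phantom_design(n_frames = 100), "n_frames")
  expect_error(phantom_design(noise_fraction = 1), "noise_fraction")
  expect_error(phantom_design(h_rest = c(
    GMother = 2.2, Vis = 1, SoM = 1, DAtt = 1, VAtt = 1, Lim = 1, FP = 1, DN = 1
  )), "indices")
  expect_error(synthesize_motion(900, mean_fd_target = 0), "positive")
  expect_error(synthesize_motion(20, 0.12), "65")
})

test_that("homogeneous noiseless phantom estimates H' near 1 everywhere", {
  h1 <- c(GMother = 1, Vis = 1, SoM = 1, DAtt = 1, VAtt = 1, Lim = 1, FP = 1, DN = 1)
  d <- phantom_design(
    n_subjects = 1, n_runs_per_condition = 1, n_frames = 900,
    h_rest = h1, delta_h = 0 * h1, noise_fraction = 0,
    subject_beta_sd = 0, run_beta_sd = 0, seed = 6
  )
  vol <- phantom_run_volume(d, 1, "rest", 1)
  atlas <- label_atlas(d$label_map)
  h <- voxelwise_hurst(vol, atlas)
  vals <- h[d$label_map != 0]
  expect_lt(abs(mean(vals) - 1), 0.02)
  expect_lt(sd(vals), 0.1)
})

test_that("written phantom NIfTI conserves label counts and TR", {
  d <- phantom_design(
    n_subjects = 1, n_runs_per_condition = 1, n_frames = 256, seed = 8
  )
  out <- synthesize_phantom(d, dir = tempfile("phantom"))
  expect_identical(nrow(out$records), 2L)  # 1 run x 2 conditions
  atlas2 <- read_atlas_nifti(file.path(dirname(out$records$path[1]), "atlas.nii.gz"))
  expect_identical(
    tabulate(atlas2$labels[atlas2$labels != 0], 8),
    tabulate(d$label_map[d$label_map != 0], 8)
  )
  vol <- read_bold_nifti(out$records$path[1])
  expect_equal(vol$tr, d$tr)
  expect_identical(dim(vol$data), c(d$grid_shape, d$n_frames))
  # streamed and materialized labelled voxels agree exactly
  direct <- phantom_run_volume(d, 1, out$records$condition[1], 1)
  expect_equal(as.numeric(vol$data), as.numeric(direct$data), tolerance = 1e-6)
})

test_that("motion tables hit the FD mean and spectral targets", {
  mp <- synthesize_motion(900, mean_fd_target = 0.12, fd_beta = 0.2, seed = 2)
  expect_identical(dim(mp), c(900L, 6L))
  tr <- framewise_displacement(mp)
  expect_gte(tr$mean_fd, 0.108)
  expect_lte(tr$mean_fd, 0.132)
  expect_true(all(tr$fd >= 0))

  # white-noise motion: H of the FD series near 0.5
  h0 <- vapply(1:100, function(s) {
    t <- framewise_displacement(synthesize_motion(900, 0.12, fd_beta = 0, seed = s))
    fd_hurst(t)$hurst_extended
  }, numeric(1))
  expect_lt(abs(mean(h0) - 0.5), 0.05)

  # weakly persistent motion: H near 0.6
  h2 <- vapply(1:100, function(s) {
    t <- framewise_displacement(synthesize_motion(900, 0.12, fd_beta = 0.2, seed = 200 + s))
    fd_hurst(t)$hurst_extended
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.6), 0.1)
})

test_that("stimulus brightness carries the requested fractal level", {
  h <- vapply(1:50, function(s) {
    st <- synthesize_stimulus(n_frames_video = 900, brightness_beta = 1.588, seed = s)
    b <- brightness_series(st$frames, st$frame_rate)
    feature_hurst(b)$hurst_extended
  }, numeric(1))
  expect_lt(abs(mean(h) - 1.294), 0.1)
})

test_that("stimulus audio RMS envelope carries its fractal level", {
  h <- vapply(1:25, function(s) {
    st <- synthesize_stimulus(n_frames_video = 900, rms_beta = 0.68, seed = 500 + s)
    r <- rms_series(st$audio_samples, st$audio_sample_rate)
    feature_hurst(r)$hurst_extended
  }, numeric(1))
  expect_lt(abs(mean(h) - 0.84), 0.12)
})
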