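# Synthetic-data generators: power-law series, 4D phantom cohorts with
# network-structured cross-condition effects, motion parameter tables, and
# audiovisual stimulus arrays. Everything is deterministic given its seed.

# Spectral synthesis engine (current RNG stream). `beta` is a scalar or a
# length-V vector of spectral indices, one per column. Draws independent
# complex Gaussian Fourier coefficients with amplitude proportional to
# f^(-beta/2), enforces Hermitian symmetry with a zero DC component,
# inverse-transforms, and rescales each column to the requested sample
# variance exactly.
#
# `white_fraction` mixes in a white-noise component in the frequency
# domain: each component's spectrum is normalized to equal total power,
# then combined with amplitude weights (1 - white_fraction) and
# white_fraction. Because both components are independent Gaussian
# processes, this is distributionally identical to summing the two series
# in the time domain, at half the RNG cost.
synth_power_law_matrix <- function(beta, n, sampling_interval = 1,
                                   variance = 1, n_series = length(beta),
                                   white_fraction = 0) {
  beta <- rep_len(as.numeric(beta), n_series)
  m <- as.integer(floor(n / 2))
  f <- (1:m) / (n * sampling_interval)
  # m x V amplitude matrix: f^(-beta/2) per column
  amp <- exp(outer(log(f), -beta / 2))
  if (white_fraction > 0) {
    wf <- white_fraction
    amp <- sweep(amp, 2, sqrt(colSums(amp^2) / m), "/")
    amp <- sqrt((1 - wf)^2 * amp^2 + wf^2)
  }
  zr <- matrix(stats::rnorm(m * n_series), m, n_series)
  zi <- matrix(stats::rnorm(m * n_series), m, n_series)
  coef <- amp * complex(real = zr, imaginary = zi)
  if (n %% 2 == 0) {
    # Nyquist coefficient must be real (self-conjugate bin)
    coef[m, ] <- complex(real = sqrt(2) * amp[m, ] * zr[m, ], imaginary = 0)
  }
  X <- matrix(0 + 0i, n, n_series)
  X[2:(m + 1), ] <- coef
  X[n:(n - m + 2), ] <- Conj(coef[1:(m - 1), , drop = FALSE])
  x <- Re(stats::mvfft(X, inverse = TRUE)) / n
  x <- sweep(x, 2, colMeans(x), "-")
  sds <- sqrt(colSums(x^2) / (n - 1))
  sweep(x, 2, sqrt(variance) / sds, "*")
}

#' Synthesize a power-law (fGn/fBm-class) time series
#'
#' Spectral synthesis: independent complex Gaussian Fourier coefficients
#' with amplitude proportional to `f^(-beta/2)` and Hermitian symmetry,
#' inverse-transformed and rescaled to the requested sample variance. The
#' DC component is zero (the f = 0 amplitude is undefined under a power
#' law), so the series is exactly zero-mean. `beta < 1` produces
#' stationary fGn-class signals, `beta > 1` fBm-class signals with
#' low-frequency-dominated variance.
#'
#' @param beta Target spectral index, in `[-2, 4]`.
#' @param n_samples Number of samples (at least 64).
#' @param sampling_interval Sampling interval in seconds.
#' @param variance Sample variance of the output.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output. `NULL` uses the current RNG stream.
#' @return A [uniform_ts()].
#' @examples
#' x <- synthesize_power_law(1.5, 900, seed = 7)
#' estimate_hurst(x)$hurst_extended  # close to 1.25
#' @export
synthesize_power_law <- function(beta, n_samples, sampling_interval = 1,
                                 variance = 1, seed = NULL) {
  stop_if_not_scalar_number(beta, "beta")
  if (beta < -2 || beta > 4) {
    stop("`beta` outside supported range [-2, 4]", call. = FALSE)
  }
  stop_if_not_scalar_number(n_samples, "n_samples", positive = TRUE)
  if (n_samples < 64) {
    stop("`n_samples` must be at least 64", call. = FALSE)
  }
  stop_if_not_scalar_number(sampling_interval, "sampling_interval", positive = TRUE)
  stop_if_not_scalar_number(variance, "variance", positive = TRUE)
  x <- with_seed(seed, synth_power_law_matrix(
    beta, as.integer(n_samples), sampling_interval, variance, 1L
  ))
  uniform_ts(x[, 1], sampling_interval)
}

#' Phantom cohort design
#'
#' Describes a synthetic multi-subject fMRI study: a voxel grid with a
#' region label map (background, non-network gray matter, and the seven
#' networks), per-region/per-condition spectral indices, and the variance
#' components that make the cohort behave like a test-retest study.
#'
#' Each labelled voxel's series is
#' `(1 - noise_fraction) * powerlaw(beta) + noise_fraction * white noise`,
#' where `beta` is the region/condition base value plus a per-subject
#' Gaussian jitter (SD `subject_beta_sd`, shared across that subject's runs
#' and conditions, giving between-subject variance for ICC) plus a per-run
#' jitter (SD `run_beta_sd`, run-to-run state variability that sets the
#' within-condition reliability level). Voxel spectra share a common
#' high-frequency density rather than a common variance, so temporal SD and
#' ALFF increase with H across voxels as they do in real BOLD data.
#' Background voxels are pure white noise of variance
#' `background_variance`.
#'
#' The default condition effects (movie minus rest, in extended-H units)
#' are +0.014 non-network gray matter, +0.096 visual, +0.022 somatomotor,
#' +0.026 dorsal attention, 0 ventral attention, 0 limbic, -0.012
#' frontoparietal, -0.010 default network.
#'
#' @param grid_shape Voxel counts per axis (default 16 x 16 x 8).
#' @param n_frames Frames per run (default 900).
#' @param tr Repetition time in seconds (default 1).
#' @param voxel_size mm per axis.
#' @param label_map 3D integer array on `grid_shape` (0 = background,
#'   1 = non-network GM, 2..8 = networks); `NULL` builds the default
#'   central-core layout with 64 voxels per region.
#' @param h_rest Named numeric of rest-condition extended-H levels per
#'   region (names as in [default_region_legend()]).
#' @param delta_h Named numeric of movie-minus-rest extended-H effects.
#' @param noise_fraction White-noise amplitude admixture per voxel, in `[0, 1)`.
#' @param subject_beta_sd SD of the per-subject spectral-index jitter.
#' @param run_beta_sd SD of the per-run spectral-index jitter.
#' @param background_variance Variance of background white noise.
#' @param n_subjects,n_runs_per_condition Cohort structure (default 24
#'   subjects, 4 runs in each of rest and movie).
#' @param seed Integer seed for the whole cohort.
#' @return An object of class `phantom_design`.
#' @export
phantom_design <- function(grid_shape = c(16L, 16L, 8L),
                           n_frames = 900L,
                           tr = 1,
                           voxel_size = c(1.3, 1.3, 1.3),
                           label_map = NULL,
                           h_rest = c(
                             GMother = 0.90, Vis = 1.00, SoM = 0.92,
                             DAtt = 0.98, VAtt = 0.95, Lim = 0.75,
                             FP = 1.05, DN = 1.10
                           ),
                           delta_h = c(
                             GMother = 0.014, Vis = 0.096, SoM = 0.022,
                             DAtt = 0.026, VAtt = 0, Lim = 0,
                             FP = -0.012, DN = -0.010
                           ),
                           noise_fraction = 0.05,
                           subject_beta_sd = 0.05,
                           run_beta_sd = 0.03,
                           background_variance = 0.01,
                           n_subjects = 24L,
                           n_runs_per_condition = 4L,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (n_subjects < 1) {
    stop("`n_subjects` must be at least 1", call. = FALSE)
  }
  if (n_runs_per_condition < 1) {
    stop("`n_runs_per_condition` must be at least 1", call. = FALSE)
  }
  if (n_frames < 256) {
    stop("`n_frames` must be at least 256", call. = FALSE)
  }
  if (noise_fraction < 0 || noise_fraction >= 1) {
    stop("`noise_fraction` must be in [0, 1)", call. = FALSE)
  }
  stop_if_not_scalar_number(tr, "tr", positive = TRUE)
  legend <- default_region_legend()
  region_names <- names(legend)
  stopifnot(
    all(region_names %in% names(h_rest)),
    all(region_names %in% names(delta_h))
  )
  if (is.null(label_map)) {
    label_map <- default_label_map(grid_shape)
  }
  stopifnot(identical(dim(label_map), grid_shape))
  counts <- tabulate(label_map[label_map != 0L], nbins = max(legend))
  if (any(counts[legend] == 0L)) {
    stop("every labelled region must be nonempty in `label_map`", call. = FALSE)
  }
  beta_rest <- 2 * h_rest[region_names] - 1
  beta_movie <- 2 * (h_rest[region_names] + delta_h[region_names]) - 1
  beta_rc <- cbind(rest = beta_rest, movie = beta_movie)
  if (any(beta_rc <= -1) || any(beta_rc >= 3)) {
    stop("region spectral indices must lie in (-1, 3)", call. = FALSE)
  }
  structure(
    list(
      grid_shape = grid_shape, n_frames = as.integer(n_frames), tr = tr,
      voxel_size = voxel_size, label_map = label_map, legend = legend,
      beta_by_region_condition = beta_rc,
      noise_fraction = noise_fraction,
      subject_beta_sd = subject_beta_sd, run_beta_sd = run_beta_sd,
      background_variance = background_variance,
      n_subjects = as.integer(n_subjects),
      n_runs_per_condition = as.integer(n_runs_per_condition),
      seed = as.integer(seed)
    ),
    class = "phantom_design"
  )
}

#' @rdname phantom_design
#' @details `default_label_map()` places an 8 x 8 x 8 labelled core at the
#'   centre of the grid (64 voxels per region, one region per core slice,
#'   labels 1..8) surrounded by background; the grid must be at least
#'   8 x 8 x 8.
#' @export
default_label_map <- function(grid_shape = c(16L, 16L, 8L)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  lab <- array(0L, grid_shape)
  ox <- floor((grid_shape[1] - 8) / 2)
  oy <- floor((grid_shape[2] - 8) / 2)
  oz <- floor((grid_shape[3] - 8) / 2)
  for (r in 1:8) {
    lab[ox + 1:8, oy + 1:8, oz + r] <- r
  }
  lab
}

#' @export
print.phantom_design <- function(x, ...) {
  cat(sprintf(
    "<phantom_design> %s grid, %d frames @ TR %g s, %d subjects x %d runs x 2 conditions\n",
    paste(x$grid_shape, collapse = "x"), x$n_frames, x$tr,
    x$n_subjects, x$n_runs_per_condition
  ))
  invisible(x)
}

# All spectral-index jitters of a design, drawn from one RNG stream so the
# variance components are iid draws from a single generator state. (Drawing
# each run's jitter under its own derived set.seed() leaves detectable
# correlation between streams seeded with nearby integers, which showed up
# as spurious condition effects in null regions.)
# Returns subject jitter (n_subjects x regions, shared across runs and
# conditions) and run jitter (regions x runs x condition x subject).
phantom_jitters <- function(design) {
  nreg <- length(design$legend)
  with_seed(derive_seed(design$seed, 424243), {
    subject <- matrix(
      stats::rnorm(design$n_subjects * nreg, 0, design$subject_beta_sd),
      design$n_subjects, nreg
    )
    run <- array(
      stats::rnorm(nreg * design$n_runs_per_condition * 2 * design$n_subjects,
        0, design$run_beta_sd
      ),
      c(nreg, design$n_runs_per_condition, 2, design$n_subjects)
    )
    list(subject = subject, run = run)
  })
}

# Seed for a run's voxel-noise stream; the large co-prime multiplier spreads
# consecutive run indices far apart in seed space.
phantom_run_seed <- function(design, subject, condition, run) {
  ci <- match(condition, c("rest", "movie"))
  idx <- ((subject - 1) * 2 + (ci - 1)) * design$n_runs_per_condition + run
  ((as.double(design$seed) %% 2147483629) * 48271 + idx * 1103515245) %%
    2147483647 + 1
}

# Labelled-voxel time-series matrix for one run (n_frames x V, V = number
# of labelled voxels, columns ordered by voxel index). Streaming building
# block shared by phantom_run_volume() and phantom_roi_hurst(): the
# background draw happens after these, so labelled voxels are identical
# whether or not background is generated.
phantom_run_matrix <- function(design, subject, condition, run) {
  idx <- which(design$label_map != 0L)
  labs <- design$label_map[idx]
  jit <- phantom_jitters(design)
  ci <- match(condition, c("rest", "movie"))
  with_seed(phantom_run_seed(design, subject, condition, run), {
    beta_region <- design$beta_by_region_condition[, condition] +
      jit$subject[subject, ] + jit$run[, run, ci, subject]
    beta_vox <- pmin(pmax(beta_region[labs], -0.95), 2.95)
    mat <- synth_power_law_matrix(
      beta_vox, design$n_frames, design$tr,
      variance = 1, n_series = length(idx),
      white_fraction = design$noise_fraction
    )
    # beta-dependent variance: voxels share a high-frequency noise floor,
    # so low-frequency power (hence SD and ALFF) grows with H as in real
    # BOLD, instead of all voxels having identical variance
    f <- (1:floor(design$n_frames / 2)) / (design$n_frames * design$tr)
    scale <- sqrt(colMeans(exp(outer(-log(f / 0.25), beta_vox))))
    mat <- sweep(mat, 2, scale, "*")
    list(matrix = mat, voxel_index = idx, labels = labs)
  })
}

#' Generate one phantom run as a 4D volume
#'
#' Deterministic given the design: the same (subject, condition, run)
#' always yields the same volume, independent of which other runs have
#' been generated.
#'
#' @param design A [phantom_design()].
#' @param subject Subject index, 1-based.
#' @param condition `"rest"` or `"movie"`.
#' @param run Run index within condition, 1-based.
#' @return A [volume4d()].
#' @export
phantom_run_volume <- function(design, subject, condition, run) {
  stopifnot(inherits(design, "phantom_design"))
  condition <- match.arg(condition, c("rest", "movie"))
  stopifnot(
    subject >= 1, subject <= design$n_subjects,
    run >= 1, run <= design$n_runs_per_condition
  )
  rm_ <- phantom_run_matrix(design, subject, condition, run)
  n <- design$n_frames
  nvox <- prod(design$grid_shape)
  bg_idx <- which(design$label_map == 0L)
  # time-major matrix, then permute into (x, y, z, t)
  full <- matrix(0, n, nvox)
  full[, rm_$voxel_index] <- rm_$matrix
  if (length(bg_idx) > 0) {
    bg <- with_seed(
      derive_seed(phantom_run_seed(design, subject, condition, run), 999983L),
      matrix(stats::rnorm(n * length(bg_idx), 0, sqrt(design$background_variance)),
        n, length(bg_idx)
      )
    )
    full[, bg_idx] <- bg
  }
  data <- aperm(array(full, c(n, design$grid_shape)), c(2, 3, 4, 1))
  volume4d(data, tr = design$tr, voxel_size = design$voxel_size)
}

#' Materialize a phantom cohort
#'
#' Generates every subject x condition x run volume of the design. With
#' `dir` set, volumes and the label atlas are written as NIfTI-1 (float32
#' BOLD with TR in `pixdim[4]`; int16 atlas) and the returned table carries
#' file paths; otherwise volumes are returned in a list-column (only
#' advisable for small designs).
#'
#' @param design A [phantom_design()].
#' @param dir Output directory, or `NULL` to keep volumes in memory.
#' @return A list with elements `atlas` (a [label_atlas()]) and `records`
#'   (a tibble with columns `subject`, `condition`, `run`, and `volume` or
#'   `path`).
#' @export
synthesize_phantom <- function(design, dir = NULL) {
  stopifnot(inherits(design, "phantom_design"))
  atlas <- label_atlas(design$label_map, design$legend)
  grid <- expand.grid(
    run = seq_len(design$n_runs_per_condition),
    condition = c("rest", "movie"),
    subject = seq_len(design$n_subjects),
    stringsAsFactors = FALSE
  )[, c("subject", "condition", "run")]
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_atlas_nifti(atlas, file.path(dir, "atlas.nii.gz"))
    paths <- character(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      vol <- phantom_run_volume(
        design, grid$subject[i], grid$condition[i], grid$run[i]
      )
      paths[i] <- file.path(dir, sprintf(
        "sub-%02d_%s_run-%d.nii.gz",
        grid$subject[i], grid$condition[i], grid$run[i]
      ))
      write_bold_nifti(vol, paths[i])
    }
    records <- tibble::as_tibble(cbind(grid, path = paths))
  } else {
    vols <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      vols[[i]] <- phantom_run_volume(
        design, grid$subject[i], grid$condition[i], grid$run[i]
      )
    }
    records <- tibble::as_tibble(grid)
    records$volume <- vols
  }
  list(atlas = atlas, records = records)
}

#' Streaming per-run ROI Hurst summary of a phantom cohort
#'
#' Generates each run's labelled voxels, estimates voxelwise extended H
#' with the Welch pipeline, and averages within regions — without ever
#' holding more than one run in memory. Background voxels (pure white
#' noise, outside the gray matter mask) are not generated. "GM" is the
#' mean over all labelled voxels.
#'
#' @param design A [phantom_design()].
#' @inheritParams estimate_hurst
#' @return A tibble with columns `subject`, `condition`, `run`, `region`
#'   (GM plus the 8 labelled regions), `h`.
#' @export
phantom_roi_hurst <- function(design, n_windows = 8, overlap_fraction = 0.5,
                              f_min = 0.01, f_max = NULL) {
  stopifnot(inherits(design, "phantom_design"))
  legend <- design$legend
  region_names <- names(legend)
  out <- vector("list", design$n_subjects * 2 * design$n_runs_per_condition)
  k <- 0
  for (subject in seq_len(design$n_subjects)) {
    for (condition in c("rest", "movie")) {
      for (run in seq_len(design$n_runs_per_condition)) {
        rm_ <- phantom_run_matrix(design, subject, condition, run)
        psd <- welch_psd_matrix(rm_$matrix, design$tr, n_windows, overlap_fraction)
        fmax <- if (is.null(f_max)) max(psd$frequencies) else f_max
        fit <- fit_scaling_matrix(psd$frequencies, psd$power, f_min, fmax)
        h <- (fit$beta + 1) / 2
        means <- vapply(
          legend, function(l) mean(h[rm_$labels == l]), numeric(1)
        )
        k <- k + 1
        out[[k]] <- tibble::tibble(
          subject = subject, condition = condition, run = run,
          region = c("GM", region_names),
          h = c(mean(h), unname(means))
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Synthesize a motion-parameter table
#'
#' Builds a six-column rigid-body motion table (3 translations in mm, 3
#' rotations in radians, one row per frame) whose derived framewise
#' displacement series has a prescribed mean and spectral index. The FD
#' target series is generated directly as a power-law process scaled to
#' `mean_fd_target` (coefficient of variation `fd_cv`, floored at 5% of the
#' target to keep FD nonnegative), then distributed across the six
#' parameter channels with random nonnegative weights and random signs so
#' that the Power-convention FD of the returned table reproduces it
#' exactly.
#'
#' @param n_frames Number of frames (at least 65, so the FD series supports
#'   spectral estimation).
#' @param mean_fd_target Target mean FD in mm (positive).
#' @param fd_beta Spectral index of the FD series (0 = white-noise-like
#'   motion).
#' @param tr Sampling interval of the frames in seconds.
#' @param fd_cv Coefficient of variation of the FD series.
#' @param radius Head radius (mm) used to convert rotations; must match the
#'   radius used when FD is recomputed.
#' @param seed Integer seed.
#' @return A tibble with columns `trans_x`, `trans_y`, `trans_z` (mm) and
#'   `rot_x`, `rot_y`, `rot_z` (radians).
#' @export
synthesize_motion <- function(n_frames, mean_fd_target = 0.12, fd_beta = 0.2,
                              tr = 1, fd_cv = 0.4, radius = 50, seed = NULL) {
  stop_if_not_scalar_number(mean_fd_target, "mean_fd_target", positive = TRUE)
  stop_if_not_scalar_number(n_frames, "n_frames", positive = TRUE)
  if (n_frames < 65) {
    stop("`n_frames` must be at least 65", call. = FALSE)
  }
  with_seed(seed, {
    m <- n_frames - 1
    z <- synth_power_law_matrix(fd_beta, m, tr, variance = 1, n_series = 1L)[, 1]
    fd <- pmax(mean_fd_target * (1 + fd_cv * z), 0.05 * mean_fd_target)
    w <- matrix(abs(stats::rnorm(m * 6)), m, 6)
    w <- w / rowSums(w)
    s <- matrix(sample(c(-1, 1), m * 6, replace = TRUE), m, 6)
    inc <- s * w * fd
    inc[, 4:6] <- inc[, 4:6] / radius
    params <- apply(rbind(0, inc), 2, cumsum)
    colnames(params) <- c(
      "trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z"
    )
    tibble::as_tibble(params)
  })
}

#' Synthesize movie-stimulus arrays
#'
#' Produces a frame-intensity stack whose per-frame brightness follows a
#' requested power law, and an amplitude-modulated white-noise audio track
#' whose one-second RMS envelope follows another. Defaults anchor the
#' brightness and RMS-envelope fractal levels at extended-H of about 1.29
#' and 0.84 respectively. The zero-crossing rate of the audio is not
#' separately controlled (a white carrier gives a near-constant ZCR around
#' 0.5).
#'
#' @param n_frames_video Number of video frames (at least 64).
#' @param frame_rate Video frame rate in Hz.
#' @param audio_sample_rate Audio sample rate in Hz.
#' @param n_samples_audio Number of audio samples; default spans the video
#'   duration.
#' @param brightness_beta Spectral index of the brightness series.
#' @param rms_beta Spectral index of the audio RMS envelope (one-second
#'   resolution).
#' @param frame_shape Pixel grid of each frame.
#' @param seed Integer seed.
#' @return A list with `frames` (3D array, time x height x width, values in
#'   (0, 1)), `frame_rate`, `audio_samples`, `audio_sample_rate`.
#' @export
synthesize_stimulus <- function(n_frames_video = 900, frame_rate = 1,
                                audio_sample_rate = 100,
                                n_samples_audio = NULL,
                                brightness_beta = 1.588, rms_beta = 0.68,
                                frame_shape = c(16L, 16L), seed = NULL) {
  stopifnot(n_frames_video >= 64, frame_rate > 0, audio_sample_rate > 0)
  n_seconds <- ceiling(n_frames_video / frame_rate)
  if (is.null(n_samples_audio)) {
    n_samples_audio <- n_seconds * audio_sample_rate
  }
  stopifnot(n_samples_audio > 0)
  with_seed(seed, {
    zb <- synth_power_law_matrix(
      brightness_beta, n_frames_video, 1 / frame_rate, 1, 1L
    )[, 1]
    brightness <- pmin(pmax(0.5 * (1 + 0.15 * zb), 0.01), 0.99)
    frames <- array(
      rep(brightness, times = prod(frame_shape)),
      c(n_frames_video, frame_shape)
    )
    n_env <- max(64L, as.integer(n_seconds))
    ze <- synth_power_law_matrix(rms_beta, n_env, 1, 1, 1L)[, 1]
    envelope <- pmax(0.2 * (1 + 0.3 * ze), 0.01)
    carrier <- stats::rnorm(n_samples_audio)
    env_per_sample <- envelope[
      pmin(n_env, 1L + (seq_len(n_samples_audio) - 1L) %/% audio_sample_rate)
    ]
    list(
      frames = frames, frame_rate = frame_rate,
      audio_samples = carrier * env_per_sample,
      audio_sample_rate = audio_sample_rate
    )
  })
}
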