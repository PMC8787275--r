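#' Segment length for a Welch periodogram
#'
#' With `n_windows` segments at overlap fraction `v`, a series of length N
#' is covered by segments of length `L = floor(N / (1 + (n_windows - 1) * (1 - v)))`;
#' for the default 8 windows at 50% overlap this is `floor(2N/9)` (a 900-frame
#' run gives L = 200 and a frequency resolution of 0.005 Hz at TR = 1 s).
#'
#' @param n_samples Series length.
#' @param n_windows Number of segments.
#' @param overlap_fraction Fractional overlap between consecutive segments.
#' @return Integer segment length.
#' @export
welch_segment_length <- function(n_samples, n_windows = 8, overlap_fraction = 0.5) {
  stopifnot(n_windows >= 1, overlap_fraction >= 0, overlap_fraction < 1)
  as.integer(floor(n_samples / (1 + (n_windows - 1) * (1 - overlap_fraction))))
}

# Hann taper of length L (periodic endpoints included; L >= 2).
hann_window <- function(L) {
  0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
}

# Vectorized Welch engine. `x` is an n x V matrix of series in columns.
# Returns list(frequencies, power [m x V matrix], segment_length).
# Per-segment mean removal, Hann taper, one-sided density normalization,
# DC bin excluded. Constant columns yield all-zero power (callers decide
# whether that is an error or a sentinel).
welch_psd_matrix <- function(x, sampling_interval, n_windows = 8,
                             overlap_fraction = 0.5) {
  n <- nrow(x)
  V <- ncol(x)
  L <- welch_segment_length(n, n_windows, overlap_fraction)
  if (L < 32) {
    stop(sprintf(
      "series too short for Welch estimation: segment length %d < 32 (n = %d)",
      L, n
    ), call. = FALSE)
  }
  step <- max(1L, as.integer(floor(L * (1 - overlap_fraction))))
  starts <- 0:(n_windows - 1) * step
  stopifnot(max(starts) + L <= n)

  w <- hann_window(L)
  W <- sum(w^2)
  fs <- 1 / sampling_interval

  # Stack all segments of all series column-wise, one big FFT call.
  segs <- matrix(0, L, V * n_windows)
  for (s in seq_len(n_windows)) {
    cols <- ((s - 1) * V + 1):(s * V)
    segs[, cols] <- x[starts[s] + seq_len(L), , drop = FALSE]
  }
  segs <- sweep(segs, 2, colMeans(segs), "-")
  segs <- segs * w
  S <- stats::mvfft(segs)

  m <- as.integer(floor(L / 2))
  P <- (2 / (fs * W)) * Mod(S[2:(m + 1), , drop = FALSE])^2
  if (L %% 2 == 0) P[m, ] <- P[m, ] / 2   # Nyquist bin appears once

  Pav <- P[, seq_len(V), drop = FALSE]
  if (n_windows > 1) {
    for (s in 2:n_windows) {
      Pav <- Pav + P[, ((s - 1) * V + 1):(s * V), drop = FALSE]
    }
  }
  Pav <- Pav / n_windows

  list(
    frequencies = (1:m) / (L * sampling_interval),
    power = Pav,
    segment_length = L
  )
}

#' Welch power spectral density of a time series
#'
#' Averages modified periodograms over Hann-tapered, mean-removed segments
#' (default: eight windows with 50% overlap). Returns a one-sided density
#' with the DC bin excluded; the frequency resolution is
#' `1 / (segment_length * sampling_interval)`.
#'
#' @param series A [uniform_ts()].
#' @param n_windows Number of segments (default 8).
#' @param overlap_fraction Fractional overlap between segments (default 0.5).
#' @return A [power_spectrum()] with attribute `segment_length`.
#' @examples
#' x <- uniform_ts(rnorm(900), 1)
#' sp <- welch_psd(x)
#' attr(sp, "segment_length")  # 200 for n = 900
#' @export
welch_psd <- function(series, n_windows = 8, overlap_fraction = 0.5) {
  stopifnot(inherits(series, "uniform_ts"))
  if (stats::sd(series$values) == 0) {
    stop("constant series: power spectrum is identically zero", call. = FALSE)
  }
  res <- welch_psd_matrix(
    matrix(series$values, ncol = 1), series$sampling_interval,
    n_windows, overlap_fraction
  )
  out <- power_spectrum(res$frequencies, res$power[, 1])
  attr(out, "segment_length") <- res$segment_length
  out
}

# Vectorized log-log slope fit over a fixed frequency band. Assumes all
# power values in the band are positive (the streaming voxel path checks
# constant columns upstream). Returns list(beta, intercept, r_squared).
fit_scaling_matrix <- function(frequencies, power, f_min, f_max) {
  keep <- frequencies >= f_min - 1e-12 & frequencies <= f_max + 1e-12
  if (sum(keep) < 4L) {
    stop(sprintf(
      "need at least 4 frequency bins in [%g, %g] Hz, have %d",
      f_min, f_max, sum(keep)
    ), call. = FALSE)
  }
  lx <- log10(frequencies[keep])
  ly <- log10(power[keep, , drop = FALSE])
  xc <- lx - mean(lx)
  sxx <- sum(xc^2)
  slope <- colSums(xc * ly) / sxx
  intercept <- colMeans(ly) - slope * mean(lx)
  fitted_ss <- slope^2 * sxx
  total_ss <- colSums(sweep(ly, 2, colMeans(ly), "-")^2)
  r2 <- ifelse(total_ss > 0, fitted_ss / total_ss, NA_real_)
  list(beta = -slope, intercept = intercept, r_squared = r2, n_bins = sum(keep))
}

#' Fit the spectral index on log-log axes
#'
#' Ordinary least squares of `log10(power)` on `log10(frequency)` over a
#' restricted band (default: 0.01 Hz up to the highest available bin). The
#' spectral index is the negative slope; the extended Hurst exponent is
#' `H' = (beta + 1) / 2` and the signal class is fGn for `beta < 1`, fBm
#' otherwise (the boundary is assigned to fBm).
#'
#' Bins with nonpositive power inside the band are excluded with a warning;
#' an error is raised if fewer than 4 usable bins remain.
#'
#' @param spectrum A [power_spectrum()].
#' @param f_min Lower band edge in Hz (default 0.01).
#' @param f_max Upper band edge in Hz; `NULL` (default) uses the highest
#'   frequency present (the Nyquist bin for a Welch spectrum).
#' @return A `scaling_fit` with fields `beta`, `intercept` (base-10, at
#'   f = 1 Hz), `hurst_extended`, `signal_class`, `fit_band`, `n_freq_bins`,
#'   `r_squared`.
#' @examples
#' f <- seq(0.005, 0.5, by = 0.005)
#' fit_scaling(power_spectrum(f, f^-1.5))  # beta = 1.5, H' = 1.25, fBm
#' @export
fit_scaling <- function(spectrum, f_min = 0.01, f_max = NULL) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (is.null(f_max)) f_max <- max(spectrum$frequencies)
  stop_if_not_scalar_number(f_min, "f_min", positive = TRUE)
  stop_if_not_scalar_number(f_max, "f_max", positive = TRUE)
  keep <- spectrum$frequencies >= f_min - 1e-12 &
    spectrum$frequencies <= f_max + 1e-12
  bad <- keep & spectrum$power <= 0
  if (any(bad)) {
    warning(sprintf(
      "%d nonpositive power bin(s) inside the fit band excluded", sum(bad)
    ), call. = FALSE)
    keep <- keep & spectrum$power > 0
  }
  if (sum(keep) < 4L) {
    stop("fewer than 4 positive-power bins inside the fit band", call. = FALSE)
  }
  res <- fit_scaling_matrix(
    spectrum$frequencies[keep],
    matrix(spectrum$power[keep], ncol = 1),
    f_min = min(spectrum$frequencies[keep]),
    f_max = max(spectrum$frequencies[keep])
  )
  new_scaling_fit(
    beta = res$beta[1],
    intercept = res$intercept[1],
    fit_band = c(f_min, f_max),
    n_freq_bins = res$n_bins,
    r_squared = res$r_squared[1]
  )
}

#' Extended Hurst exponent of a time series
#'
#' The core estimator: Welch PSD (eight Hann windows, 50% overlap) followed
#' by a log-log OLS slope fit above 0.01 Hz. The extended Hurst exponent
#' `H' = (beta + 1) / 2` spans (0, 2): values below 1 indicate stationary
#' fractional Gaussian noise, above 1 nonstationary fractional Brownian
#' motion.
#'
#' @inheritParams welch_psd
#' @inheritParams fit_scaling
#' @return A `scaling_fit`; see [fit_scaling()].
#' @examples
#' x <- synthesize_power_law(beta = 0.5, n_samples = 900, seed = 1)
#' estimate_hurst(x)
#' @export
estimate_hurst <- function(series, n_windows = 8, overlap_fraction = 0.5,
                           f_min = 0.01, f_max = NULL) {
  sp <- welch_psd(series, n_windows, overlap_fraction)
  fit_scaling(sp, f_min = f_min, f_max = f_max)
}

#' Class-dependent classical Hurst exponent
#'
#' Converts a spectral index to the classical Hurst exponent in (0, 1)
#' using the class-dependent formulas `H = (beta + 1) / 2` for fractional
#' Gaussian noise (`beta < 1`) and `H = (beta - 1) / 2` for fractional
#' Brownian motion (`beta >= 1`). Two processes of different class sharing
#' a classical H therefore have spectral indices differing by exactly 2,
#' which is why the pipeline reports the class-spanning extended exponent
#' instead.
#'
#' @param beta Spectral index (finite scalar).
#' @return A list with elements `hurst` and `signal_class`.
#' @examples
#' classical_hurst(0.2)  # fGn, H = 0.6
#' classical_hurst(1.8)  # fBm, H = 0.4
#' @export
classical_hurst <- function(beta) {
  stop_if_not_scalar_number(beta, "beta")
  if (beta < 1) {
    list(hurst = (beta + 1) / 2, signal_class = "fGn")
  } else {
    list(hurst = (beta - 1) / 2, signal_class = "fBm")
  }
}

#' Voxelwise extended Hurst map
#'
#' Runs [estimate_hurst()] on every in-mask voxel of a 4D volume. The
#' computation is vectorized across voxels (result independent of voxel
#' order). Out-of-mask voxels are `NaN`; in-mask constant voxels are set to
#' `NaN` with a warning.
#'
#' @param volume A [volume4d()].
#' @param mask A [label_atlas()] (any nonzero label is in-mask), or a
#'   logical/numeric 3D array on the same grid.
#' @inheritParams estimate_hurst
#' @return A 3D array of H' values with attribute `kind = "hurst"`.
#' @export
voxelwise_hurst <- function(volume, mask, n_windows = 8, overlap_fraction = 0.5,
                            f_min = 0.01, f_max = NULL) {
  stopifnot(inherits(volume, "volume4d"))
  mask_arr <- as_mask_array(mask)
  grid <- dim(volume$data)[1:3]
  if (!identical(dim(mask_arr), grid)) {
    stop("mask grid does not match volume grid", call. = FALSE)
  }
  idx <- which(mask_arr)
  if (length(idx) == 0L) {
    stop("mask is empty", call. = FALSE)
  }
  n <- dim(volume$data)[4]
  mat <- matrix(aperm(volume$data, c(4, 1, 2, 3)), nrow = n)[, idx, drop = FALSE]

  h <- rep(NaN, length(idx))
  sds <- apply(mat, 2, stats::sd)
  ok <- sds > 0
  if (any(!ok)) {
    warning(sprintf("%d constant voxel(s) set to NaN", sum(!ok)), call. = FALSE)
  }
  if (any(ok)) {
    psd <- welch_psd_matrix(
      mat[, ok, drop = FALSE], volume$tr, n_windows, overlap_fraction
    )
    fmax <- if (is.null(f_max)) max(psd$frequencies) else f_max
    fit <- fit_scaling_matrix(psd$frequencies, psd$power, f_min, fmax)
    h[ok] <- (fit$beta + 1) / 2
  }
  out <- array(NaN, grid)
  out[idx] <- h
  attr(out, "kind") <- "hurst"
  out
}
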