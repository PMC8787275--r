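# Companion voxelwise measures: spatial Gaussian smoothing, ALFF in the
# 0.01-0.08 Hz band, and temporal standard deviation.

# 1D Gaussian kernel for a given FWHM (mm) and voxel size (mm). Truncated
# at 4 sigma and renormalized to unit sum so constants are preserved.
gaussian_kernel_1d <- function(fwhm, voxel_size) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve a 4D array along spatial axis `axis` with kernel `k`, reflect
# padding at the edges. Implemented as a sum of shifted slabs so the work
# is vectorized across all other dimensions.
convolve_axis_reflect <- function(data, k, axis) {
  n <- dim(data)[axis]
  r <- (length(k) - 1L) / 2L
  # reflect-pad index sequence; repeated reflection handles kernels wider
  # than the axis
  idx_for <- function(shift) {
    i <- seq_len(n) + shift
    while (any(i < 1L) || any(i > n)) {
      i[i < 1L] <- 2L - i[i < 1L]
      i[i > n] <- 2L * n - i[i > n]
    }
    i
  }
  out <- array(0, dim(data))
  sel <- function(i) {
    switch(axis,
      data[i, , , , drop = FALSE],
      data[, i, , , drop = FALSE],
      data[, , i, , drop = FALSE]
    )
  }
  for (j in seq_along(k)) {
    out <- out + k[j] * sel(idx_for(j - 1L - r))
  }
  out
}

#' Spatial Gaussian smoothing of a 4D volume
#'
#' Per-frame 3D Gaussian convolution, applied separably along each spatial
#' axis with `sigma = fwhm / (2 * sqrt(2 * log(2)))` converted to voxel
#' units per axis (anisotropic voxel sizes are handled per axis). Edges use
#' reflect padding; `fwhm = 0` is the identity.
#'
#' @param volume A [volume4d()].
#' @param fwhm Full width at half maximum of the kernel, in mm.
#' @return A smoothed [volume4d()].
#' @export
smooth_gaussian <- function(volume, fwhm = 5) {
  stopifnot(inherits(volume, "volume4d"))
  stop_if_not_scalar_number(fwhm, "fwhm")
  if (fwhm < 0) {
    stop("`fwhm` must be nonnegative", call. = FALSE)
  }
  if (fwhm == 0) {
    return(volume)
  }
  data <- volume$data
  for (axis in 1:3) {
    if (dim(data)[axis] > 1L) {
      k <- gaussian_kernel_1d(fwhm, volume$voxel_size[axis])
      data <- convolve_axis_reflect(data, k, axis)
    }
  }
  volume4d(data, volume$tr, volume$voxel_size, volume$affine)
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Sum of the amplitude spectrum of the (mean-removed) series over the
#' full-length discrete-Fourier bins inside the band — frequency-domain
#' band selection, no Welch averaging. Amplitudes are scaled as
#' `2 * |X_k| / n`, so a pure in-band sinusoid of amplitude `a` aligned
#' with a bin contributes `a`; ALFF is linear in signal amplitude.
#'
#' @param series A [uniform_ts()].
#' @param f_low,f_high Band edges in Hz (defaults 0.01 and 0.08).
#' @return ALFF value (nonnegative scalar).
#' @export
alff <- function(series, f_low = 0.01, f_high = 0.08) {
  stopifnot(inherits(series, "uniform_ts"))
  n <- length(series$values)
  if (n < 64) {
    stop("series must have at least 64 samples", call. = FALSE)
  }
  nyq <- nyquist_frequency(series)
  if (f_low <= 0 || f_high > nyq || f_low >= f_high) {
    stop("band must satisfy 0 < f_low < f_high <= Nyquist", call. = FALSE)
  }
  f <- (1:floor(n / 2)) / (n * series$sampling_interval)
  keep <- f >= f_low - 1e-12 & f <= f_high + 1e-12
  if (!any(keep)) {
    stop("band contains no frequency bins at this resolution", call. = FALSE)
  }
  X <- stats::fft(series$values - mean(series$values))
  amp <- 2 * Mod(X[2:(floor(n / 2) + 1)]) / n
  sum(amp[keep])
}

#' Temporal standard deviation
#'
#' Sample standard deviation (n - 1 denominator) of a series.
#'
#' @param series A [uniform_ts()].
#' @return Nonnegative scalar.
#' @export
temporal_sd <- function(series) {
  stopifnot(inherits(series, "uniform_ts"))
  stats::sd(series$values)
}

#' Voxelwise ALFF and SD maps
#'
#' Apply [alff()] / [temporal_sd()] to every in-mask voxel of a volume.
#' Out-of-mask voxels are `NaN`.
#'
#' @param volume A [volume4d()].
#' @param mask A [label_atlas()] or 3D mask array.
#' @inheritParams alff
#' @return 3D array with attribute `kind` set to `"alff"` or `"sd"`.
#' @export
alff_map <- function(volume, mask, f_low = 0.01, f_high = 0.08) {
  stopifnot(inherits(volume, "volume4d"))
  mask_arr <- as_mask_array(mask)
  stopifnot(identical(dim(mask_arr), dim(volume$data)[1:3]))
  n <- dim(volume$data)[4]
  mat <- voxel_matrix(volume, mask_arr)
  f <- (1:floor(n / 2)) / (n * volume$tr)
  keep <- f >= f_low - 1e-12 & f <= f_high + 1e-12
  if (!any(keep)) {
    stop("band contains no frequency bins at this resolution", call. = FALSE)
  }
  mat <- sweep(mat, 2, colMeans(mat), "-")
  X <- stats::mvfft(mat)
  amp <- 2 * Mod(X[1 + which(keep), , drop = FALSE]) / n
  out <- array(NaN, dim(volume$data)[1:3])
  out[which(mask_arr)] <- colSums(amp)
  attr(out, "kind") <- "alff"
  out
}

#' @rdname alff_map
#' @export
sd_map <- function(volume, mask) {
  stopifnot(inherits(volume, "volume4d"))
  mask_arr <- as_mask_array(mask)
  stopifnot(identical(dim(mask_arr), dim(volume$data)[1:3]))
  mat <- voxel_matrix(volume, mask_arr)
  out <- array(NaN, dim(volume$data)[1:3])
  out[which(mask_arr)] <- apply(mat, 2, stats::sd)
  attr(out, "kind") <- "sd"
  out
}
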