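#' Uniformly sampled time series
#'
#' The atomic unit consumed by every estimator in the package: a vector of
#' real-valued samples taken at a fixed sampling interval (for BOLD data,
#' the repetition time TR in seconds).
#'
#' @param values Numeric vector of samples. All values must be finite.
#' @param sampling_interval Time between consecutive samples, in seconds.
#'
#' @return An object of class `uniform_ts`: a list with elements `values`
#'   and `sampling_interval`.
#' @examples
#' ts <- uniform_ts(sin(seq(0, 20, by = 0.1)), sampling_interval = 0.1)
#' nyquist_frequency(ts)
#' @export
uniform_ts <- function(values, sampling_interval = 1) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("a time series needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("time series values must all be finite", call. = FALSE)
  }
  stop_if_not_scalar_number(sampling_interval, "sampling_interval", positive = TRUE)
  structure(
    list(values = values, sampling_interval = as.numeric(sampling_interval)),
    class = "uniform_ts"
  )
}

#' @export
print.uniform_ts <- function(x, ...) {
  cat(sprintf(
    "<uniform_ts> %d samples @ %g s (%.4g .. %.4g)\n",
    length(x$values), x$sampling_interval,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
length.uniform_ts <- function(x) length(x$values)

#' @rdname uniform_ts
#' @param x A `uniform_ts` object.
#' @export
nyquist_frequency <- function(x) {
  stopifnot(inherits(x, "uniform_ts"))
  1 / (2 * x$sampling_interval)
}

#' One-sided power spectrum
#'
#' @param frequencies Strictly increasing frequencies in Hz (DC excluded).
#' @param power Nonnegative power spectral density values, same length.
#'
#' @return An object of class `power_spectrum`.
#' @export
power_spectrum <- function(frequencies, power) {
  frequencies <- as.numeric(frequencies)
  power <- as.numeric(power)
  if (length(frequencies) != length(power)) {
    stop("frequencies and power must have the same length", call. = FALSE)
  }
  if (length(frequencies) < 2L || any(diff(frequencies) <= 0)) {
    stop("frequencies must be strictly increasing, length >= 2", call. = FALSE)
  }
  if (any(frequencies <= 0)) {
    stop("frequencies must be positive (DC bin excluded)", call. = FALSE)
  }
  if (any(!is.finite(power)) || any(power < 0)) {
    stop("power values must be finite and nonnegative", call. = FALSE)
  }
  structure(
    list(frequencies = frequencies, power = power),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum> %d bins, %g .. %g Hz\n",
    length(x$frequencies), min(x$frequencies), max(x$frequencies)
  ))
  invisible(x)
}

# Constructor for the scaling-fit result; internal, populated by fit_scaling().
new_scaling_fit <- function(beta, intercept, fit_band, n_freq_bins, r_squared) {
  structure(
    list(
      beta = beta,
      intercept = intercept,
      hurst_extended = (beta + 1) / 2,
      signal_class = if (beta < 1) "fGn" else "fBm",
      fit_band = fit_band,
      n_freq_bins = n_freq_bins,
      r_squared = r_squared
    ),
    class = "scaling_fit"
  )
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit> beta = %.4f, H' = %.4f (%s), band %g-%g Hz, %d bins, R^2 = %.3f\n",
    x$beta, x$hurst_extended, x$signal_class,
    x$fit_band[1], x$fit_band[2], x$n_freq_bins, x$r_squared
  ))
  invisible(x)
}
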