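# Movie-stimulus feature extraction: per-frame brightness, and windowed
# audio RMS and zero-crossing rate — the three series whose fractal
# structure is compared against the BOLD signal's.

#' Per-frame brightness series
#'
#' Mean luminance of each frame. Grayscale stacks (time x height x width)
#' are averaged directly; 3-channel stacks (time x height x width x 3) are
#' converted with the Rec. 601 weights 0.299 / 0.587 / 0.114 first.
#'
#' @param frames 3D or 4D numeric array, time first.
#' @param frame_rate Frames per second.
#' @return A [uniform_ts()] with sampling interval `1 / frame_rate`.
#' @export
brightness_series <- function(frames, frame_rate = 1) {
  stopifnot(is.array(frames))
  nd <- length(dim(frames))
  if (!nd %in% c(3L, 4L)) {
    stop("`frames` must be time x height x width (x 3 channels)", call. = FALSE)
  }
  if (dim(frames)[1] < 64) {
    stop("need at least 64 frames", call. = FALSE)
  }
  if (prod(dim(frames)[-1]) == 0) {
    stop("frames are empty", call. = FALSE)
  }
  if (nd == 4L) {
    stopifnot(dim(frames)[4] == 3L)
    w <- c(0.299, 0.587, 0.114)
    lum <- frames[, , , 1] * w[1] + frames[, , , 2] * w[2] + frames[, , , 3] * w[3]
  } else {
    lum <- frames
  }
  vals <- apply(lum, 1, mean)
  uniform_ts(vals, 1 / frame_rate)
}

# Window/hop arithmetic shared by rms_series and zcr_series: start indices
# of each full window (floor convention).
window_starts <- function(n_samples, win_n, hop_n) {
  if (win_n > n_samples) {
    stop("window longer than track", call. = FALSE)
  }
  n_win <- 1L + (n_samples - win_n) %/% hop_n
  if (n_win < 64L) {
    stop("need at least 64 windows for downstream estimation", call. = FALSE)
  }
  (seq_len(n_win) - 1L) * hop_n + 1L
}

#' Windowed audio RMS series
#'
#' Root mean square of the waveform per window: `sqrt(mean(samples^2))`,
#' sampled every `hop` seconds.
#'
#' @param samples Numeric waveform.
#' @param sample_rate Samples per second.
#' @param window Window length in seconds (default 1).
#' @param hop Hop between windows in seconds (default 1); must satisfy
#'   `window >= hop > 0`.
#' @return A [uniform_ts()] with sampling interval `hop`.
#' @export
rms_series <- function(samples, sample_rate, window = 1, hop = 1) {
  stopifnot(is.numeric(samples), sample_rate > 0, window >= hop, hop > 0)
  win_n <- as.integer(round(window * sample_rate))
  hop_n <- as.integer(round(hop * sample_rate))
  starts <- window_starts(length(samples), win_n, hop_n)
  vals <- vapply(
    starts,
    function(s) sqrt(mean(samples[s:(s + win_n - 1L)]^2)),
    numeric(1)
  )
  uniform_ts(vals, hop)
}

#' Windowed audio zero-crossing rate series
#'
#' Per window, the fraction of adjacent sample pairs with a strict sign
#' change, in `[0, 1]`. Zero samples are treated as positive (touching
#' zero is not a crossing).
#'
#' @inheritParams rms_series
#' @return A [uniform_ts()] with sampling interval `hop`.
#' @export
zcr_series <- function(samples, sample_rate, window = 1, hop = 1) {
  stopifnot(is.numeric(samples), sample_rate > 0, window >= hop, hop > 0)
  win_n <- as.integer(round(window * sample_rate))
  hop_n <- as.integer(round(hop * sample_rate))
  starts <- window_starts(length(samples), win_n, hop_n)
  sgn <- ifelse(samples >= 0, 1, -1)
  cross <- sgn[-1] != sgn[-length(sgn)]  # crossing between i and i+1
  vals <- vapply(
    starts,
    function(s) sum(cross[s:(s + win_n - 2L)]) / (win_n - 1L),
    numeric(1)
  )
  uniform_ts(vals, hop)
}

#' Fractal analysis of a stimulus feature series
#'
#' Delegates to [estimate_hurst()]: Welch PSD and log-log slope with the
#' pipeline defaults.
#'
#' @param series A [uniform_ts()] (brightness, RMS or ZCR series).
#' @inheritParams estimate_hurst
#' @return A `scaling_fit`.
#' @export
feature_hurst <- function(series, n_windows = 8, overlap_fraction = 0.5,
                          f_min = 0.01, f_max = NULL) {
  estimate_hurst(
    series,
    n_windows = n_windows, overlap_fraction = overlap_fraction,
    f_min = f_min, f_max = f_max
  )
}
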