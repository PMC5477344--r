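#' Zero-phase Butterworth low-pass filter
#'
#' Applies a 2nd-order Butterworth low-pass filter forward and backward
#' (zero phase, so velocity and catch timing are not lag-shifted). The
#' series is reflection-padded at both ends before filtering to suppress
#' edge transients, then trimmed, so output length equals input length and
#' a constant series passes through unchanged (DC gain 1).
#'
#' @param x Uniformly sampled numeric series.
#' @param cutoff_hz Cutoff frequency, Hz (default 10).
#' @param sample_rate_hz Sampling rate, Hz. Must exceed twice the cutoff.
#' @param order Filter order (default 2; the effective attenuation is that
#'   of the squared magnitude response because of the two passes).
#' @return Filtered series of the same length.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' noisy <- sin(2 * pi * 2 * t) + sin(2 * pi * 50 * t)
#' smooth <- lowpass_filter(noisy)
#' @export
lowpass_filter <- function(x, cutoff_hz = 10, sample_rate_hz = 1000,
                           order = 2) {
  stopifnot(is.numeric(x), cutoff_hz > 0, sample_rate_hz > 2 * cutoff_hz,
            order >= 1)
  n <- length(x)
  if (n <= 3 * (2 * order + 1))
    stop("filter error: series too short for zero-phase filtering (need > ",
         3 * (2 * order + 1), " samples)")
  # reflection padding, about 3 filter time constants
  pad <- min(n - 1, max(9L, ceiling(3 * sample_rate_hz / cutoff_hz)))
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2),
                       type = "low")
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(pad + 1):(pad + n)]
}

#' Filter a trial recording
#'
#' Low-pass filters the angle series of a trial and derives the filtered
#' velocity: the recorded velocity channel is filtered when present,
#' otherwise velocity is obtained by central differences of the filtered
#' angle.
#'
#' @param trial A \code{kaps_trial}.
#' @param cutoff_hz Cutoff frequency, Hz.
#' @return The trial with filtered \code{angle_deg} and
#'   \code{velocity_deg_s}; \code{meta$filtered} is set to \code{TRUE}.
#' @export
filter_trial <- function(trial, cutoff_hz = 10) {
  stopifnot(inherits(trial, "kaps_trial"))
  fs <- trial$meta$sample_rate_hz
  trial$data$angle_deg <- lowpass_filter(trial$data$angle_deg, cutoff_hz, fs)
  v <- trial$data$velocity_deg_s
  if (is.null(v) || all(is.na(v))) {
    a <- trial$data$angle_deg
    n <- length(a)
    v <- c(a[2] - a[1],
           (a[3:n] - a[1:(n - 2)]) / 2,
           a[n] - a[n - 1]) * fs
  } else {
    v <- lowpass_filter(v, cutoff_hz, fs)
  }
  trial$data$velocity_deg_s <- v
  trial$meta$filtered <- TRUE
  trial
}
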