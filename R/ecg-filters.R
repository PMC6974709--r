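# Zero-phase filtering stages for ECG preprocessing.

# Symmetric-boundary index folding: maps any integer index onto 1..n by
# mirror reflection, so padded convolution has no edge discontinuity.
fold_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- ((i - 1L) %% p) + 1L
  ifelse(j > n, p - j + 2L, j)
}

# Centered convolution with symmetric (reflect) padding; exact zero phase for
# symmetric odd-length kernels.
conv_same <- function(x, h) {
  n <- length(x)
  pad <- length(h)
  xp <- x[fold_index(seq.int(1L - pad, n + pad), n)]
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y[(pad + 1):(pad + n)])
}

# Kaiser-window FIR low-pass, DC gain exactly 1, with the -3 dB point tuned
# onto `cutoff_hz` (fir1's nominal cutoff is the -6 dB point).
design_fir_lowpass <- function(fs, cutoff_hz, beta = 5, taps_per_cycle = 2.5) {
  assert_that(cutoff_hz > 0 && cutoff_hz < fs / 2,
              "FIR cutoff must lie in (0, Nyquist)")
  ord <- max(8L, 2L * floor(taps_per_cycle * fs / cutoff_hz / 2))
  wc <- cutoff_hz / (fs / 2)
  h <- NULL
  for (it in 1:3) {
    h <- signal::fir1(ord, min(wc, 0.99), type = "low",
                      window = signal::kaiser(ord + 1, beta))
    h <- h / sum(h)
    f3 <- fir_db_point(h, fs, -3)
    if (!is.finite(f3) || f3 <= 0) break
    wc <- wc * cutoff_hz / f3
  }
  h
}

# Frequency (Hz) at which the magnitude response first drops to `db`.
fir_db_point <- function(h, fs, db = -3) {
  f <- seq(0, fs / 2, length.out = 2048)
  k <- seq_along(h) - 1
  H <- vapply(f, function(ff) abs(sum(h * exp(-2i * pi * ff * k / fs))), numeric(1))
  target <- 10^(db / 20)
  below <- which(H <= target)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(f[1])
  approx(H[(i - 1):i], f[(i - 1):i], xout = target)$y
}

#' Band-pass filter an ECG record (zero phase)
#'
#' Forward-backward Butterworth band-pass; the bidirectional pass cancels the
#' phase response, so fiducial points are not shifted in time.
#'
#' @param record Data frame with columns `time_ms`, `mv`.
#' @param fs Sampling rate (Hz); inferred from `time_ms` when `NULL`.
#' @param low_hz,high_hz Pass-band edges (Hz).
#' @param order Butterworth order of each one-directional pass.
#' @return The filtered record (same shape tibble).
#' @export
ecg_bandpass <- function(record, fs = NULL, low_hz = 0.5, high_hz = 250,
                         order = 2) {
  check_ecg_record(record)
  fs <- infer_fs(record, fs)
  assert_that(low_hz > 0 && low_hz < high_hz,
              "need 0 < low_hz < high_hz")
  assert_that(high_hz < fs / 2, "high cutoff must be below Nyquist")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  tibble(time_ms = record$time_ms,
         mv = as.numeric(signal::filtfilt(bf, record$mv)))
}

#' Remove baseline wander (bidirectional high-pass)
#'
#' Forward-backward (zero-phase) Butterworth high-pass. Drift below the
#' cutoff is strongly attenuated while QRS morphology and T-wave shape are
#' preserved, which is what interval measurement depends on.
#'
#' @inheritParams ecg_bandpass
#' @param cutoff_hz High-pass cutoff (Hz).
#' @param order Butterworth order of each one-directional pass.
#' @return The drift-corrected record.
#' @export
ecg_remove_baseline <- function(record, fs = NULL, cutoff_hz = 1.5, order = 4) {
  check_ecg_record(record)
  fs <- infer_fs(record, fs)
  n <- nrow(record)
  assert_that(n > 2 * fs / cutoff_hz,
              "record shorter than the baseline filter warm-up length")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  tibble(time_ms = record$time_ms,
         mv = as.numeric(signal::filtfilt(bf, record$mv)))
}

#' Low-pass smooth a P- or T-wave segment (Kaiser-window FIR)
#'
#' Linear-phase FIR low-pass with the group delay compensated (centered
#' convolution), so the smoothed wave is not shifted in time. Segments
#' shorter than the filter are reflect-padded with a warning.
#'
#' @param x Numeric vector of segment samples (mV).
#' @param fs Sampling rate (Hz).
#' @param cutoff_hz Low-pass cutoff; 20 Hz is the conventional smoothing for
#'   wave display, higher cutoffs preserve narrow murine waves for
#'   measurement.
#' @param beta Kaiser window shape parameter.
#' @return Smoothed numeric vector of the same length.
#' @export
ecg_smooth_wave <- function(x, fs, cutoff_hz = 20, beta = 5) {
  h <- design_fir_lowpass(fs, cutoff_hz, beta)
  if (length(x) < length(h)) {
    rlang::warn("segment shorter than the FIR smoothing filter; reflect-padding")
  }
  conv_same(x, h)
}
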