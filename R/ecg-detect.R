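# R-peak detection: undecimated coiflet wavelet transform, squared detail
# magnitude, adaptive thresholding, refractory pruning, and sub-sample
# localization by 3-point parabolic fitting.

# Coiflet-4 analysis filters (24 taps, standard published coefficients).
coif4_filters <- function() {
  dec_lo <- c(-1.7849909144933469e-06, -3.259647940030751e-06,
              3.1229861599195265e-05, 6.233885431278719e-05,
              -0.0002599743371222568, -0.0005890202246332165,
              0.0012665610789256603, 0.0037514346971460866,
              -0.0056582838001308835, -0.015211728187697211,
              0.02508225333794961, 0.03933442260558915,
              -0.09622042453595264, -0.06662747236681717,
              0.43438603311435653, 0.7822389344242826,
              0.41530842700068227, -0.05607731960356926,
              -0.08126671024919373, 0.02668230466960483,
              0.01606894713157503, -0.007346167936268051,
              -0.001629492425226786, 0.000892313902537003)
  dec_hi <- rev(dec_lo) * rep_len(c(-1, 1), length(dec_lo))
  list(lo = dec_lo, hi = dec_hi)
}

# Undecimated (a trous) wavelet detail coefficients at `level`.
swt_detail <- function(x, level, filters = coif4_filters()) {
  a <- x
  d <- NULL
  for (j in seq_len(level)) {
    spacing <- 2L^(j - 1L)
    up <- function(f) {
      m <- matrix(0, spacing, length(f))
      m[1, ] <- f
      as.vector(m)[seq_len((length(f) - 1L) * spacing + 1L)]
    }
    d <- conv_same(a, up(filters$hi))
    a <- conv_same(a, up(filters$lo))
  }
  d
}

# Time offset (samples, sub-sample) of the squared-detail energy peak for a
# Gaussian reference pulse, used to compensate the transform's group delay.
swt_delay_samples <- function(level, fs, qrs_sigma_ms = 2) {
  n <- max(512L, 2L^(level + 6L))
  center <- n / 2
  t <- seq_len(n)
  pulse <- exp(-((t - center)^2) / (2 * (qrs_sigma_ms * fs / 1000)^2))
  e <- swt_detail(pulse, level)^2
  i <- which.max(e)
  parabolic_vertex(e[i - 1], e[i], e[i + 1], i) - center
}

#' Detect R peaks by coiflet wavelet transform
#'
#' Computes undecimated coiflet-4 detail coefficients at a scale matched to
#' the QRS bandwidth, squares them, thresholds adaptively (per-second block
#' maxima), prunes detections closer than a refractory period of
#' `0.5 x running-median RR` (floored), and localizes each surviving peak to
#' sub-sample precision with a 3-point parabolic fit of the squared wavelet
#' magnitude. The transform's group delay is measured at run time on a
#' Gaussian reference pulse and subtracted.
#'
#' @param record Baseline-corrected ECG record (`time_ms`, `mv`).
#' @param fs Sampling rate (Hz); inferred when `NULL`.
#' @param level Wavelet scale; default matches the detail band to the murine
#'   QRS bandwidth (`round(log2(fs / 125))`).
#' @param threshold_frac Detection threshold as a fraction of the median
#'   per-second block maximum of the squared detail magnitude.
#' @param refractory_floor_ms Lower bound on the refractory period (ms).
#' @param qrs_sigma_ms Width of the reference pulse used for delay
#'   compensation.
#' @return Tibble with columns `beat` and `r_ms` (sub-sample R times),
#'   strictly increasing.
#' @export
detect_r_peaks <- function(record, fs = NULL, level = NULL,
                           threshold_frac = 0.2,
                           refractory_floor_ms = 30,
                           qrs_sigma_ms = 2) {
  check_ecg_record(record)
  fs <- infer_fs(record, fs)
  x <- record$mv
  if (sd(x) < .Machine$double.eps^0.5) {
    stop_cardioage("flatline record: no beats detectable", "cardioage_no_beats")
  }
  level <- level %||% max(1L, min(8L, round(log2(fs / 125))))

  e <- swt_detail(x, level)^2
  delay <- swt_delay_samples(level, fs, qrs_sigma_ms)

  # Adaptive threshold from per-second block maxima (robust to a few bad
  # blocks and to slow amplitude drift).
  block <- pmax(1L, ceiling(seq_along(e) / fs))
  bmax <- tapply(e, block, max)
  thr <- threshold_frac * median(bmax)

  loc_max <- which(e > thr &
                     e >= c(-Inf, e[-length(e)]) &
                     e > c(e[-1], -Inf))
  if (length(loc_max) == 0) {
    stop_cardioage("no QRS-like activity above threshold", "cardioage_no_beats")
  }

  prune <- function(cand, refr_samples) {
    keep <- integer(0)
    for (i in cand) {
      if (length(keep) == 0 || i - keep[length(keep)] >= refr_samples) {
        keep <- c(keep, i)
      } else if (e[i] > e[keep[length(keep)]]) {
        keep[length(keep)] <- i
      }
    }
    keep
  }
  # Two passes: a floor-refractory pass to estimate the RR scale, then the
  # adaptive refractory (0.5 x median RR).
  pass1 <- prune(loc_max, refractory_floor_ms * fs / 1000)
  refr_ms <- refractory_floor_ms
  if (length(pass1) >= 3) {
    refr_ms <- max(refractory_floor_ms, 0.5 * median(diff(pass1)) * 1000 / fs)
  }
  keep <- prune(loc_max, refr_ms * fs / 1000)
  keep <- keep[keep > 1 & keep < length(e)]

  vert <- parabolic_vertex(e[keep - 1], e[keep], e[keep + 1], keep)
  r_ms <- (vert - delay - 1) / fs * 1000
  r_ms <- r_ms[r_ms >= record$time_ms[1] & r_ms <= record$time_ms[length(e)]]
  tibble(beat = seq_along(r_ms), r_ms = r_ms)
}

as_r_times <- function(r_peaks) {
  if (is.data.frame(r_peaks)) r_peaks$r_ms else as.numeric(r_peaks)
}
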