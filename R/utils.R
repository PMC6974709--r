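# Internal helpers shared across modules.

# Stop with a consistent error class so tests can assert on failures.
stop_cardioage <- function(msg, class = "cardioage_error") {
  rlang::abort(msg, class = class)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_cardioage(msg)
  invisible(TRUE)
}

# Sampling rate (Hz) from a time axis in ms, unless given explicitly.
infer_fs <- function(record, fs = NULL) {
  if (!is.null(fs)) return(fs)
  dt <- diff(record$time_ms)
  assert_that(length(dt) >= 1 && all(is.finite(dt)) && all(dt > 0),
              "cannot infer sampling rate: time_ms must be strictly increasing")
  1000 / median(dt)
}

as_ecg_record <- function(mv, fs, t0_ms = 0) {
  tibble(time_ms = t0_ms + (seq_along(mv) - 1) * 1000 / fs, mv = as.numeric(mv))
}

check_ecg_record <- function(record) {
  assert_that(is.data.frame(record) && all(c("time_ms", "mv") %in% names(record)),
              "an ECG record is a data frame with columns `time_ms` and `mv`")
  assert_that(all(is.finite(record$mv)), "ECG record contains non-finite samples")
  invisible(record)
}

#' Vertex of the parabola through three equally spaced samples
#'
#' Sub-sample peak localization used by the R-peak detector: the vertex of the
#' parabola through `(i-1, y1)`, `(i, y2)`, `(i+1, y3)`. For a symmetric triple
#' the vertex is exactly `i`.
#'
#' @param y1,y2,y3 Sample values at positions `i - 1`, `i`, `i + 1`.
#' @param i Index (any real unit) of the central sample.
#' @return Vertex position in the units of `i`.
#' @examples
#' parabolic_vertex(1, 3, 1, 10) # exactly 10
#' parabolic_vertex(1, 3, 2, 10) # 10 + 1/6
#' @export
parabolic_vertex <- function(y1, y2, y3, i = 0) {
  denom <- y1 - 2 * y2 + y3
  delta <- ifelse(abs(denom) < .Machine$double.eps, 0, (y1 - y3) / (2 * denom))
  i + delta
}

# Linear interpolation of the time at which `y` first crosses `level` between
# consecutive samples, scanning indices `idx` (must be contiguous).
# direction = "down": first crossing from above to <= level.
cross_time <- function(t, y, level, direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (direction == "up") {
    hit <- which(y[-1] >= level & y[-length(y)] < level)
  } else {
    hit <- which(y[-1] <= level & y[-length(y)] > level)
  }
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  frac <- (level - y[i]) / (y[i + 1] - y[i])
  t[i] + frac * (t[i + 1] - t[i])
}

signif_marks <- function(p) {
  dplyr::case_when(
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ ""
  )
}
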