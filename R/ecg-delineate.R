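# Adaptive beat segmentation, fiducial-point delineation, interval and HRV
# measurement.

#' Adaptive P/T analysis windows from RR context
#'
#' Windows scale with the local RR interval: the P window spans
#' `[R - f_p * RR_prev, R - g_p * RR_prev]` and the T window
#' `[R + g_t * RR_next, R + f_t * RR_next]`. Windows are clipped so they never
#' enter the QRS guard band and consecutive beats' windows stay disjoint.
#'
#' @param r_peaks R times: tibble from [detect_r_peaks()] or a numeric vector
#'   of ms.
#' @param f_p,g_p P-window fractions of the preceding RR.
#' @param g_t,f_t T-window fractions of the following RR.
#' @param guard_ms QRS guard band half-width (ms).
#' @return Tibble with per-beat window bounds (`p_start_ms`, `p_end_ms`,
#'   `t_start_ms`, `t_end_ms`) and the RR context used.
#' @export
segment_beats <- function(r_peaks, f_p = 0.45, g_p = 0.05,
                          g_t = 0.08, f_t = 0.52, guard_ms = 4) {
  r <- as_r_times(r_peaks)
  assert_that(length(r) >= 2, "need at least 2 R detections for RR context")
  assert_that(f_p > g_p && f_t > g_t, "window fractions must satisfy f > g")
  rr <- diff(r)
  rr_prev <- c(rr[1], rr)
  rr_next <- c(rr, rr[length(rr)])
  w <- tibble(
    beat = seq_along(r),
    r_ms = r,
    rr_prev_ms = rr_prev,
    rr_next_ms = rr_next,
    p_start_ms = r - f_p * rr_prev,
    p_end_ms = pmin(r - g_p * rr_prev, r - guard_ms),
    t_start_ms = pmax(r + g_t * rr_next, r + guard_ms),
    t_end_ms = r + f_t * rr_next
  )
  # Disjointness across consecutive beats: clip T end at the next P start.
  nxt_p <- c(w$p_start_ms[-1], Inf)
  w$t_end_ms <- pmin(w$t_end_ms, nxt_p)
  w
}

#' Delineation parameter set
#'
#' @param p_cutoff_hz,t_cutoff_hz Measurement smoothing cutoffs for the P and
#'   T windows. Murine P/T waves carry energy well above 20 Hz, so the
#'   measurement default is higher than the conventional 20 Hz display
#'   smoothing.
#' @param qrs_cutoff_hz Smoothing cutoff for Q/S measurement.
#' @param slope_frac Slope-threshold level as a fraction of the wave's peak
#'   upstroke/downstroke slope; the measured crossing is mapped to the
#'   3-sigma onset convention by Gaussian self-calibration.
#' @param k_mad Robust noise floor multiplier for the slope threshold.
#' @param min_wave_amp_mv Minimum wave amplitude (vs baseline) to accept a
#'   P/Q/T wave.
#' @param q_search_ms,q_gap_ms,s_search_ms,s_gap_ms QRS search windows
#'   around R (ms).
#' @param t90_mode `"by"`: T90 is the decline BY 90% of the peak-to-baseline
#'   amplitude (standard murine convention, crossing at 10% amplitude);
#'   `"to"`: decline TO 90% (crossing at 90% amplitude).
#' @param pq_window_ms `c(from, to)` ms before R defining the PQ
#'   (isoelectric) segment used for the baseline level; the median is pooled
#'   over all beats of the record.
#' @param t_sign,p_sign Expected polarity (+1/-1) of the T and P waves.
#' @param kaiser_beta Kaiser window parameter for the measurement filters.
#' @return A named list of parameters for [delineate()].
#' @export
delineate_params <- function(p_cutoff_hz = 70, qrs_cutoff_hz = 150,
                             t_cutoff_hz = 70, slope_frac = 0.3, k_mad = 3,
                             min_wave_amp_mv = 0.04,
                             q_search_ms = 14, q_gap_ms = 1.5,
                             s_search_ms = 14, s_gap_ms = 1.5,
                             t90_mode = c("by", "to"),
                             t_sign = 1, p_sign = 1,
                             pq_window_ms = c(16, 10),
                             kaiser_beta = 5) {
  list(p_cutoff_hz = p_cutoff_hz, qrs_cutoff_hz = qrs_cutoff_hz,
       t_cutoff_hz = t_cutoff_hz, slope_frac = slope_frac, k_mad = k_mad,
       min_wave_amp_mv = min_wave_amp_mv,
       q_search_ms = q_search_ms, q_gap_ms = q_gap_ms,
       s_search_ms = s_search_ms, s_gap_ms = s_gap_ms,
       t90_mode = match.arg(t90_mode), t_sign = t_sign, p_sign = p_sign,
       pq_window_ms = pq_window_ms, kaiser_beta = kaiser_beta)
}

# ---- Gaussian self-calibration -------------------------------------------
# Amplitude/slope-threshold fiducials measured after low-pass smoothing are
# biased by the filter's pulse broadening. Both estimators are calibrated at
# run time: clean Gaussian pulses of known sigma are pushed through the SAME
# kernel and measurement code, giving a monotone map from measured offset to
# the true convention (onset at center - 3 sigma; T90 at
# center + sigma * sqrt(2 * log(1/frac))).

# Monotone (isotonic) fit of a flank before threshold crossing: under
# correlated noise a raw "first crossing" fires systematically early; the
# isotonic projection removes the wiggles without shifting a clean flank.
iso_increasing <- function(y) stats::isoreg(seq_along(y), y)$yf
iso_decreasing <- function(y) -stats::isoreg(seq_along(y), -y)$yf

onset_from_slope <- function(t, y, peak_idx, slope_frac, thr_floor = 0) {
  d <- c(NA, diff(y)) / c(NA, diff(t))
  up <- d[seq_len(peak_idx)]
  if (all(is.na(up))) return(NA_real_)
  i_smax <- which.max(up)
  s_max <- up[i_smax]
  if (!is.finite(s_max) || s_max <= 0 || i_smax < 3) return(NA_real_)
  thr <- max(slope_frac * s_max, thr_floor)
  upstroke <- up[2:i_smax] # drop the leading NA
  fit <- iso_increasing(upstroke)
  tt <- t[2:i_smax]
  below <- which(fit < thr)
  if (length(below) == 0 || max(below) >= length(fit)) return(NA_real_)
  i <- max(below)
  approx(c(fit[i], fit[i + 1]), c(tt[i], tt[i + 1]), xout = thr,
         ties = "ordered")$y
}

calib_grid_sigmas <- function() c(seq(0.6, 3, by = 0.2), seq(3.5, 18, by = 0.5))

calib_onset_map <- function(h, fs, slope_frac) {
  dt <- 1000 / fs
  purrr::map_dfr(calib_grid_sigmas(), function(sig) {
    t <- seq(-8 * sig, 8 * sig, by = dt)
    y <- conv_same(exp(-t^2 / (2 * sig^2)), h)
    pk <- which.max(y)
    cross <- onset_from_slope(t, y, pk, slope_frac)
    tibble(measured = t[pk] - cross, true = 3 * sig)
  })
}

calib_t90_map <- function(h, fs, frac) {
  dt <- 1000 / fs
  purrr::map_dfr(calib_grid_sigmas(), function(sig) {
    t <- seq(-8 * sig, 10 * sig, by = dt)
    y <- conv_same(exp(-t^2 / (2 * sig^2)), h)
    pk <- which.max(y)
    level <- frac * y[pk]
    dec <- iso_decreasing(y[pk:length(y)])
    cross <- cross_time(t[pk:length(t)], dec, level, "down")
    tibble(measured = cross - t[pk], true = sig * sqrt(2 * log(1 / frac)))
  })
}

apply_calib <- function(map, measured) {
  ok <- is.finite(map$measured) & is.finite(map$true)
  approx(map$measured[ok], map$true[ok], xout = measured, rule = 2)$y
}

# ---- Delineation ----------------------------------------------------------

#' Delineate fiducial points for every detected beat
#'
#' Per beat: the baseline is the median of the P window; P onset and Q onset
#' are located by a finite-difference slope threshold (relative to the wave's
#' own peak slope, mapped to the 3-sigma onset convention by Gaussian
#' self-calibration against the smoothing kernel); S end is the first
#' baseline crossing after the S trough; T peak is the extremum of the
#' smoothed T window; T90 is the first point after the T peak where the
#' amplitude has declined by 90% of the peak-to-baseline amplitude. Beats
#' violating the ordering invariant
#' `P onset < Q onset < R < S end < T peak < T90`, or missing any wave, are
#' QC-rejected with a reason, never silently fixed.
#'
#' @param record Preprocessed ECG record (band-passed, baseline-corrected).
#' @param r_peaks R detections ([detect_r_peaks()] output or numeric ms).
#' @param windows Per-beat windows from [segment_beats()]; computed from
#'   `r_peaks` when `NULL`.
#' @param fs Sampling rate (Hz); inferred when `NULL`.
#' @param params Parameter list from [delineate_params()].
#' @return Tibble with per-beat fiducial times (ms), `accepted` flag and
#'   `reject_reason`.
#' @export
delineate <- function(record, r_peaks, windows = NULL, fs = NULL,
                      params = delineate_params()) {
  check_ecg_record(record)
  fs <- infer_fs(record, fs)
  r <- as_r_times(r_peaks)
  windows <- windows %||% segment_beats(r)
  t_ms <- record$time_ms
  x <- record$mv
  dt <- 1000 / fs

  h_p <- design_fir_lowpass(fs, params$p_cutoff_hz, params$kaiser_beta)
  h_q <- design_fir_lowpass(fs, params$qrs_cutoff_hz, params$kaiser_beta)
  h_t <- design_fir_lowpass(fs, params$t_cutoff_hz, params$kaiser_beta)
  t90_frac <- if (params$t90_mode == "by") 0.1 else 0.9
  map_on_p <- calib_onset_map(h_p, fs, params$slope_frac)
  map_on_q <- calib_onset_map(h_q, fs, params$slope_frac)
  map_t90 <- calib_t90_map(h_t, fs, t90_frac)

  # Smooth the whole record once per kernel (zero phase); windows are then
  # plain index slices, avoiding reflect-padding artifacts at window edges
  # that sit on steep QRS flanks.
  xs_p <- conv_same(x, h_p)
  xs_q <- conv_same(x, h_q)
  xs_t <- conv_same(x, h_t)

  idx_range <- function(a, b) {
    i0 <- max(1L, ceiling(a / dt) + 1L)
    i1 <- min(length(x), floor(b / dt) + 1L)
    if (i0 + 2 >= i1) NULL else i0:i1
  }

  # Record-level isoelectric baseline: median over the pooled PQ segments of
  # all beats (the PQ segment is the flattest part of a murine beat; pooling
  # averages noise out and residual drift is already high-passed away).
  pq_idx <- unlist(lapply(r, function(r_ms) {
    idx_range(r_ms - params$pq_window_ms[1], r_ms - params$pq_window_ms[2])
  }))
  baseline_global <- if (length(pq_idx) >= 5) median(x[pq_idx]) else NA_real_

  one_beat <- function(beat, r_ms, p_start_ms, p_end_ms, t_start_ms,
                       t_end_ms, ...) {
    res <- tibble(beat = beat, r_ms = r_ms, p_on_ms = NA_real_,
                  q_on_ms = NA_real_, s_end_ms = NA_real_,
                  t_peak_ms = NA_real_, t90_ms = NA_real_,
                  accepted = FALSE, reject_reason = NA_character_)
    reject <- function(reason) {
      res$reject_reason <- reason
      res
    }

    ip <- idx_range(p_start_ms, p_end_ms)
    if (is.null(ip)) return(reject("window-out-of-record"))
    pseg <- xs_p[ip]
    baseline <- if (is.finite(baseline_global)) baseline_global
                else median(x[ip])

    # --- P wave ---
    dev_p <- params$p_sign * (pseg - baseline)
    pk_p <- which.max(dev_p)
    if (dev_p[pk_p] < params$min_wave_amp_mv) return(reject("no-P"))
    cross_p <- onset_from_slope(t_ms[ip], dev_p, pk_p, params$slope_frac)
    if (is.na(cross_p)) return(reject("no-P"))
    res$p_on_ms <- t_ms[ip][pk_p] - apply_calib(map_on_p,
                                                t_ms[ip][pk_p] - cross_p)

    # --- Q onset ---
    iq <- idx_range(r_ms - params$q_search_ms, r_ms - params$q_gap_ms)
    if (is.null(iq)) return(reject("no-Q"))
    qseg <- xs_q[iq]
    dev_q <- -(qseg - baseline) # Q is a negative deflection
    pk_q <- which.max(dev_q)
    if (dev_q[pk_q] < params$min_wave_amp_mv) return(reject("no-Q"))
    cross_q <- onset_from_slope(t_ms[iq], dev_q, pk_q, params$slope_frac)
    if (is.na(cross_q)) return(reject("no-Q"))
    res$q_on_ms <- t_ms[iq][pk_q] - apply_calib(map_on_q,
                                                t_ms[iq][pk_q] - cross_q)

    # --- S end: first baseline crossing after the S trough ---
    is_ <- idx_range(r_ms + params$s_gap_ms, r_ms + params$s_search_ms)
    if (is.null(is_)) return(reject("no-S-end"))
    sseg <- xs_q[is_]
    tr <- which.min(sseg)
    if (tr >= length(sseg)) return(reject("no-S-end"))
    s_rise <- iso_increasing(sseg[tr:length(sseg)])
    res$s_end_ms <- cross_time(t_ms[is_][tr:length(sseg)], s_rise,
                               baseline, "up")
    if (is.na(res$s_end_ms)) return(reject("no-S-end"))

    # --- T wave and T90 ---
    it <- idx_range(t_start_ms, t_end_ms)
    if (is.null(it)) return(reject("no-T"))
    tseg <- xs_t[it]
    dev_t <- params$t_sign * (tseg - baseline)
    pk_t <- which.max(dev_t)
    if (dev_t[pk_t] < params$min_wave_amp_mv) return(reject("no-T"))
    res$t_peak_ms <- t_ms[it][pk_t]
    level <- t90_frac * dev_t[pk_t]
    t_dec <- iso_decreasing(dev_t[pk_t:length(dev_t)])
    tau <- cross_time(t_ms[it][pk_t:length(dev_t)], t_dec, level, "down")
    if (is.na(tau)) return(reject("no-T90"))
    res$t90_ms <- res$t_peak_ms + apply_calib(map_t90, tau - res$t_peak_ms)

    # --- QC ordering invariant ---
    ord <- c(res$p_on_ms, res$q_on_ms, res$r_ms, res$s_end_ms,
             res$t_peak_ms, res$t90_ms)
    if (any(!is.finite(ord)) || any(diff(ord) <= 0)) return(reject("ordering"))
    res$accepted <- TRUE
    res
  }

  purrr::pmap_dfr(windows, one_beat)
}

#' Per-beat intervals from delineated fiducials
#'
#' PR = R - P onset; QRS = S end - Q onset; QT = T90 - Q onset;
#' RR = R - previous R. Rejected beats keep their row with `NA` intervals and
#' are excluded from summaries downstream.
#'
#' @param fiducials Output of [delineate()].
#' @return Tibble `beat`, `pr_ms`, `qrs_ms`, `qt_ms`, `rr_ms`, `accepted`.
#' @export
measure_intervals <- function(fiducials) {
  dplyr::transmute(
    fiducials,
    beat = .data$beat,
    pr_ms = ifelse(.data$accepted, .data$r_ms - .data$p_on_ms, NA_real_),
    qrs_ms = ifelse(.data$accepted, .data$s_end_ms - .data$q_on_ms, NA_real_),
    qt_ms = ifelse(.data$accepted, .data$t90_ms - .data$q_on_ms, NA_real_),
    rr_ms = c(NA_real_, diff(.data$r_ms)),
    accepted = .data$accepted
  )
}

#' Heart-rate-variability summary over detected beats
#'
#' SDNN is the standard deviation of the RR series; RMSSD the root mean
#' square of successive RR differences.
#'
#' @param r_peaks R detections (tibble or numeric ms).
#' @return One-row tibble: `mean_rr_ms`, `sdnn_ms`, `rmssd_ms`, `n_beats`.
#' @export
hrv_summary <- function(r_peaks) {
  r <- as_r_times(r_peaks)
  assert_that(length(r) >= 3, "HRV summary needs at least 3 beats")
  rr <- diff(r)
  tibble(
    mean_rr_ms = mean(rr),
    sdnn_ms = sd(rr),
    rmssd_ms = sqrt(mean(diff(rr)^2)),
    n_beats = length(r)
  )
}

#' Per-record interval summary
#'
#' Mean and median PR/QRS/QT/RR over QC-accepted beats, with acceptance
#' counts. Errors when no beat was accepted.
#'
#' @param intervals Output of [measure_intervals()].
#' @param condition Optional condition label carried into the summary.
#' @return One-row tibble of summary statistics.
#' @export
summarize_record <- function(intervals, condition = NULL) {
  acc <- dplyr::filter(intervals, .data$accepted)
  assert_that(nrow(acc) >= 1, "no accepted beats to summarize")
  out <- tibble(
    condition = condition %||% NA_character_,
    n_detected = nrow(intervals),
    n_accepted = nrow(acc),
    n_rejected = nrow(intervals) - nrow(acc),
    pr_mean_ms = mean(acc$pr_ms), pr_median_ms = median(acc$pr_ms),
    qrs_mean_ms = mean(acc$qrs_ms), qrs_median_ms = median(acc$qrs_ms),
    qt_mean_ms = mean(acc$qt_ms), qt_median_ms = median(acc$qt_ms),
    rr_mean_ms = mean(acc$rr_ms, na.rm = TRUE),
    rr_median_ms = median(acc$rr_ms, na.rm = TRUE)
  )
  out
}

#' Full single-record ECG analysis chain
#'
#' Band-pass -> baseline removal -> wavelet R detection -> adaptive
#' segmentation -> delineation -> intervals, HRV and record summary.
#'
#' @param record Raw ECG record (`time_ms`, `mv`).
#' @param fs Sampling rate (Hz); inferred when `NULL`.
#' @param condition Optional condition label (e.g. baseline / challenge).
#' @param bandpass_low_hz,bandpass_high_hz,baseline_cutoff_hz Filter
#'   settings.
#' @param params Delineation parameters ([delineate_params()]).
#' @return An object of class `ecg_analysis`: list with `filtered`,
#'   `r_peaks`, `windows`, `fiducials`, `intervals`, `hrv`, `summary`, `fs`.
#' @export
ecg_analyze <- function(record, fs = NULL, condition = NULL,
                        bandpass_low_hz = 0.5, bandpass_high_hz = 250,
                        baseline_cutoff_hz = 1.5,
                        params = delineate_params()) {
  fs <- infer_fs(record, fs)
  filt <- ecg_bandpass(record, fs, bandpass_low_hz, bandpass_high_hz)
  filt <- ecg_remove_baseline(filt, fs, baseline_cutoff_hz)
  r_peaks <- detect_r_peaks(filt, fs)
  windows <- segment_beats(r_peaks)
  fid <- delineate(filt, r_peaks, windows, fs, params)
  intervals <- measure_intervals(fid)
  structure(
    list(filtered = filt, r_peaks = r_peaks, windows = windows,
         fiducials = fid, intervals = intervals,
         hrv = hrv_summary(r_peaks),
         summary = summarize_record(intervals, condition), fs = fs),
    class = "ecg_analysis"
  )
}

#' @export
print.ecg_analysis <- function(x, ...) {
  cat("<ecg_analysis>", x$summary$n_accepted, "of", x$summary$n_detected,
      "beats accepted\n")
  print(x$summary)
  invisible(x)
}
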