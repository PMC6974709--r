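# Deterministic derived metrics: echocardiographic formulas, OGTT AUC,
# adipokine and heart-weight ratios. All pure arithmetic, unit-annotated.

#' Left-ventricular fractional shortening
#'
#' `FS = 100 * (LVIDd - LVIDs) / LVIDd` (percent).
#'
#' @param lvidd_mm,lvids_mm End-diastolic / end-systolic LV internal
#'   diameter (mm).
#' @return FS in percent.
#' @export
fractional_shortening <- function(lvidd_mm, lvids_mm) {
  assert_that(all(lvidd_mm > 0), "LVIDd must be positive")
  if (any(lvids_mm >= lvidd_mm)) {
    rlang::warn("LVIDs >= LVIDd: non-physiological input")
  }
  100 * (lvidd_mm - lvids_mm) / lvidd_mm
}

#' Teichholz M-mode LV volume
#'
#' `V(D) = 7.0 / (2.4 + D) * D^3` microlitres, `D` in mm.
#'
#' @param d_mm LV internal diameter (mm).
#' @return Volume in microlitres.
#' @export
teichholz_volume <- function(d_mm) {
  assert_that(all(d_mm > 0), "diameter must be positive")
  7.0 / (2.4 + d_mm) * d_mm^3
}

#' Ejection fraction by the Teichholz formula
#'
#' `EF = 100 * (V(LVIDd) - V(LVIDs)) / V(LVIDd)` with the Teichholz volume.
#'
#' @inheritParams fractional_shortening
#' @return EF in percent.
#' @export
ef_teichholz <- function(lvidd_mm, lvids_mm) {
  vd <- teichholz_volume(lvidd_mm)
  vs <- teichholz_volume(lvids_mm)
  100 * (vd - vs) / vd
}

#' M-mode LV mass (cubed formula) and corrected LV mass
#'
#' `LV mass (mg) = 1.05 * ((LVIDd + LVPWd + IVSd)^3 - LVIDd^3) * 0.8`;
#' `corrected = 0.8 * mass`. Both values are reported.
#'
#' @param lvidd_mm LV end-diastolic internal diameter (mm).
#' @param lvpwd_mm Diastolic posterior wall thickness (mm).
#' @param ivsd_mm Diastolic interventricular septum thickness (mm).
#' @return Tibble with `lv_mass_mg` and `lv_mass_corr_mg`.
#' @export
lv_mass <- function(lvidd_mm, lvpwd_mm, ivsd_mm) {
  assert_that(all(lvidd_mm > 0) && all(lvpwd_mm >= 0) && all(ivsd_mm >= 0),
              "diameters must be positive, walls non-negative")
  mass <- 1.05 * ((lvidd_mm + lvpwd_mm + ivsd_mm)^3 - lvidd_mm^3) * 0.8
  tibble(lv_mass_mg = mass, lv_mass_corr_mg = 0.8 * mass)
}

#' Derive echocardiographic metrics for a cohort table
#'
#' Appends FS, Teichholz EF and (when wall thicknesses are present) LV mass
#' columns to a per-animal table with columns `lvidd_mm`, `lvids_mm` and
#' optionally `lvpwd_mm`, `ivsd_mm`.
#'
#' @param data Data frame of M-mode measurements.
#' @return The input tibble with derived columns appended.
#' @export
echo_derive <- function(data) {
  out <- as_tibble(data)
  out$fs_pct <- fractional_shortening(out$lvidd_mm, out$lvids_mm)
  out$ef_pct <- ef_teichholz(out$lvidd_mm, out$lvids_mm)
  if (all(c("lvpwd_mm", "ivsd_mm") %in% names(out))) {
    out <- dplyr::bind_cols(out, lv_mass(out$lvidd_mm, out$lvpwd_mm,
                                         out$ivsd_mm))
  }
  out
}

#' Area under an OGTT glucose curve (trapezoidal rule)
#'
#' @param time_min Strictly increasing sample times (minutes from bolus).
#' @param glucose_mg_dl Glucose values (mg/dl).
#' @return AUC in mg.min/dl.
#' @export
ogtt_auc <- function(time_min, glucose_mg_dl) {
  assert_that(length(time_min) >= 2, "need at least 2 time points")
  assert_that(all(diff(time_min) > 0), "times must be strictly increasing")
  assert_that(length(time_min) == length(glucose_mg_dl),
              "times and glucose values must align")
  sum(diff(time_min) * (head(glucose_mg_dl, -1) + tail(glucose_mg_dl, -1)) / 2)
}

#' Adipokine and heart-weight ratios
#'
#' Leptin/adiponectin ratio (on the stated ng/ml over ug/ml units) and heart
#' weight normalized to body weight (mg/g).
#'
#' @param leptin_ng_ml,adiponectin_ug_ml Serum adipokine levels.
#' @param heart_mg,body_g Organ and body weight.
#' @return Tibble with `leptin_adiponectin` and/or `heart_body_mg_g`.
#' @export
metabolic_ratios <- function(leptin_ng_ml = NULL, adiponectin_ug_ml = NULL,
                             heart_mg = NULL, body_g = NULL) {
  out <- tibble(.rows = max(length(leptin_ng_ml), length(heart_mg), 1))
  if (!is.null(leptin_ng_ml)) {
    assert_that(all(adiponectin_ug_ml > 0), "adiponectin must be positive")
    out$leptin_adiponectin <- leptin_ng_ml / adiponectin_ug_ml
  }
  if (!is.null(heart_mg)) {
    assert_that(all(body_g > 0), "body weight must be positive")
    out$heart_body_mg_g <- heart_mg / body_g
  }
  out
}
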