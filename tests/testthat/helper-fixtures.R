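# Shared fixtures. Expensive artefacts (the full-cohort calibration) are
# computed once per test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

bundled_cohort <- function() cached("cohort", load_cohort("bundled"))

bundled_calibration <- function() {
  cached("calibration", calibrate_cohort(bundled_cohort()))
}

bundled_record <- function(id, lesion = 1L) {
  dplyr::filter(bundled_cohort(), .data$patient_id == id, .data$lesion_index == lesion)
}

# A lesion that never receives dose (zero-height pulses).
untreated_record <- function(v_pre_cm3 = 1, followup = 30) {
  tibble::tibble(
    patient_id = "U01", lesion_index = 1L,
    total_dose_gy = 0, n_fractions = 1L, treatment_days = list(1L),
    followup_days = followup, v_pre_cm3 = v_pre_cm3, v_post_cm3 = v_pre_cm3,
    not_measurable = FALSE, in_regimen_stats = TRUE,
    mld_gy = NA_real_, tlv_cm3 = NA_real_, v5_pct = NA_real_, v20_pct = NA_real_
  )
}
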