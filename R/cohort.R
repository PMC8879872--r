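# Lesion-level cohort I/O and dose schedules ---------------------------------

cohort_columns <- c(
  patient_id = "c", lesion_index = "i", total_dose_gy = "d", n_fractions = "i",
  treatment_days = "c", followup_days = "d", v_pre_cm3 = "d", v_post_cm3 = "d",
  not_measurable = "l", in_regimen_stats = "l",
  mld_gy = "d", tlv_cm3 = "d", v5_pct = "d", v20_pct = "d"
)

# Fraction-day patterns present in the bundled cohort, keyed by fraction count.
day_patterns <- list(
  `1` = list(1L),
  `3` = list(c(1L, 3L, 6L), c(1L, 4L, 6L), c(3L, 5L, 7L), c(1L, 3L, 7L), c(1L, 2L, 6L)),
  `4` = list(c(1L, 3L, 5L, 8L), c(1L, 3L, 6L, 8L), c(1L, 3L, 6L, 9L), c(2L, 6L, 8L, 10L),
             c(1L, 3L, 7L, 9L), c(1L, 3L, 7L, 10L), c(1L, 3L, 8L, 11L), c(2L, 4L, 7L, 9L)),
  `8` = list(c(1L, 3L, 6L, 8L, 10L, 13L, 15L, 17L))
)

parse_days <- function(x) {
  lapply(strsplit(as.character(x), "-", fixed = TRUE), function(d) as.integer(d))
}

format_days <- function(days) {
  vapply(days, function(d) paste(d, collapse = "-"), character(1))
}

#' Load a lesion-level cohort table
#'
#' Reads a cohort CSV (one row per treated lesion) and validates it. With
#' `path = "bundled"` the reference cohort shipped with the package is
#' loaded: 19 patients, 23 lesions, with per-lesion dose, fractionation
#' calendar, follow-up interval and the two gross tumour volume (GTV)
#' measurements in cm^3. Post-treatment volumes recorded as not measurable
#' on follow-up CT are encoded as `v_post_cm3 = 0` with
#' `not_measurable = TRUE`. The `in_regimen_stats` flag marks the 21 lesions
#' that enter per-regimen efficacy means (see [regimen_efficacy()]).
#'
#' @param path Path to a cohort CSV, or `"bundled"`.
#' @return A tibble with one row per lesion; `treatment_days` is a
#'   list-column of strictly increasing 1-based day indices.
#' @examples
#' cohort <- load_cohort("bundled")
#' nrow(cohort)
#' dplyr::n_distinct(cohort$patient_id)
#' @export
load_cohort <- function(path = "bundled") {
  if (identical(path, "bundled")) {
    path <- system.file("extdata", "cohort_table2.csv", package = "sbrtpkpd")
  }
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  header <- tryCatch(names(utils::read.csv(path, nrows = 1, check.names = FALSE)),
                     error = function(e) stop("cohort file is empty or unreadable: ",
                                              path, call. = FALSE))
  missing_cols <- setdiff(names(cohort_columns), header)
  if (length(missing_cols)) {
    stop("cohort file is missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  spec <- do.call(readr::cols, c(
    lapply(cohort_columns, function(t) {
      switch(t, c = readr::col_character(), i = readr::col_integer(),
             d = readr::col_double(), l = readr::col_logical())
    }),
    list(.default = readr::col_guess())
  ))
  raw <- tryCatch(
    readr::read_csv(path, col_types = spec, progress = FALSE),
    error = function(e) stop("failed to parse cohort CSV: ", conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0) stop("cohort file is empty: ", path, call. = FALSE)
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("non-numeric or malformed value in cohort row ", prob$row[1],
         " (column ", prob$col[1], ")", call. = FALSE)
  }
  cohort <- raw |>
    dplyr::select(dplyr::all_of(names(cohort_columns))) |>
    dplyr::mutate(treatment_days = parse_days(.data$treatment_days))
  validate_cohort(cohort)
  cohort
}

#' Validate a cohort tibble
#'
#' Checks the per-lesion invariants: positive pre-treatment volume,
#' non-negative post-treatment volume, one treatment day per fraction,
#' strictly increasing day indices, and follow-up measured no earlier than
#' the last fraction. Validation failures name the offending lesion and
#' field.
#'
#' @param cohort A cohort tibble as returned by [load_cohort()].
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  fail <- function(i, field, msg) {
    stop(sprintf("invalid cohort row (patient %s, lesion %d): %s [%s]",
                 cohort$patient_id[i], cohort$lesion_index[i], msg, field),
         call. = FALSE)
  }
  for (i in seq_len(nrow(cohort))) {
    days <- cohort$treatment_days[[i]]
    if (is.na(cohort$v_pre_cm3[i]) || cohort$v_pre_cm3[i] <= 0)
      fail(i, "v_pre_cm3", "pre-treatment volume must be > 0")
    if (is.na(cohort$v_post_cm3[i]) || cohort$v_post_cm3[i] < 0)
      fail(i, "v_post_cm3", "post-treatment volume must be >= 0")
    if (is.na(cohort$total_dose_gy[i]) || cohort$total_dose_gy[i] < 0)
      fail(i, "total_dose_gy", "total dose must be >= 0")
    if (any(is.na(days)))
      fail(i, "treatment_days", "day list must be numeric")
    if (length(days) != cohort$n_fractions[i])
      fail(i, "treatment_days", sprintf("%d treatment day(s) for %d fraction(s)",
                                        length(days), cohort$n_fractions[i]))
    if (length(days) > 1 && any(diff(days) <= 0))
      fail(i, "treatment_days", "day indices must be strictly increasing")
    if (max(days) > cohort$followup_days[i])
      fail(i, "followup_days", "follow-up precedes the last fraction")
  }
  invisible(cohort)
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(x, path))` returns a
#' cohort identical to `x`.
#'
#' @param cohort Cohort tibble (may have zero rows, giving a header-only file).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (nrow(cohort) > 0) validate_cohort(cohort)
  out <- cohort |>
    dplyr::mutate(treatment_days = format_days(.data$treatment_days)) |>
    dplyr::select(dplyr::all_of(names(cohort_columns)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Build the radiotherapy dosing schedule for a lesion
#'
#' Converts a lesion's fraction calendar into the forcing function of the
#' model: one rectangular dose-rate pulse per fraction, each delivering
#' `total_dose / n_fractions` Gy over `pulse_width` days, starting at the
#' beginning of its treatment day (elapsed time; the first treatment day is
#' t = 0). The integral of the forcing equals the printed total dose
#' exactly.
#'
#' @param record A one-row cohort tibble (or equivalent named list).
#' @param pulse_width Pulse width in days; must be positive, below one day,
#'   and below the smallest inter-fraction gap.
#' @return An object of class `pkpd_schedule`: fraction dose (Gy), pulse
#'   start times (days), pulse width (days), dose rate during a pulse
#'   (Gy/day), and the treatment duration (span from first to last fraction
#'   day, inclusive).
#' @examples
#' rec <- load_cohort("bundled") |> dplyr::filter(patient_id == "019")
#' build_schedule(rec)
#' @export
build_schedule <- function(record, pulse_width = 0.1) {
  days <- if (is.list(record$treatment_days[[1]]) || length(record$treatment_days) == 1) {
    record$treatment_days[[1]]
  } else {
    record$treatment_days
  }
  days <- as.numeric(days)
  if (!is.numeric(pulse_width) || length(pulse_width) != 1 || pulse_width <= 0) {
    stop("'pulse_width' must be a positive number of days", call. = FALSE)
  }
  if (pulse_width >= 1) stop("'pulse_width' must be below one day", call. = FALSE)
  if (length(days) != record$n_fractions) {
    stop(sprintf("fraction-count/day-list mismatch for patient %s lesion %d",
                 record$patient_id, record$lesion_index), call. = FALSE)
  }
  gaps <- if (length(days) > 1) diff(days) else Inf
  if (any(gaps <= 0)) stop("treatment days must be strictly increasing", call. = FALSE)
  if (pulse_width >= min(gaps)) {
    stop("'pulse_width' (", pulse_width, " d) would overlap fractions ",
         "(smallest inter-fraction gap ", min(gaps), " d)", call. = FALSE)
  }
  fraction_dose <- record$total_dose_gy / record$n_fractions
  structure(
    list(
      fraction_dose = fraction_dose,
      pulse_starts = days - min(days),
      pulse_width = pulse_width,
      dose_rate_during_pulse = fraction_dose / pulse_width,
      treatment_duration = max(days) - min(days) + 1,
      total_dose = record$total_dose_gy
    ),
    class = "pkpd_schedule"
  )
}

#' @export
print.pkpd_schedule <- function(x, ...) {
  cat(sprintf("<pkpd_schedule> %g Gy in %d fraction(s) of %g Gy\n",
              x$total_dose, length(x$pulse_starts), x$fraction_dose))
  cat(sprintf("  pulses start (elapsed days): %s\n", paste(x$pulse_starts, collapse = ", ")))
  cat(sprintf("  pulse width %g d, dose rate %g Gy/d, treatment duration %g d\n",
              x$pulse_width, x$dose_rate_during_pulse, x$treatment_duration))
  invisible(x)
}
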