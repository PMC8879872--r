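# Treatment-outcome statistics -----------------------------------------------

#' Treatment efficacy from pre/post volumes
#'
#' Percent reduction of the gross tumour volume between the planning CT and
#' the follow-up CT: `100 - 100 * v_post / v_pre`. 100 means complete
#' disappearance; negative values mean progression. The measure is
#' scale-invariant in the two volumes.
#'
#' @param v_pre Pre-treatment volume (cm^3), > 0 (vectorised).
#' @param v_post Post-treatment volume (cm^3), >= 0.
#' @return Efficacy in percent.
#' @examples
#' efficacy(10.5, 11)   # progression of the single 60 Gy lesion
#' efficacy(5.6, 4.6)
#' @export
efficacy <- function(v_pre, v_post) {
  if (any(v_pre <= 0)) stop("'v_pre' must be > 0", call. = FALSE)
  if (any(v_post < 0)) stop("'v_post' must be >= 0", call. = FALSE)
  100 - 100 * v_post / v_pre
}

regimen_label <- function(total_dose_gy, n_fractions) {
  paste0(total_dose_gy, " Gy/", n_fractions)
}

#' Per-lesion efficacy table
#'
#' @param cohort Cohort tibble.
#' @return A tibble with one row per lesion: regimen label, efficacy (%),
#'   and the response class (`decreased` when efficacy > 0, otherwise
#'   `stable_or_increased`).
#' @export
lesion_efficacy <- function(cohort) {
  cohort |>
    dplyr::mutate(
      regimen = regimen_label(.data$total_dose_gy, .data$n_fractions),
      efficacy_pct = efficacy(.data$v_pre_cm3, .data$v_post_cm3),
      response_class = ifelse(.data$efficacy_pct > 0, "decreased", "stable_or_increased")
    ) |>
    dplyr::select(dplyr::all_of(c("patient_id", "lesion_index", "regimen",
                                  "total_dose_gy", "n_fractions",
                                  "efficacy_pct", "response_class")))
}

#' Mean efficacy per fractionation regimen
#'
#' Unweighted mean of per-lesion efficacies within each (total dose, number
#' of fractions) group, over the lesions flagged `in_regimen_stats`.
#' Progressing lesions (negative efficacy) are included.
#'
#' @param cohort Cohort tibble.
#' @return A tibble keyed by regimen with lesion count and mean efficacy (%).
#' @examples
#' load_cohort("bundled") |> regimen_efficacy()
#' @export
regimen_efficacy <- function(cohort) {
  kept <- dplyr::filter(cohort, .data$in_regimen_stats)
  dropped <- dplyr::anti_join(
    dplyr::distinct(cohort, .data$total_dose_gy, .data$n_fractions),
    dplyr::distinct(kept, .data$total_dose_gy, .data$n_fractions),
    by = c("total_dose_gy", "n_fractions")
  )
  if (nrow(dropped) > 0) {
    warning("regimen group(s) without eligible lesions omitted: ",
            paste(regimen_label(dropped$total_dose_gy, dropped$n_fractions),
                  collapse = ", "), call. = FALSE)
  }
  kept |>
    lesion_efficacy() |>
    dplyr::group_by(.data$regimen, .data$total_dose_gy, .data$n_fractions) |>
    dplyr::summarise(
      n_lesions = dplyr::n(),
      mean_efficacy_pct = mean(.data$efficacy_pct),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$total_dose_gy, .data$n_fractions)
}

#' Response classification counts
#'
#' Partitions all lesions of the cohort into volume `decreased`
#' (efficacy > 0) and `stable_or_increased`.
#'
#' @param cohort Cohort tibble.
#' @return A tibble with columns `response_class` and `n`.
#' @export
classify_responses <- function(cohort) {
  lesion_efficacy(cohort) |>
    dplyr::count(
      response_class = factor(.data$response_class,
                              levels = c("decreased", "stable_or_increased")),
      .drop = FALSE, name = "n"
    ) |>
    dplyr::mutate(response_class = as.character(.data$response_class))
}

#' Regression of simulated on measured post-treatment volumes
#'
#' Ordinary least squares of the calibrated model's final volume on the
#' measured post-treatment GTV across lesions, with the Pearson correlation
#' and the root-mean-square difference between the two series (cm^3).
#'
#' @param cohort Cohort tibble.
#' @param calibration A `pkpd_calibration` object (or tibble with
#'   `patient_id`, `lesion_index`, `v_sim_final`).
#' @return A one-row tibble: `slope`, `intercept`, `r`, `rmse_cm3`, `n`.
#' @export
volume_regression <- function(cohort, calibration) {
  d <- cohort |>
    dplyr::inner_join(tibble::as_tibble(calibration),
                      by = c("patient_id", "lesion_index")) |>
    dplyr::filter(.data$converged)
  if (nrow(d) < 2) stop("regression needs at least two calibrated lesions", call. = FALSE)
  fit <- stats::lm(v_sim_final ~ v_post_cm3, data = d)
  degenerate <- stats::var(d$v_post_cm3) == 0 || stats::var(d$v_sim_final) == 0
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = if (degenerate) NA_real_ else stats::cor(d$v_post_cm3, d$v_sim_final),
    rmse_cm3 = sqrt(mean((d$v_sim_final - d$v_post_cm3)^2)),
    n = nrow(d)
  )
}

#' Initial-volume uncertainty analysis
#'
#' Re-simulates each lesion with its baseline volume perturbed by the given
#' fractions (decreased by default, mirroring measurement uncertainty in the
#' planning CT), holding the calibrated response exponent fixed, and reports
#' the percent change of the simulated final volume. For eradicated lesions
#' (baseline simulated final below 0.05 cm^3) a relative change is not
#' meaningful and the absolute change in mm^3 is reported instead
#' (`pct_change_final = NA`).
#'
#' @param cohort Cohort tibble.
#' @param calibration A `pkpd_calibration` object for this cohort.
#' @param params A [pkpd_params()] object (must match the calibration).
#' @param levels Perturbation fractions of the initial volume.
#' @param direction `"decrease"` (default) or `"increase"`.
#' @return A tibble with one row per (lesion, level): baseline and
#'   perturbed final volumes (cm^3), `pct_change_final`
#'   (`100 * |perturbed - baseline| / baseline`), `abs_change_mm3`, and an
#'   `eradicated` flag.
#' @export
sensitivity_analysis <- function(cohort, calibration, params = pkpd_params(),
                                 levels = c(0.05, 0.10, 0.20),
                                 direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  stopifnot(all(levels >= 0), all(levels < 1))
  sgn <- if (direction == "decrease") -1 else 1
  cal <- tibble::as_tibble(calibration) |> dplyr::filter(.data$converged)
  d <- dplyr::inner_join(cohort, cal, by = c("patient_id", "lesion_index"))
  purrr::map(seq_len(nrow(d)), function(i) {
    rec <- d[i, ]
    base <- simulate_final(rec, params, rec$gamma_hat)
    purrr::map(levels, function(lv) {
      pert_rec <- rec
      pert_rec$v_pre_cm3 <- rec$v_pre_cm3 * (1 + sgn * lv)
      pert <- if (lv == 0) base else simulate_final(pert_rec, params, rec$gamma_hat)
      eradicated <- base < 50   # 0.05 cm^3
      tibble::tibble(
        patient_id = rec$patient_id,
        lesion_index = rec$lesion_index,
        perturbation = lv,
        v_final_cm3 = base / 1000,
        v_final_pert_cm3 = pert / 1000,
        pct_change_final = if (eradicated) NA_real_ else 100 * abs(pert - base) / base,
        abs_change_mm3 = abs(pert - base),
        eradicated = eradicated
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Quartile summary of the uncertainty analysis
#'
#' @param sensitivity Output of [sensitivity_analysis()].
#' @return A tibble per perturbation level with the median and 25th/75th
#'   percentiles of the percent change in final volume (eradicated lesions
#'   excluded).
#' @export
sensitivity_summary <- function(sensitivity) {
  sensitivity |>
    dplyr::filter(!.data$eradicated) |>
    dplyr::group_by(.data$perturbation) |>
    dplyr::summarise(
      n = dplyr::n(),
      q25 = stats::quantile(.data$pct_change_final, 0.25),
      median = stats::median(.data$pct_change_final),
      q75 = stats::quantile(.data$pct_change_final, 0.75),
      .groups = "drop"
    )
}

#' Assemble the outcomes report
#'
#' Bundles regimen means, response counts, the measured-versus-simulated
#' regression, and the uncertainty-analysis quartiles into one list ready
#' for JSON serialisation.
#'
#' @param cohort Cohort tibble.
#' @param calibration A `pkpd_calibration` object.
#' @param params A [pkpd_params()] object.
#' @param levels Perturbation levels for the uncertainty analysis.
#' @return A named list.
#' @export
outcomes_report <- function(cohort, calibration, params = pkpd_params(),
                            levels = c(0.05, 0.10, 0.20)) {
  sens <- sensitivity_analysis(cohort, calibration, params, levels = levels)
  list(
    regimen_means = regimen_efficacy(cohort),
    response_counts = classify_responses(cohort),
    regression = volume_regression(cohort, calibration),
    sensitivity_quartiles = sensitivity_summary(sens),
    sensitivity = sens
  )
}
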