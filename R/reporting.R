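# Pipeline entry points ------------------------------------------------------
#
# Thin orchestration over the analysis functions: each run_* stage loads its
# inputs, runs one pipeline step, and writes CSV/JSON (and optionally PNG)
# artifacts into an output directory. The exec/sbrt-pkpd script exposes the
# same stages on the command line.

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

resolve_cohort <- function(cohort) {
  if (is.character(cohort)) load_cohort(cohort) else validate_cohort(cohort)
}

#' Calibrate a cohort and write the calibration report
#'
#' @param cohort Cohort tibble, path to a cohort CSV, or `"bundled"`.
#' @param out_dir Output directory (created if needed).
#' @param params A [pkpd_params()] object.
#' @param overrides Named list of parameter overrides (keys must be
#'   [pkpd_params()] argument names).
#' @param bounds Calibration search interval for the response exponent.
#' @return The `pkpd_calibration` object, invisibly. Writes
#'   `calibration.csv`.
#' @export
run_calibrate <- function(cohort, out_dir, params = pkpd_params(),
                          overrides = list(), bounds = c(1e-3, 1)) {
  params <- apply_overrides(params, overrides)
  cohort <- resolve_cohort(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_msg("calibrate", "fitting %d lesion(s)", nrow(cohort))
  cal <- calibrate_cohort(cohort, params, bounds = bounds)
  for (e in attr(cal, "errors")) {
    stage_msg("calibrate", "FAILED patient %s lesion %d: %s",
              e$patient_id, e$lesion_index, e$message)
  }
  write_calibration(cal, file.path(out_dir, "calibration.csv"))
  stage_msg("calibrate", "%d/%d converged -> %s", sum(cal$converged), nrow(cal),
            file.path(out_dir, "calibration.csv"))
  invisible(cal)
}

#' Simulate calibrated trajectories and write them per lesion
#'
#' @param cohort Cohort tibble, path, or `"bundled"`.
#' @param gamma_source A `pkpd_calibration` object, a tibble with
#'   `patient_id`/`lesion_index`/`gamma_hat`, or the path to a calibration
#'   CSV written by [run_calibrate()].
#' @param out_dir Output directory.
#' @param params A [pkpd_params()] object.
#' @param overrides Named list of parameter overrides.
#' @param plots Also write one PNG per lesion.
#' @return Tibble of written trajectory files, invisibly.
#' @export
run_simulate <- function(cohort, gamma_source, out_dir, params = pkpd_params(),
                         overrides = list(), plots = FALSE) {
  params <- apply_overrides(params, overrides)
  cohort <- resolve_cohort(cohort)
  if (missing(gamma_source) || is.null(gamma_source)) {
    stop("no response exponents supplied: pass a calibration (see --gamma-file) ",
         "or run the calibrate stage first", call. = FALSE)
  }
  gammas <- if (is.character(gamma_source)) read_calibration(gamma_source)
            else tibble::as_tibble(gamma_source)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- dplyr::inner_join(cohort,
                         dplyr::select(gammas, dplyr::all_of(c("patient_id", "lesion_index", "gamma_hat"))),
                         by = c("patient_id", "lesion_index"))
  files <- purrr::map_chr(seq_len(nrow(d)), function(i) {
    rec <- d[i, ]
    traj <- simulate_lesion(rec, params, gamma = rec$gamma_hat)
    stem <- sprintf("trajectory_%s_les%d", rec$patient_id, rec$lesion_index)
    write_trajectory(traj, file.path(out_dir, paste0(stem, ".csv")))
    if (plots) {
      ggplot2::ggsave(file.path(out_dir, paste0(stem, ".png")), autoplot(traj),
                      width = 6, height = 4, dpi = 150)
    }
    paste0(stem, ".csv")
  })
  stage_msg("simulate", "wrote %d trajectory file(s) to %s", length(files), out_dir)
  invisible(tibble::tibble(patient_id = d$patient_id,
                           lesion_index = d$lesion_index, file = files))
}

#' Run the outcomes analysis and write the report
#'
#' Computes per-lesion and per-regimen efficacy, response counts, the
#' measured-versus-simulated regression and the uncertainty analysis, and
#' writes `efficacy.csv`, `sensitivity.csv` and `summary.json` (plus
#' figures when `plots = TRUE`).
#'
#' @param cohort Cohort tibble, path, or `"bundled"`.
#' @param out_dir Output directory.
#' @param calibration Optional `pkpd_calibration` (recomputed when absent).
#' @param params A [pkpd_params()] object.
#' @param overrides Named list of parameter overrides.
#' @param levels Perturbation levels for the uncertainty analysis.
#' @param plots Also write PNG figures.
#' @return The report list, invisibly.
#' @export
run_report <- function(cohort, out_dir, calibration = NULL,
                       params = pkpd_params(), overrides = list(),
                       levels = c(0.05, 0.10, 0.20), plots = FALSE) {
  params <- apply_overrides(params, overrides)
  cohort <- resolve_cohort(cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(calibration)) {
    stage_msg("report", "no calibration supplied; fitting %d lesion(s)", nrow(cohort))
    calibration <- calibrate_cohort(cohort, params)
  }
  rep <- outcomes_report(cohort, calibration, params, levels = levels)
  readr::write_csv(lesion_efficacy(cohort), file.path(out_dir, "efficacy.csv"),
                   progress = FALSE)
  readr::write_csv(rep$sensitivity, file.path(out_dir, "sensitivity.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(
      regimen_means = rep$regimen_means,
      response_counts = rep$response_counts,
      regression = as.list(rep$regression),
      sensitivity_quartiles = rep$sensitivity_quartiles
    ),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (plots) {
    ggplot2::ggsave(file.path(out_dir, "regimen_efficacy.png"),
                    plot_regimen_efficacy(cohort), width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "regression.png"),
                    autoplot(calibration), width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "sensitivity.png"),
                    plot_sensitivity(rep$sensitivity), width = 6, height = 4, dpi = 150)
  }
  stage_msg("report", "summary written to %s", file.path(out_dir, "summary.json"))
  invisible(rep)
}

#' Generate a synthetic cohort and its recovery summary
#'
#' Writes the generated cohort CSV, a sidecar CSV of the true response
#' exponents, and a JSON recovery summary.
#'
#' @param out_dir Output directory.
#' @param n_lesions,seed,noise_cv Passed to [cohort_spec()].
#' @param params A [pkpd_params()] object.
#' @param overrides Named list of parameter overrides.
#' @param recovery Also run the calibration recovery experiment.
#' @return The generation list from [generate_cohort()], invisibly.
#' @export
run_synth <- function(out_dir, n_lesions, seed, noise_cv = 0,
                      params = pkpd_params(), overrides = list(),
                      recovery = TRUE) {
  params <- apply_overrides(params, overrides)
  if (missing(seed)) stop("'seed' is required for synthetic generation", call. = FALSE)
  spec <- cohort_spec(n_lesions, seed, noise_cv = noise_cv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_msg("synth", "generating %d lesion(s), seed %d", n_lesions, spec$seed)
  gen <- generate_cohort(spec, params)
  write_cohort(gen$cohort, file.path(out_dir, "synthetic_cohort.csv"))
  readr::write_csv(gen$gamma, file.path(out_dir, "gamma_true.csv"), progress = FALSE)
  if (recovery) {
    summ <- recovery_experiment(spec, params)
    jsonlite::write_json(as.list(summ), file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_msg("synth", "recovery: median |error| = %s over %d identifiable lesion(s)",
              format(summ$median_abs_error), summ$n_identifiable)
  }
  invisible(gen)
}
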