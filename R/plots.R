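# Plotting -------------------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated tumour-volume trajectory
#'
#' Total, necrotic and active volume over time, with the fraction days
#' marked on the axis and the initial/final reported volumes highlighted.
#'
#' @param object A `pkpd_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pkpd_trajectory
#' @export
autoplot.pkpd_trajectory <- function(object, ...) {
  schedule <- attr(object, "schedule")
  long <- object |>
    dplyr::select(dplyr::all_of(c("t_days", "total_mm3", "x2", "delta_v_mm3"))) |>
    dplyr::rename(total = "total_mm3", necrotic = "x2", active = "delta_v_mm3") |>
    tidyr::pivot_longer(-"t_days", names_to = "series", values_to = "mm3")
  ends <- object[c(1, nrow(object)), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_days, y = .data$mm3,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_point(data = ends, ggplot2::aes(y = .data$reported_mm3),
                        colour = "black", shape = 21, fill = "white", size = 2) +
    ggplot2::geom_rug(data = tibble::tibble(t_days = schedule$pulse_starts),
                      ggplot2::aes(x = .data$t_days), inherit.aes = FALSE,
                      sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::scale_colour_manual(values = c(total = "#1f77b4", necrotic = "#d62728",
                                            active = "#2ca02c")) +
    ggplot2::labs(
      title = sprintf("Patient %s, lesion %d (gamma = %.3g)",
                      attr(object, "patient_id"), attr(object, "lesion_index"),
                      attr(object, "gamma")),
      x = "days since first fraction", y = "volume (mm^3)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot measured versus simulated post-treatment volumes
#'
#' Scatter of the calibrated model's final volume against the measured
#' post-treatment GTV, with the identity line and the fitted regression.
#'
#' @param object A `pkpd_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pkpd_calibration
#' @export
autoplot.pkpd_calibration <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(.data$converged)
  reg <- volume_regression(attr(object, "cohort"), object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$v_post_cm3, y = .data$v_sim_final)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_abline(slope = reg$slope, intercept = reg$intercept, colour = "#1f77b4") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      title = sprintf("Measured vs simulated final volume (r = %.3f, slope = %.3f)",
                      reg$r, reg$slope),
      x = "measured post-treatment GTV (cm^3)",
      y = "simulated final volume (cm^3)"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of mean efficacy per fractionation regimen
#'
#' @param cohort Cohort tibble.
#' @return A ggplot object.
#' @export
plot_regimen_efficacy <- function(cohort) {
  d <- regimen_efficacy(cohort)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$regimen, y = .data$mean_efficacy_pct)) +
    ggplot2::geom_col(fill = "#1f77b4", width = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("n = %d", .data$n_lesions)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "mean efficacy (%)",
                  title = "Mean efficacy per SBRT regimen") +
    ggplot2::theme_minimal()
}

#' Box plot of the initial-volume uncertainty analysis
#'
#' @param sensitivity Output of [sensitivity_analysis()].
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sensitivity) {
  d <- dplyr::filter(sensitivity, !.data$eradicated)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(100 * .data$perturbation),
                                  y = .data$pct_change_final)) +
    ggplot2::geom_boxplot(fill = "#aec7e8") +
    ggplot2::labs(x = "perturbation of initial volume (%)",
                  y = "change in simulated final volume (%)",
                  title = "Sensitivity of the final volume to baseline uncertainty") +
    ggplot2::theme_minimal()
}
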