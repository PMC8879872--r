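# PKPD tumour-dynamics core ---------------------------------------------------
#
# State vector (volumes in mm^3, drug levels in model concentration units):
#   x1  proliferating tumour volume        x2  necrotic tumour volume
#   x3/xe3  antiangiogenic level / effect site (inert by default)
#   x4/xe4  immunotherapy level / effect site (inert by default)
#   x5/xe5  radiotherapy level / effect site
#
#   dx1 = (a - n) x1 - E x1
#   dx2 = n x1 + E x1 - washout x2
#   dx5 = -cr x5 + ur(t)            dxe5 = etr x5 [- cr xe5 in tracking mode]
#
# E is the Hill effect of the interaction index I = Unt + Unr + sigma Unr Unt,
# active only while radiotherapy exposure is present (Unr > 0).

#' Normalise radiotherapy exposure to its half-effect level
#'
#' @param ur_level Radiotherapy effect-site level (Gy-equivalent), >= 0.
#' @param c50r Half-effect exposure (Gy), > 0.
#' @return `ur_level / c50r`, dimensionless.
#' @examples
#' normalized_dose(34, 20)
#' @export
normalized_dose <- function(ur_level, c50r) {
  if (any(c50r <= 0)) stop("'c50r' must be > 0", call. = FALSE)
  if (any(ur_level < 0)) stop("exposure must be >= 0", call. = FALSE)
  ur_level / c50r
}

#' Normalise tumour burden to its half-effect level
#'
#' In `"absolute"` mode (default) the half-effect tumour burden is the fixed
#' volume `c50t * 10` mm^3 (500 mm^3 at the default `c50t = 50`), so
#' `Unt = (x1 + x2) / (c50t * 10)`. In `"relative"` mode the burden is
#' expressed as a percentage of the lesion's own baseline:
#' `Unt = (100 * (x1 + x2) / v0) / c50t`.
#'
#' @param x1,x2 Proliferating and necrotic volumes (mm^3), >= 0.
#' @param v0 Baseline volume (mm^3); required > 0 in relative mode.
#' @param params A [pkpd_params()] object (uses `c50t`, `normalization_mode`).
#' @return Dimensionless tumour burden.
#' @export
normalized_tumor <- function(x1, x2, v0, params = pkpd_params()) {
  if (any(x1 < 0) || any(x2 < 0)) stop("volumes must be >= 0", call. = FALSE)
  total <- x1 + x2
  if (identical(params$normalization_mode, "relative")) {
    if (any(v0 <= 0)) stop("'v0' must be > 0 in relative normalisation mode", call. = FALSE)
    (100 * total / v0) / params$c50t
  } else {
    total / (params$c50t * 10)
  }
}

#' Interaction index of tumour burden and radiotherapy exposure
#'
#' `I = Unt + Unr + sigma * Unr * Unt`: additive in the two normalised
#' drivers with a synergy cross-term.
#'
#' @param unt,unr Normalised tumour burden and radiotherapy exposure, >= 0.
#' @param sigma Synergy coefficient, >= 0.
#' @return Dimensionless interaction index.
#' @export
interaction_index <- function(unt, unr, sigma) {
  if (any(unt < 0) || any(unr < 0)) stop("normalised inputs must be >= 0", call. = FALSE)
  unt + unr + sigma * unr * unt
}

#' Hill dose-response curve
#'
#' `Effect = i^gamma / (1 + i^gamma)`: 0 at `i = 0`, exactly 0.5 at `i = 1`
#' for any `gamma`, strictly increasing, approaching 1. `gamma` sets the
#' sigmoidicity and is the per-patient response parameter of the model.
#'
#' @param i Interaction index, >= 0 (vectorised).
#' @param gamma Response exponent, > 0.
#' @return Effect fraction in `[0, 1)`.
#' @examples
#' hill_effect(1, 0.1)   # 0.5 regardless of gamma
#' hill_effect(10, 0.25)
#' @export
hill_effect <- function(i, gamma) {
  if (any(i < 0)) stop("interaction index must be >= 0", call. = FALSE)
  if (any(gamma <= 0)) stop("'gamma' must be > 0", call. = FALSE)
  # 1 / (1 + i^-gamma) is stable for very large i, where i^gamma overflows
  ifelse(i == 0, 0, 1 / (1 + i^(-gamma)))
}

#' Combined treatment effect in 1/day
#'
#' The volume-kill rate applied to the proliferating compartment:
#' `E = (emaxr / 50) * hill_effect(I, gamma)` while radiotherapy exposure is
#' present (`unr > 0`), and 0 without exposure, so an untreated tumour grows
#' at the net rate `a - n`. At the half-effect index (I = 1) the kill rate
#' equals `emaxr / 100` per day.
#'
#' @param unt,unr Normalised tumour burden and radiotherapy exposure.
#' @param params A [pkpd_params()] object (uses `emaxr`, `sigma`, `gamma`).
#' @param gamma Response exponent; defaults to `params$gamma`.
#' @return Effect rate E (1/day), in `[0, emaxr / 50)`.
#' @export
combined_effect <- function(unt, unr, params = pkpd_params(), gamma = params$gamma) {
  if (any(is.na(gamma))) stop("'gamma' must be supplied", call. = FALSE)
  e <- (params$emaxr / 50) * hill_effect(interaction_index(unt, unr, params$sigma), gamma)
  ifelse(unr > 0, e, 0)
}

# Right-hand side of the ODE system; `ur` is the dose rate of the current
# segment (piecewise constant). States are clamped at zero before use so
# integrator round-off cannot feed negative volumes into the Hill terms.
pkpd_rhs <- function(t, y, p, ur) {
  y <- pmax(y, 0)
  x1 <- y[1]; x2 <- y[2]
  x3 <- y[3]; xe3 <- y[4]
  x4 <- y[5]; xe4 <- y[6]
  x5 <- y[7]; xe5 <- y[8]

  unr <- xe5 / p$c50r
  unt <- if (identical(p$normalization_mode, "relative")) {
    (100 * (x1 + x2) / p$v0) / p$c50t
  } else {
    (x1 + x2) / (p$c50t * 10)
  }
  E <- if (unr > 0) {
    idx <- unt + unr + p$sigma * unr * unt
    (p$emaxr / 50) / (1 + idx^(-p$gamma))
  } else 0

  cumulative <- identical(p$effect_site_mode, "cumulative")
  list(c(
    (p$a - p$n) * x1 - E * x1,
    p$n * x1 + E * x1 - p$washout * x2,
    -p$ca * x3,
    p$eta * x3 - if (cumulative) 0 else p$ca * xe3,
    -p$ci * x4,
    p$eti * x4 - if (cumulative) 0 else p$ci * xe4,
    -p$cr * x5 + ur,
    p$etr * x5 - if (cumulative) 0 else p$cr * xe5
  ))
}

state_names <- c("x1", "x2", "x3", "xe3", "x4", "xe4", "x5", "xe5")

# Integrate the system piecewise between pulse boundaries so the forcing is
# exactly constant within every integrator call. Returns a matrix of states
# at the requested output times.
integrate_pkpd <- function(schedule, p, y0, times) {
  times <- sort(unique(times))
  t_end <- max(times)
  starts <- schedule$pulse_starts
  ends <- starts + schedule$pulse_width
  rate <- schedule$dose_rate_during_pulse * p$gy_to_conc
  bounds <- sort(unique(c(0, starts, ends, times)))
  bounds <- bounds[bounds >= 0 & bounds <= t_end]
  if (max(bounds) < t_end) bounds <- c(bounds, t_end)

  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0),
                dimnames = list(NULL, state_names))
  y <- y0
  if (times[1] == 0) out[1, ] <- y
  for (k in seq_len(length(bounds) - 1)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    in_pulse <- any(t0 >= starts - 1e-12 & t0 < ends - 1e-12)
    ur <- if (in_pulse && schedule$total_dose > 0) rate else 0
    wanted <- times[times > t0 & times <= t1]
    seg_times <- sort(unique(c(t0, wanted, t1)))
    sol <- deSolve::lsoda(y, seg_times, pkpd_rhs, parms = p, ur = ur,
                          rtol = p$rtol, atol = p$atol)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("ODE integration failed on [%g, %g] (istate %d); try looser tolerances",
                   t0, t1, attr(sol, "istate")[1]), call. = FALSE)
    }
    if (length(wanted)) {
      idx <- match(wanted, sol[, 1])
      out[match(wanted, times), ] <- pmax(sol[idx, -1, drop = FALSE], 0)
    }
    y <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
  }
  out
}

#' Simulate the tumour-volume trajectory of a lesion
#'
#' Integrates the PKPD system for one lesion from the start of treatment
#' (t = 0, first treatment day) to follow-up. The initial condition puts the
#' whole measured pre-treatment GTV in the proliferating compartment:
#' `x1(0) = v_pre * 1000` mm^3, all other states zero.
#'
#' @param record A one-row cohort tibble (see [load_cohort()]).
#' @param params A [pkpd_params()] object.
#' @param gamma Patient-response exponent; overrides `params$gamma`.
#' @param times Output grid in days; defaults to daily sampling over
#'   `[0, followup_days]`.
#' @return A tibble of class `pkpd_trajectory` with the state columns
#'   (mm^3), the derived `total_mm3` (x1 + x2), `delta_v_mm3` (active
#'   volume, total minus necrotic), `reported_mm3` (the series selected by
#'   `params$reported_volume`) and `effect_per_day` (E(t)).
#' @examples
#' rec <- load_cohort("bundled") |> dplyr::filter(patient_id == "001")
#' traj <- simulate_lesion(rec, gamma = 0.05)
#' tail(traj, 3)
#' @export
simulate_lesion <- function(record, params = pkpd_params(), gamma = NULL,
                            times = NULL) {
  if (nrow(tibble::as_tibble(record)) != 1) stop("'record' must be a single lesion row", call. = FALSE)
  schedule <- build_schedule(record, params$pulse_width)
  p <- resolve_params(params, schedule$treatment_duration)
  if (!is.null(gamma)) p$gamma <- gamma
  if (is.na(p$gamma)) stop("'gamma' must be supplied (argument or params$gamma)", call. = FALSE)
  if (p$gamma <= 0) stop("'gamma' must be > 0", call. = FALSE)
  fu <- record$followup_days
  if (is.null(times)) times <- unique(c(seq(0, fu, by = 1), fu))
  if (min(times) < 0 || max(times) > fu) {
    stop("output grid must lie within [0, followup_days]", call. = FALSE)
  }
  v0 <- record$v_pre_cm3 * 1000
  p$v0 <- v0
  y0 <- c(v0, rep(0, 7))
  states <- integrate_pkpd(schedule, p, y0, sort(unique(times)))

  traj <- tibble::as_tibble(as.data.frame(states)) |>
    dplyr::mutate(
      t_days = sort(unique(times)), .before = 1
    ) |>
    dplyr::mutate(
      total_mm3 = .data$x1 + .data$x2,
      delta_v_mm3 = .data$x1,
      reported_mm3 = if (identical(p$reported_volume, "total")) .data$total_mm3 else .data$delta_v_mm3,
      effect_per_day = combined_effect(
        normalized_tumor(.data$x1, .data$x2, v0, params),
        normalized_dose(.data$xe5, p$c50r),
        params, gamma = p$gamma
      )
    )
  structure(traj,
            class = c("pkpd_trajectory", class(traj)),
            patient_id = record$patient_id,
            lesion_index = record$lesion_index,
            gamma = p$gamma,
            schedule = schedule,
            params = params)
}

# Final reported volume (mm^3) at follow-up, on the minimal two-point grid.
simulate_final <- function(record, params, gamma) {
  traj <- simulate_lesion(record, params, gamma = gamma,
                          times = c(0, record$followup_days))
  traj$reported_mm3[nrow(traj)]
}

#' Write a trajectory to CSV
#'
#' @param trajectory A `pkpd_trajectory` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  trajectory |>
    dplyr::select(dplyr::all_of(c("t_days", "x1_mm3" = "x1", "x2_mm3" = "x2",
                                  "x5", "xe5", "total_mm3", "delta_v_mm3",
                                  "effect_per_day"))) |>
    readr::write_csv(path, progress = FALSE)
  invisible(path)
}
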