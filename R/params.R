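# Model coefficients and configuration ---------------------------------------

#' Model coefficients for the SBRT tumour-dynamics model
#'
#' Constructs the full coefficient set of the PKPD tumour model together with
#' the configuration switches that close the model (normalisation convention,
#' reported volume, effect-site closure). The defaults are the reference
#' parameterisation used for the bundled cohort.
#'
#' @details
#' Rates are in 1/day, volumes in mm^3, doses in Gy. The radiotherapy
#' clearance rate `cr` defaults to `NA`, meaning "3 / treatment duration":
#' it is resolved per lesion from the span of its fraction days. Effect-site
#' transfer rates default to their matching clearance rates.
#'
#' `emaxr` (in %) anchors the magnitude of the combined effect E: at the
#' half-effect interaction index (I = 1) the kill rate is `emaxr/100` per
#' day, and the asymptotic maximum is `emaxr/50` per day. With the default
#' `emaxr = 50` the effect can therefore exceed the net growth rate
#' `a - n = 0.593`/day, which is what makes tumour regression representable;
#' see the package vignette for the reasoning.
#'
#' `effect_site_mode` selects the closure of the radiotherapy effect-site
#' compartment: `"cumulative"` (default) integrates exposure,
#' `d(xe5)/dt = etr * x5`, so that with `etr = cr` the effect-site level
#' tends to the total delivered dose in Gy (radiation damage is persistent);
#' `"tracking"` uses the transient form `d(xe5)/dt = -cr * xe5 + etr * x5`
#' under which the effect washes out after the last fraction.
#'
#' `normalization_mode` controls the tumour-burden normalisation `Unt`:
#' `"absolute"` reads `c50t` as an absolute half-effect volume of
#' `c50t * 10` mm^3 (default 500 mm^3); `"relative"` normalises the volume
#' to its own baseline, `Unt = (100 * V / V0) / c50t`.
#'
#' @param a Tumour growth rate (1/day).
#' @param n Necrosis rate (1/day).
#' @param cr Radiotherapy clearance rate (1/day); `NA` = 3 / treatment
#'   duration, resolved per lesion.
#' @param ca,ci Clearance rates of the antiangiogenic and immunotherapy
#'   branches (1/day); both default to 0 so the branches are inert.
#' @param etr,eta,eti Effect-site transfer rates (1/day); `NA` = equal to the
#'   matching clearance rate.
#' @param c50r Half-effect radiotherapy exposure (Gy).
#' @param c50t Half-effect tumour burden; interpreted per
#'   `normalization_mode`.
#' @param emaxr Effect magnitude anchor (%); see Details.
#' @param gamma Patient-response exponent of the Hill curve (dimensionless).
#'   Per-lesion; left `NA` here and supplied by calibration or simulation.
#' @param sigma Synergy coefficient of the interaction index.
#' @param washout Necrotic washout rate (1/day); 0 disables removal of
#'   necrotic tissue.
#' @param normalization_mode `"absolute"` or `"relative"`.
#' @param reported_volume Which series stands for the measurable tumour
#'   volume: `"delta_v"` (active volume, total minus necrotic) or `"total"`.
#' @param effect_site_mode `"cumulative"` or `"tracking"`; see Details.
#' @param gy_to_conc Unit conversion factor applied to the dose rate (Gy to
#'   model concentration units); identity by default.
#' @param pulse_width Width of the rectangular dose pulse representing one
#'   fraction (days).
#' @param rtol,atol Integration tolerances.
#'
#' @return An object of class `pkpd_params` (a named list).
#' @examples
#' p <- pkpd_params()
#' p$a
#' pkpd_params(washout = 0.05)$washout
#' @export
pkpd_params <- function(a = 0.693,
                        n = 0.10,
                        cr = NA_real_,
                        ca = 0,
                        ci = 0,
                        etr = NA_real_,
                        eta = NA_real_,
                        eti = NA_real_,
                        c50r = 20,
                        c50t = 50,
                        emaxr = 50,
                        gamma = NA_real_,
                        sigma = 8,
                        washout = 0,
                        normalization_mode = c("absolute", "relative"),
                        reported_volume = c("delta_v", "total"),
                        effect_site_mode = c("cumulative", "tracking"),
                        gy_to_conc = 1,
                        pulse_width = 0.1,
                        rtol = 1e-8,
                        atol = 1e-8) {
  p <- list(
    a = a, n = n, cr = cr, ca = ca, ci = ci,
    etr = etr, eta = eta, eti = eti,
    c50r = c50r, c50t = c50t, emaxr = emaxr,
    gamma = gamma, sigma = sigma, washout = washout,
    normalization_mode = match.arg(normalization_mode),
    reported_volume = match.arg(reported_volume),
    effect_site_mode = match.arg(effect_site_mode),
    gy_to_conc = gy_to_conc,
    pulse_width = pulse_width,
    rtol = rtol, atol = atol
  )
  validate_params(p)
  structure(p, class = "pkpd_params")
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1
  for (f in c("a", "n", "ca", "ci", "c50r", "c50t", "emaxr", "sigma",
              "washout", "gy_to_conc", "pulse_width", "rtol", "atol")) {
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a single number", call. = FALSE)
  }
  rates <- c("a", "n", "ca", "ci", "sigma", "washout")
  bad <- rates[vapply(rates, function(f) p[[f]] < 0, logical(1))]
  if (length(bad)) stop("parameters must be non-negative: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.na(p$cr) && p$cr < 0) stop("'cr' must be non-negative", call. = FALSE)
  if (!is.na(p$gamma) && p$gamma <= 0) stop("'gamma' must be > 0", call. = FALSE)
  if (p$c50r <= 0) stop("'c50r' must be > 0", call. = FALSE)
  if (p$c50t <= 0) stop("'c50t' must be > 0", call. = FALSE)
  if (p$emaxr <= 0 || p$emaxr > 100) stop("'emaxr' must be in (0, 100]", call. = FALSE)
  if (p$pulse_width <= 0 || p$pulse_width >= 1) stop("'pulse_width' must be in (0, 1) days", call. = FALSE)
  invisible(p)
}

#' @export
print.pkpd_params <- function(x, ...) {
  cat("<pkpd_params>\n")
  num <- vapply(x, is.numeric, logical(1))
  cat("  rates/coefficients:\n")
  for (f in names(x)[num]) cat(sprintf("    %-12s %s\n", f, format(x[[f]])))
  cat("  modes:\n")
  for (f in names(x)[!num]) cat(sprintf("    %-18s %s\n", f, x[[f]]))
  invisible(x)
}

# Fill the per-lesion closures: cr = 3 / treatment duration when unset,
# effect-site transfer rates default to the matching clearance rates.
resolve_params <- function(params, treatment_duration) {
  p <- unclass(params)
  if (is.na(p$cr)) p$cr <- 3 / treatment_duration
  if (is.na(p$etr)) p$etr <- p$cr
  if (is.na(p$eta)) p$eta <- p$ca
  if (is.na(p$eti)) p$eti <- p$ci
  p
}

#' Read or write a parameter configuration file
#'
#' Flat key-value YAML whose keys match the [pkpd_params()] argument names;
#' keys that are absent keep their defaults, so an empty file reproduces the
#' reference parameter set.
#'
#' @param path File path.
#' @return `read_params()` returns a `pkpd_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(pkpd_params)))
  if (length(unknown)) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pkpd_params, vals)
}

#' @param params A `pkpd_params` object.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pkpd_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

# Apply a named list of overrides to a parameter set, refusing unknown keys.
apply_overrides <- function(params, overrides) {
  if (is.null(overrides) || !length(overrides)) return(params)
  unknown <- setdiff(names(overrides), names(formals(pkpd_params)))
  if (length(unknown)) {
    stop("unknown parameter override(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  vals <- utils::modifyList(as.list(unclass(params)), overrides)
  do.call(pkpd_params, vals[names(formals(pkpd_params))])
}
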