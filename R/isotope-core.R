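#' Isotope system descriptors
#'
#' A small descriptor of a heavy-isotope tracer system: the international
#' reference ratio used by delta notation and the atomic mass of the element
#' (needed later to turn atom percent excess into molar tissue
#' concentrations). Two systems are built in: carbon-13 against the VPDB
#' standard and nitrogen-15 against atmospheric N2 (AIR).
#'
#' The reference ratios default to the community-standard values
#' 13C/12C (VPDB) = 0.0111802 and 15N/14N (AIR) = 0.0036765; both can be
#' overridden for laboratories that calibrate against different values.
#'
#' @param element `"13C"` or `"15N"`.
#' @param reference_ratio Heavy/light isotope ratio of the standard.
#'   Must lie in (0, 0.05).
#' @param atomic_mass Atomic mass of the element in g mol^-1.
#' @return A list of class `isotope_system` with fields `element`,
#'   `reference_ratio` and `atomic_mass`.
#' @examples
#' isotope_system("15N")
#' isotope_system("13C")$reference_ratio
#' @export
isotope_system <- function(element = c("13C", "15N"),
                           reference_ratio = NULL,
                           atomic_mass = NULL) {
  element <- match.arg(element)
  defaults <- list(
    "13C" = list(reference_ratio = 0.0111802, atomic_mass = 12.011),
    "15N" = list(reference_ratio = 0.0036765, atomic_mass = 14.007)
  )[[element]]
  reference_ratio <- reference_ratio %||% defaults$reference_ratio
  atomic_mass <- atomic_mass %||% defaults$atomic_mass
  if (!is.numeric(reference_ratio) || length(reference_ratio) != 1 ||
      reference_ratio <= 0 || reference_ratio >= 0.05) {
    abort("`reference_ratio` must be a single number in (0, 0.05).",
          class = "turftracer_error_invalid_system")
  }
  if (!is.numeric(atomic_mass) || atomic_mass <= 0) {
    abort("`atomic_mass` must be a positive number.",
          class = "turftracer_error_invalid_system")
  }
  structure(
    list(element = element, reference_ratio = reference_ratio,
         atomic_mass = atomic_mass),
    class = "isotope_system"
  )
}

#' @export
print.isotope_system <- function(x, ...) {
  cat(sprintf("<isotope_system> %s: R_std = %.7f, M = %.3f g/mol\n",
              x$element, x$reference_ratio, x$atomic_mass))
  invisible(x)
}

#' Convert delta notation to atom percent
#'
#' Delta values (per mil deviation of the sample heavy/light ratio from the
#' international standard) are converted to the percentage of the element's
#' atoms that are the heavy isotope:
#' \deqn{R_{sample} = R_{std}\,(\delta/1000 + 1), \qquad
#'       \mathrm{atom\,\%} = 100\,\frac{R_{sample}}{1 + R_{sample}}.}
#' The map is strictly increasing in delta and is exactly inverted by
#' [atom_percent_to_delta()].
#'
#' @param delta Numeric vector of delta values in per mil. Values must be
#'   greater than -1000 (a delta of -1000 would mean zero heavy isotope).
#' @param system An [isotope_system()].
#' @return Numeric vector of atom percent values in (0, 100).
#' @examples
#' delta_to_atom_percent(0, isotope_system("13C"))  # 1.1056 atom %
#' delta_to_atom_percent(0, isotope_system("15N"))  # 0.3663 atom %
#' @export
delta_to_atom_percent <- function(delta, system) {
  stopifnot(inherits(system, "isotope_system"))
  if (any(!is.finite(delta)) || any(delta <= -1000)) {
    abort(
      "delta values must be finite and > -1000 permil (invalid measurement).",
      class = "turftracer_error_invalid_measurement"
    )
  }
  r_sample <- system$reference_ratio * (delta / 1000 + 1)
  100 * r_sample / (1 + r_sample)
}

#' Convert atom percent back to delta notation
#'
#' Exact algebraic inverse of [delta_to_atom_percent()], used to express
#' simulated enrichments as the delta values an isotope ratio mass
#' spectrometer would report, and for round-trip checking.
#'
#' @param atom_percent Numeric vector in the open interval (0, 100).
#' @inheritParams delta_to_atom_percent
#' @return Numeric vector of delta values (per mil).
#' @export
atom_percent_to_delta <- function(atom_percent, system) {
  stopifnot(inherits(system, "isotope_system"))
  if (any(!is.finite(atom_percent)) ||
      any(atom_percent <= 0) || any(atom_percent >= 100)) {
    abort("atom percent values must lie strictly between 0 and 100.",
          class = "turftracer_error_domain")
  }
  f <- atom_percent / 100
  r_sample <- f / (1 - f)
  (r_sample / system$reference_ratio - 1) * 1000
}

#' Control baseline for excess-enrichment calculations
#'
#' The tracer signal is the atom percent *excess* over a natural-abundance
#' baseline estimated from control material. The baseline rule differs by
#' isotope. For nitrogen-15 the controls are the water-injected turves and
#' the baseline is their mean (or median) atom percent. For carbon-13 the
#' control set additionally includes the turves labeled with the inorganic
#' nitrogen forms (which received no 13C label), and the baseline is the
#' *minimum* control atom percent: natural-abundance 13C is noisy relative
#' to the small added 13C signal, and taking the minimum avoids negative
#' 13C enrichments.
#'
#' @param controls Numeric vector of control atom percent values.
#' @param system An [isotope_system()].
#' @param control_sources Optional character vector (same length as
#'   `controls`) of the labeled-form of each control sample. When supplied,
#'   the control-set composition is validated: nitrogen-15 controls must all
#'   be water controls; carbon-13 controls may be water or inorganic-N
#'   (`"NO3"`, `"NH4"`) turves but never organic-form turves.
#' @param stat Aggregation for the nitrogen-15 baseline, `"mean"` (default)
#'   or `"median"`. Ignored for carbon-13, which always uses the minimum.
#' @return A single baseline atom percent value.
#' @examples
#' control_baseline(c(1.08, 1.09, 1.11), isotope_system("13C")) # 1.08
#' control_baseline(c(0.366, 0.368), isotope_system("15N"))     # 0.367
#' @export
control_baseline <- function(controls, system, control_sources = NULL,
                             stat = c("mean", "median")) {
  stopifnot(inherits(system, "isotope_system"))
  stat <- match.arg(stat)
  if (length(controls) == 0 || all(is.na(controls))) {
    abort("empty control set: no control samples to form a baseline.",
          class = "turftracer_error_missing_control")
  }
  controls <- controls[!is.na(controls)]
  if (!is.null(control_sources)) {
    control_sources <- control_sources[!is.na(control_sources)]
    allowed <- switch(system$element,
      "15N" = "control",
      "13C" = c("control", "NO3", "NH4")
    )
    bad <- setdiff(unique(control_sources), allowed)
    if (length(bad) > 0) {
      abort(
        sprintf(
          "invalid control set for %s baseline: treatment(s) %s are not allowed controls (allowed: %s).",
          system$element, paste(bad, collapse = ", "),
          paste(allowed, collapse = ", ")
        ),
        class = "turftracer_error_invalid_control_set"
      )
    }
  }
  switch(system$element,
    "13C" = min(controls),
    "15N" = if (stat == "mean") mean(controls) else stats::median(controls)
  )
}

#' Atom percent excess
#'
#' Treatment atom percent minus the control baseline. Under the carbon-13
#' minimum-baseline rule every sample in a dataset containing its own
#' controls has nonnegative excess; nitrogen-15 excess may be slightly
#' negative through measurement noise, and such values are preserved (not
#' clipped) so that averages remain unbiased.
#'
#' @param treatment Numeric vector of treatment atom percent values.
#' @param baseline A single baseline atom percent (see [control_baseline()]).
#' @return Numeric vector of atom percent excess values (percentage points).
#' @export
atom_percent_excess <- function(treatment, baseline) {
  if (length(baseline) != 1 || !is.finite(baseline)) {
    abort("`baseline` must be a single finite atom percent value.",
          class = "turftracer_error_domain")
  }
  treatment - baseline
}
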