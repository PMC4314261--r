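#' Tissue excess concentration
#'
#' Converts atom percent excess to a molar excess concentration on a
#' dry-weight basis:
#' \deqn{\mathrm{conc} = \frac{\mathrm{APE}}{100} \times
#'       \frac{\mathrm{content}}{M} \times 10^9 \quad
#'       [\mathrm{nmol\ excess\ g^{-1}\ DW}]}
#' where `content` is the elemental content (g element per g dry weight) and
#' `M` the atomic mass (g mol^-1). Linear in both APE and content.
#'
#' @param ape Atom percent excess (percentage points).
#' @param element_content Elemental content as a mass fraction in (0, 1).
#' @param system An [isotope_system()] supplying the atomic mass.
#' @return Excess concentration in nmol g^-1 DW.
#' @examples
#' tissue_excess_concentration(0.01, 0.02, isotope_system("15N")) # ~142.8
#' @export
tissue_excess_concentration <- function(ape, element_content, system) {
  stopifnot(inherits(system, "isotope_system"))
  if (any(!is.finite(element_content)) ||
      any(element_content <= 0) || any(element_content >= 1)) {
    abort("`element_content` must be a mass fraction strictly in (0, 1).",
          class = "turftracer_error_invalid_composition")
  }
  (ape / 100) * element_content / system$atomic_mass * 1e9
}

#' Microbial biomass excess from a fumigation-extraction pair
#'
#' Microbial label content is estimated by chloroform fumigation-extraction:
#' the difference (the "flush") between the excess measured in K2SO4 extracts
#' of fumigated and non-fumigated soil, optionally divided by an extraction
#' efficiency factor `k_extract`. The default `k_extract = 1` reports the
#' raw flush; users wanting a Vance-style correction can supply e.g. 0.54
#' (kEN) or 0.45 (kEC). Negative flushes (measurement noise) are retained,
#' not clipped.
#'
#' @param fumigated,nonfumigated Excess concentrations (nmol g^-1 soil DW)
#'   of the paired extracts.
#' @param k_extract Extraction efficiency in (0, 1].
#' @return Microbial excess concentration (nmol g^-1 soil DW).
#' @export
microbial_excess <- function(fumigated, nonfumigated, k_extract = 1) {
  if (!is.numeric(k_extract) || k_extract <= 0 || k_extract > 1) {
    abort("`k_extract` must lie in (0, 1].",
          class = "turftracer_error_config")
  }
  if (length(fumigated) != length(nonfumigated)) {
    abort("fumigated and non-fumigated extracts must be paired 1:1.",
          class = "turftracer_error_missing_pair")
  }
  (fumigated - nonfumigated) / k_extract
}

# Shared schema validation for measurement tables. Returns the table
# invisibly; aborts with row-indexed messages on violations.
validate_measurements <- function(measurements, call_source = "measurements") {
  required <- c(
    "site", "block", "turf", "labeled_form", "fraction", "species",
    "delta13C_permil", "delta15N_permil", "c_content", "n_content",
    "pool_dry_mass_g"
  )
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing required column(s): %s.", call_source,
                  paste(missing_cols, collapse = ", ")),
          class = "turftracer_error_schema")
  }
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf(
        "%s (rows %s)", what,
        paste(head(rows, 10), collapse = ", ")))
    }
  }
  allowed_forms <- c(n_forms(), "control")
  note(which(!measurements$labeled_form %in% allowed_forms),
       sprintf("unknown labeled_form; allowed: %s",
               paste(allowed_forms, collapse = ", ")))
  note(which(!measurements$fraction %in% turf_fractions()),
       sprintf("unknown fraction; allowed: %s",
               paste(turf_fractions(), collapse = ", ")))
  note(which(!is.finite(measurements$c_content) |
               measurements$c_content <= 0 | measurements$c_content >= 1),
       "c_content outside (0, 1)")
  note(which(!is.finite(measurements$n_content) |
               measurements$n_content <= 0 | measurements$n_content >= 1),
       "n_content outside (0, 1)")
  note(which(!is.finite(measurements$pool_dry_mass_g) |
               measurements$pool_dry_mass_g <= 0),
       "pool_dry_mass_g must be > 0")
  note(which(measurements$delta13C_permil <= -1000 |
               measurements$delta15N_permil <= -1000),
       "delta values must be > -1000 permil")
  note(which(measurements$fraction == "shoot" & is.na(measurements$species)),
       "species required for shoot fractions")
  note(which(measurements$fraction != "shoot" & !is.na(measurements$species)),
       "species must be empty for non-shoot fractions")
  dup <- duplicated(measurements[, c("turf", "fraction", "species")])
  note(which(dup), "duplicated (turf, fraction, species) key")
  if (length(problems) > 0) {
    abort(paste0(call_source, " failed validation:\n  - ",
                 paste(problems, collapse = "\n  - ")),
          class = "turftracer_error_schema")
  }
  invisible(measurements)
}

#' Compute per-sample excess enrichment from raw delta measurements
#'
#' The central analysis step. Takes the tidy measurement table (one row per
#' IRMS observation; see [read_measurements()] for the schema), converts
#' delta values to atom percent, estimates natural-abundance baselines from
#' the control material within each stratum, subtracts them to obtain atom
#' percent excess for both isotopes, converts excess to molar tissue
#' concentrations, and collapses each turf's fumigation-extraction pair into
#' a `microbial` fraction.
#'
#' Baselines are stratified by `baseline_by` (default site x fraction x
#' species) because natural abundance differs between tissues; the
#' nitrogen-15 baseline is the mean (or median) of the water-control turves
#' in the stratum, while the carbon-13 baseline is the minimum over water
#' controls *and* the inorganic-N turves, which received no 13C label
#' (see [control_baseline()]).
#'
#' @param measurements A measurement tibble (schema of [read_measurements()]).
#' @param k_extract Fumigation extraction efficiency, see [microbial_excess()].
#' @param baseline_by Character vector of stratification columns for
#'   baseline estimation.
#' @param n15_baseline_stat `"mean"` or `"median"` for the 15N baseline.
#' @param system_13C,system_15N Isotope systems (override reference ratios
#'   here if needed).
#' @return A tibble with one row per turf x pool (`microbial`, `root`, and
#'   one `shoot` row per species), carrying atom percent excess
#'   (`ape_13C`, `ape_15N`), the baselines used, excess concentrations
#'   (`conc_excess_13C`, `conc_excess_15N`, nmol g^-1 DW) and the pool dry
#'   mass. For microbial rows the concentration is per g soil DW and the
#'   mass is the whole-turf soil dry mass.
#' @export
compute_enrichment <- function(measurements,
                               k_extract = 1,
                               baseline_by = c("site", "fraction", "species"),
                               n15_baseline_stat = c("mean", "median"),
                               system_13C = isotope_system("13C"),
                               system_15N = isotope_system("15N")) {
  n15_baseline_stat <- match.arg(n15_baseline_stat)
  validate_measurements(measurements)

  m <- measurements |>
    dplyr::mutate(
      atom_pct_13C = delta_to_atom_percent(.data$delta13C_permil, system_13C),
      atom_pct_15N = delta_to_atom_percent(.data$delta15N_permil, system_15N)
    )

  baselines <- m |>
    dplyr::group_by(dplyr::across(dplyr::all_of(baseline_by))) |>
    dplyr::summarise(
      baseline_15N = {
        ctl <- .data$atom_pct_15N[.data$labeled_form == "control"]
        if (length(ctl) == 0) NA_real_ else
          control_baseline(ctl, system_15N, stat = n15_baseline_stat)
      },
      baseline_13C = {
        idx <- .data$labeled_form %in% c("control", "NO3", "NH4")
        if (!any(idx)) NA_real_ else
          control_baseline(.data$atom_pct_13C[idx], system_13C,
                           .data$labeled_form[idx])
      },
      .groups = "drop"
    )

  m <- dplyr::left_join(m, baselines, by = baseline_by)
  if (anyNA(m$baseline_15N) || anyNA(m$baseline_13C)) {
    miss <- m |>
      dplyr::filter(is.na(.data$baseline_15N) | is.na(.data$baseline_13C)) |>
      dplyr::distinct(dplyr::across(dplyr::all_of(baseline_by)))
    abort(paste0(
      "missing control baseline for stratum(s): ",
      paste(do.call(paste, c(miss, sep = "/")), collapse = "; ")
    ), class = "turftracer_error_missing_control")
  }

  m <- m |>
    dplyr::mutate(
      ape_13C = atom_percent_excess_vec(.data$atom_pct_13C, .data$baseline_13C),
      ape_15N = atom_percent_excess_vec(.data$atom_pct_15N, .data$baseline_15N),
      conc_excess_13C =
        tissue_excess_concentration(.data$ape_13C, .data$c_content, system_13C),
      conc_excess_15N =
        tissue_excess_concentration(.data$ape_15N, .data$n_content, system_15N)
    )

  plant <- m |>
    dplyr::filter(.data$fraction %in% c("shoot", "root")) |>
    dplyr::transmute(
      site, block, turf, labeled_form,
      pool = .data$fraction, species,
      ape_13C, ape_15N, baseline_13C, baseline_15N,
      conc_excess_13C, conc_excess_15N,
      pool_dry_mass_g
    )

  microbial <- m |>
    dplyr::filter(.data$fraction %in%
                    c("soil_fumigated", "soil_nonfumigated")) |>
    dplyr::select(site, block, turf, labeled_form, fraction,
                  conc_excess_13C, conc_excess_15N, pool_dry_mass_g) |>
    tidyr::pivot_wider(
      names_from = fraction,
      values_from = c(conc_excess_13C, conc_excess_15N, pool_dry_mass_g)
    )
  need <- c("conc_excess_13C_soil_fumigated",
            "conc_excess_13C_soil_nonfumigated",
            "conc_excess_15N_soil_fumigated",
            "conc_excess_15N_soil_nonfumigated")
  if (nrow(microbial) > 0 && !all(need %in% names(microbial))) {
    abort("fumigation-extraction pair incomplete: need both fumigated and non-fumigated extracts per turf.",
          class = "turftracer_error_missing_pair")
  }
  if (nrow(microbial) > 0) {
    unpaired <- microbial |>
      dplyr::filter(dplyr::if_any(dplyr::all_of(need), is.na))
    if (nrow(unpaired) > 0) {
      abort(sprintf(
        "turf(s) missing a fumigation-extraction pair member: %s.",
        paste(unpaired$turf, collapse = ", ")),
        class = "turftracer_error_missing_pair")
    }
    microbial <- microbial |>
      dplyr::transmute(
        site, block, turf, labeled_form,
        pool = "microbial", species = NA_character_,
        ape_13C = NA_real_, ape_15N = NA_real_,
        baseline_13C = NA_real_, baseline_15N = NA_real_,
        conc_excess_13C = microbial_excess(
          .data$conc_excess_13C_soil_fumigated,
          .data$conc_excess_13C_soil_nonfumigated, k_extract),
        conc_excess_15N = microbial_excess(
          .data$conc_excess_15N_soil_fumigated,
          .data$conc_excess_15N_soil_nonfumigated, k_extract),
        pool_dry_mass_g = .data$pool_dry_mass_g_soil_fumigated
      )
  }

  out <- dplyr::bind_rows(plant, microbial) |>
    dplyr::arrange(site, block, turf, pool, species)
  n_neg <- sum(out$conc_excess_15N < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warn(sprintf(
      "%d sample(s) have negative 15N excess (measurement noise); retained unclipped.",
      n_neg))
  }
  out
}

# vectorised excess with per-row baselines (internal)
atom_percent_excess_vec <- function(treatment, baseline) treatment - baseline
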