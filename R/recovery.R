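#' Percent recovery of added label in one pool
#'
#' The mass-balance core: the number of labeled atoms found in a pool
#' (excess concentration times pool dry mass) as a percentage of the number
#' of labeled atoms added to the turf.
#'
#' @param conc_excess Excess concentration, nmol g^-1 DW.
#' @param pool_dry_mass_g Whole-turf dry mass of the pool, g.
#' @param added_label_nmol Labeled atoms added, nmol (> 0).
#' @return Recovery in percent of the added label.
#' @examples
#' pool_recovery(100, 50, 25000) # 20 %
#' @export
pool_recovery <- function(conc_excess, pool_dry_mass_g, added_label_nmol) {
  if (any(!is.finite(added_label_nmol)) || any(added_label_nmol <= 0)) {
    abort("`added_label_nmol` must be positive.",
          class = "turftracer_error_config")
  }
  if (any(pool_dry_mass_g < 0, na.rm = TRUE)) {
    abort("`pool_dry_mass_g` must be >= 0.",
          class = "turftracer_error_config")
  }
  100 * conc_excess * pool_dry_mass_g / added_label_nmol
}

#' Aggregate per-sample enrichment into a recovery table
#'
#' Builds the turf-level mass balance: for every labeled turf, the percent
#' of added 15N (and, for organic forms, 13C) recovered in the microbial
#' biomass, roots, and shoots. Shoot species within a turf are summed into a
#' single shoot pool (species-level rows are retained in the output of
#' [compute_enrichment()]); turf totals across the three pools are attached
#' to every row.
#'
#' 13C recovery is computed only for turves labeled with an organic form;
#' inorganic-form turves carry no 13C label (they serve as additional 13C
#' baseline material) and get `NA`. Water-control turves received no label
#' and are reported with zero recovery.
#'
#' @param enrichment Output of [compute_enrichment()].
#' @param additions Output of [tracer_addition()] (one row per labeled
#'   form present in the data).
#' @return A tibble of class `tracer_recovery`, one row per
#'   site x block x turf x labeled_form x pool, with `recovery_pct_15N`,
#'   `recovery_pct_13C`, `turf_total_pct_15N` and `turf_total_pct_13C`.
#' @export
aggregate_recovery <- function(enrichment, additions = tracer_addition()) {
  labeled <- enrichment |> dplyr::filter(.data$labeled_form != "control")
  forms_present <- unique(labeled$labeled_form)
  missing_forms <- setdiff(forms_present, additions$labeled_form)
  if (length(missing_forms) > 0) {
    abort(sprintf("no tracer addition specified for form(s): %s.",
                  paste(missing_forms, collapse = ", ")),
          class = "turftracer_error_config")
  }

  pools_per_turf <- labeled |>
    dplyr::distinct(.data$turf, .data$pool) |>
    dplyr::count(.data$turf)
  incomplete <- pools_per_turf$turf[pools_per_turf$n < 3]
  if (length(incomplete) > 0) {
    warn(sprintf(
      "turf(s) missing one or more of microbial/root/shoot pools (missing pools contribute 0): %s",
      paste(incomplete, collapse = ", ")))
  }

  per_pool <- labeled |>
    dplyr::left_join(
      additions |>
        dplyr::select("labeled_form", "added_label_nmol_15N",
                      "added_label_nmol_13C"),
      by = "labeled_form"
    ) |>
    dplyr::group_by(site, block, turf, labeled_form, pool) |>
    dplyr::summarise(
      nmol_15N = sum(.data$conc_excess_15N * .data$pool_dry_mass_g),
      nmol_13C = sum(.data$conc_excess_13C * .data$pool_dry_mass_g),
      added_label_nmol_15N = .data$added_label_nmol_15N[1],
      added_label_nmol_13C = .data$added_label_nmol_13C[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      recovery_pct_15N = pool_recovery(
        .data$nmol_15N, 1, .data$added_label_nmol_15N),
      recovery_pct_13C = dplyr::if_else(
        .data$added_label_nmol_13C > 0,
        100 * .data$nmol_13C / .data$added_label_nmol_13C,
        NA_real_)
    )

  controls <- enrichment |>
    dplyr::filter(.data$labeled_form == "control") |>
    dplyr::distinct(site, block, turf, labeled_form, pool) |>
    dplyr::mutate(
      nmol_15N = NA_real_, nmol_13C = NA_real_,
      added_label_nmol_15N = 0, added_label_nmol_13C = 0,
      recovery_pct_15N = 0, recovery_pct_13C = NA_real_
    )

  out <- dplyr::bind_rows(per_pool, controls) |>
    dplyr::group_by(site, block, turf, labeled_form) |>
    dplyr::mutate(
      turf_total_pct_15N = sum(.data$recovery_pct_15N),
      turf_total_pct_13C = if (all(is.na(.data$recovery_pct_13C))) NA_real_
        else sum(.data$recovery_pct_13C, na.rm = TRUE)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"nmol_15N", -"nmol_13C") |>
    dplyr::arrange(site, block, turf, pool)
  class(out) <- c("tracer_recovery", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.tracer_recovery <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      dplyr::all_of(c("recovery_pct_15N", "recovery_pct_13C")),
      names_to = "isotope", values_to = "recovery_pct",
      names_prefix = "recovery_pct_"
    ) |>
    dplyr::filter(!is.na(.data$recovery_pct))
}

#' @exportS3Method generics::glance
glance.tracer_recovery <- function(x, ...) {
  labeled <- dplyr::filter(x, .data$labeled_form != "control")
  tibble::tibble(
    n_turves = dplyr::n_distinct(labeled$turf),
    n_pools = dplyr::n_distinct(labeled$pool),
    mean_total_pct_15N = mean(
      dplyr::distinct(labeled, .data$turf,
                      .keep_all = TRUE)$turf_total_pct_15N),
    max_total_pct_15N = max(labeled$turf_total_pct_15N),
    min_recovery_pct_15N = min(labeled$recovery_pct_15N)
  )
}
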