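#' Ambient dissolved-N pool sizes of the two grasslands
#'
#' Default soil solution pool sizes (mg N m^-2, 0-15 cm) for the
#' high-productivity (fertilised lowland) and low-productivity (upland
#' Agrostis-Festuca) grassland of the study design the simulator emulates.
#'
#' @return A tibble with columns `site`, `nh4_mgN_m2`, `no3_mgN_m2`,
#'   `faa_mgN_m2` (free amino acid N), `peptide_mgN_m2`, `don_mgN_m2`.
#' @examples
#' grassland_pool_sizes()
#' @export
grassland_pool_sizes <- function() {
  tibble::tibble(
    site = c("high", "low"),
    nh4_mgN_m2 = c(132, 73.4),
    no3_mgN_m2 = c(401, 0.6),
    faa_mgN_m2 = c(0.54, 0.28),
    peptide_mgN_m2 = c(1.74, 1.71),
    don_mgN_m2 = c(169, 301)
  )
}

# ambient pool column matched to each labeled N form
form_pool_column <- c(
  NO3 = "no3_mgN_m2", NH4 = "nh4_mgN_m2",
  alanine = "faa_mgN_m2", trialanine = "peptide_mgN_m2"
)

#' Isotope pool-dilution factor
#'
#' The injected tracer mixes into the ambient soil pool of the same N form,
#' so the enrichment measured in plant tissue under-represents uptake from
#' large pools. The default factor is the tracer's dilution in the target
#' pool, (ambient + added)/added, which equals 1 when the ambient pool is
#' empty; the alternative `"pool_only"` convention (ambient/added) is also
#' provided.
#'
#' @param pool_mgN_m2 Ambient pool size, mg N m^-2 (>= 0).
#' @param added_mgN_m2 Areal tracer dose of that form, mg N m^-2 (> 0).
#' @param method `"pool_plus_added"` (default) or `"pool_only"`.
#' @return Dimensionless dilution factor.
#' @examples
#' dilution_factor(401, 8.75)  # nitrate, high-productivity site: ~46.8
#' dilution_factor(0, 8.75)    # tracer is the whole pool: 1
#' @export
dilution_factor <- function(pool_mgN_m2, added_mgN_m2,
                            method = c("pool_plus_added", "pool_only")) {
  method <- match.arg(method)
  if (any(!is.finite(added_mgN_m2)) || any(added_mgN_m2 <= 0)) {
    abort("`added_mgN_m2` must be positive.",
          class = "turftracer_error_config")
  }
  if (any(pool_mgN_m2 < 0, na.rm = TRUE)) {
    abort("`pool_mgN_m2` must be >= 0.", class = "turftracer_error_config")
  }
  switch(method,
    pool_plus_added = (pool_mgN_m2 + added_mgN_m2) / added_mgN_m2,
    pool_only = pool_mgN_m2 / added_mgN_m2
  )
}

#' Scale shoot enrichment by ambient pool dilution
#'
#' Multiplies per-species shoot 15N excess concentrations by the
#' pool-dilution factor of the labeled form at that site, putting uptake
#' from N forms of very different ambient pool size on a comparable scale.
#'
#' @param enrichment Output of [compute_enrichment()].
#' @param pool_sizes Tibble in the shape of [grassland_pool_sizes()].
#' @param additions Output of [tracer_addition()], supplying the areal dose
#'   per form.
#' @inheritParams dilution_factor
#' @return A tibble with one row per shoot sample of a labeled turf:
#'   `site`, `block`, `turf`, `labeled_form`, `species`, `shoot_excess`
#'   (nmol 15N g^-1 DW), `dilution_factor`, `scaled_value`.
#' @export
scale_shoot_uptake <- function(enrichment,
                               pool_sizes = grassland_pool_sizes(),
                               additions = tracer_addition(),
                               method = c("pool_plus_added", "pool_only")) {
  method <- match.arg(method)
  pools_long <- pool_sizes |>
    tidyr::pivot_longer(-"site", names_to = "pool_col",
                        values_to = "pool_mgN_m2") |>
    dplyr::inner_join(
      tibble::tibble(labeled_form = names(form_pool_column),
                     pool_col = unname(form_pool_column)),
      by = "pool_col"
    ) |>
    dplyr::select("site", "labeled_form", "pool_mgN_m2")
  enrichment |>
    dplyr::filter(.data$pool == "shoot",
                  .data$labeled_form %in% n_forms()) |>
    dplyr::inner_join(pools_long, by = c("site", "labeled_form")) |>
    dplyr::inner_join(
      dplyr::select(additions, "labeled_form", "areal_per_form_mgN_m2"),
      by = "labeled_form"
    ) |>
    dplyr::transmute(
      site, block, turf, labeled_form, species,
      shoot_excess = .data$conc_excess_15N,
      dilution_factor = dilution_factor(
        .data$pool_mgN_m2, .data$areal_per_form_mgN_m2, method),
      scaled_value = .data$shoot_excess * .data$dilution_factor
    )
}

#' Ratio of pool-dilution-scaled uptake between two N forms
#'
#' Compares scaled shoot uptake of two labeled forms within site (and
#' species, when present), e.g. to ask how much more ammonium-N than
#' peptide-N a species acquires once pool dilution is accounted for.
#' Ratios with a zero denominator are flagged `undefined` rather than
#' raising an error.
#'
#' @param scaled Output of [scale_shoot_uptake()].
#' @param form_a,form_b Labeled forms to compare (numerator, denominator).
#' @param by Grouping columns, default `c("site", "species")`.
#' @return Tibble with mean scaled uptake of each form, their ratio, and an
#'   `undefined` flag.
#' @export
scaled_uptake_ratio <- function(scaled, form_a, form_b,
                                by = c("site", "species")) {
  means <- scaled |>
    dplyr::filter(.data$labeled_form %in% c(form_a, form_b)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "labeled_form")))) |>
    dplyr::summarise(scaled_value = mean(.data$scaled_value),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "labeled_form",
                       values_from = "scaled_value")
  means |>
    dplyr::mutate(
      ratio = .data[[form_a]] / .data[[form_b]],
      undefined = !is.finite(.data$ratio)
    )
}

#' Dissolved inorganic : organic N ratio of a site
#'
#' DIN:DON = (NH4 + NO3) / DON, the standard index of the balance between
#' inorganic and organic dissolved N; reported to two decimals.
#'
#' @param pool_sizes Tibble in the shape of [grassland_pool_sizes()].
#' @return `pool_sizes` with an added `din_don` column (rounded to 2
#'   decimals; `NA` with a warning flag column `undefined` when DON is 0).
#' @examples
#' din_don_ratio(grassland_pool_sizes()) # 3.15 (high), 0.25 (low)
#' @export
din_don_ratio <- function(pool_sizes) {
  pool_sizes |>
    dplyr::mutate(
      undefined = .data$don_mgN_m2 <= 0,
      din_don = dplyr::if_else(
        .data$undefined, NA_real_,
        round((.data$nh4_mgN_m2 + .data$no3_mgN_m2) / .data$don_mgN_m2, 2))
    )
}
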