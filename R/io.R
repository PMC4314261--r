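#' Read a measurement table from CSV
#'
#' Reads and validates the tidy per-sample measurement schema used
#' throughout the pipeline. Expected columns (UTF-8 CSV, decimal point, no
#' thousands separators):
#' `site`, `block`, `turf`, `labeled_form` (`NO3`, `NH4`, `alanine`,
#' `trialanine` or `control`),
#' `fraction` (`shoot`, `root`, `soil_fumigated`, `soil_nonfumigated`),
#' `species` (shoots only, empty otherwise), `delta13C_permil`,
#' `delta15N_permil`, `c_content` and `n_content` (g per g DW, in (0,1)),
#' `pool_dry_mass_g` (whole-turf pool dry mass; for extracts, the
#' whole-turf soil dry mass).
#'
#' Validation problems are collected and reported together with row
#' numbers; any violation aborts the read.
#'
#' @param path Path to the CSV file.
#' @return A validated measurement tibble.
#' @export
read_measurements <- function(path) {
  m <- readr::read_csv(
    path,
    col_types = readr::cols(
      site = readr::col_character(),
      block = readr::col_integer(),
      turf = readr::col_character(),
      labeled_form = readr::col_character(),
      fraction = readr::col_character(),
      species = readr::col_character(),
      delta13C_permil = readr::col_double(),
      delta15N_permil = readr::col_double(),
      c_content = readr::col_double(),
      n_content = readr::col_double(),
      pool_dry_mass_g = readr::col_double()
    ),
    progress = FALSE
  )
  validate_measurements(m, call_source = path)
  m
}

#' Read ambient pool sizes from CSV
#'
#' Schema of [grassland_pool_sizes()]: `site`, `nh4_mgN_m2`, `no3_mgN_m2`,
#' `faa_mgN_m2`, `peptide_mgN_m2`, `don_mgN_m2` (all mg N m^-2, >= 0).
#'
#' @param path Path to the CSV file.
#' @return A pool-size tibble.
#' @export
read_pool_sizes <- function(path) {
  p <- readr::read_csv(path, col_types = readr::cols(
    site = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  required <- names(grassland_pool_sizes())
  missing_cols <- setdiff(required, names(p))
  if (length(missing_cols) > 0) {
    abort(sprintf("pool-size table missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "turftracer_error_schema")
  }
  if (any(p[setdiff(required, "site")] < 0, na.rm = TRUE)) {
    abort("pool sizes must be >= 0.", class = "turftracer_error_schema")
  }
  p
}

#' Run the full tracer analysis pipeline
#'
#' Chains the analysis stages on a measurement table: excess enrichment
#' ([compute_enrichment()]), recovery mass balance ([aggregate_recovery()]),
#' pool-dilution scaling of shoot uptake ([scale_shoot_uptake()]) and the
#' site / N form / pool comparison layer ([fit_factorial_anova()],
#' [site_contrast()]). Deterministic given its inputs; when `out_dir` is
#' supplied the result tables are written as CSV (full double precision)
#' together with a plain-text manifest echoing the resolved configuration.
#'
#' @param measurements Measurement tibble ([read_measurements()] schema).
#' @param additions [tracer_addition()] table.
#' @param pool_sizes [grassland_pool_sizes()]-shaped tibble.
#' @param k_extract,baseline_by,n15_baseline_stat Passed to
#'   [compute_enrichment()].
#' @param dilution_method Passed to [scale_shoot_uptake()].
#' @param transform Passed to [fit_factorial_anova()].
#' @param out_dir Optional output directory for CSV artifacts.
#' @return A list of class `turf_pipeline` with `enrichment`, `recovery`,
#'   `scaled_uptake`, `anova` (a [fit_factorial_anova()] object on 15N
#'   recovery), `site_contrast` and `config`.
#' @export
run_pipeline <- function(measurements,
                         additions = tracer_addition(),
                         pool_sizes = grassland_pool_sizes(),
                         k_extract = 1,
                         baseline_by = c("site", "fraction", "species"),
                         n15_baseline_stat = "mean",
                         dilution_method = "pool_plus_added",
                         transform = "none",
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "turftracer_error_pipeline", parent = e)
    })
  }
  enrichment <- stage("enrichment", compute_enrichment(
    measurements, k_extract = k_extract, baseline_by = baseline_by,
    n15_baseline_stat = n15_baseline_stat))
  recovery <- stage("recovery", aggregate_recovery(enrichment, additions))
  scaled <- stage("dilution", scale_shoot_uptake(
    enrichment, pool_sizes, additions, method = dilution_method))
  labeled <- dplyr::filter(recovery, .data$labeled_form != "control")
  anova_fit <- stage("stats", fit_factorial_anova(
    labeled, "recovery_pct_15N",
    factors = c("site", "labeled_form", "pool", "block"),
    transform = transform))
  contrast <- stage("stats", site_contrast(
    dplyr::filter(labeled, .data$pool == "shoot"), "recovery_pct_15N"))

  config <- list(
    k_extract = k_extract, baseline_by = baseline_by,
    n15_baseline_stat = n15_baseline_stat,
    dilution_method = dilution_method,
    transform_requested = transform,
    transform_used = anova_fit$transform,
    n_measurements = nrow(measurements)
  )
  result <- structure(
    list(enrichment = enrichment, recovery = recovery,
         scaled_uptake = scaled, anova = anova_fit,
         site_contrast = contrast, config = config),
    class = "turf_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(enrichment, file.path(out_dir, "enrichment.csv"))
    readr::write_csv(tibble::as_tibble(recovery),
                     file.path(out_dir, "recovery.csv"))
    readr::write_csv(scaled, file.path(out_dir, "scaled_uptake.csv"))
    readr::write_csv(tidy(anova_fit), file.path(out_dir, "anova.csv"))
    writeLines(
      c("turftracer pipeline manifest",
        sprintf("generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
        sprintf("%s: %s", names(config),
                vapply(config, function(v) paste(v, collapse = ","), ""))),
      file.path(out_dir, "manifest.txt"))
  }
  result
}

#' @export
print.turf_pipeline <- function(x, ...) {
  cat("<turf_pipeline>\n")
  cat(sprintf("  %d enrichment rows, %d recovery rows\n",
              nrow(x$enrichment), nrow(x$recovery)))
  cat(sprintf("  site contrast (shoot 15N recovery): F(%d,%d) = %.2f, p = %.3g\n",
              x$site_contrast$df1, x$site_contrast$df2,
              x$site_contrast$statistic, x$site_contrast$p.value))
  invisible(x)
}
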