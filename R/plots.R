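#' Plot percent recovery of added label by pool, N form and site
#'
#' Bar chart of mean per-pool recovery (percent of added 15N) with one
#' panel per N form, mirroring the standard presentation of tracer
#' recovery experiments.
#'
#' @param recovery A [aggregate_recovery()] table.
#' @param isotope `"15N"` or `"13C"`.
#' @return A ggplot object.
#' @export
plot_recovery <- function(recovery, isotope = c("15N", "13C")) {
  isotope <- match.arg(isotope)
  col <- paste0("recovery_pct_", isotope)
  df <- recovery |>
    dplyr::filter(.data$labeled_form != "control",
                  is.finite(.data[[col]])) |>
    dplyr::group_by(.data$site, .data$labeled_form, .data$pool) |>
    dplyr::summarise(
      mean_pct = mean(.data[[col]]),
      se_pct = stats::sd(.data[[col]]) / sqrt(dplyr::n()),
      .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pool, y = .data$mean_pct,
                                   fill = .data$site)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_pct - .data$se_pct,
                   ymax = .data$mean_pct + .data$se_pct),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::facet_wrap(~labeled_form) +
    ggplot2::labs(
      x = NULL, fill = "Site",
      y = sprintf("Recovery of added %s (%%)", isotope)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.tracer_recovery <- function(object, ...) plot_recovery(object, ...)

#' Plot the dual-isotope colocation relationship
#'
#' Scatter of 13C against 15N excess concentrations with the OLS fit, the
#' diagnostic behind inferring intact uptake of dual-labeled substrates
#' (slope near the substrate C:N of 3 suggests intact uptake; near 0,
#' uptake of mineralization products).
#'
#' @param enrichment A [compute_enrichment()] table (typically filtered to
#'   one pool and organic form).
#' @return A ggplot object.
#' @export
plot_colocation <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$conc_excess_15N,
                               y = .data$conc_excess_13C)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$site)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(
      x = expression(paste({}^15, "N excess (nmol ", g^-1, " DW)")),
      y = expression(paste({}^13, "C excess (nmol ", g^-1, " DW)")),
      colour = "Site") +
    ggplot2::theme_minimal()
}

#' Plot pool-dilution-scaled shoot uptake
#'
#' @param scaled A [scale_shoot_uptake()] table.
#' @return A ggplot object.
#' @export
plot_scaled_uptake <- function(scaled) {
  ggplot2::ggplot(scaled,
                  ggplot2::aes(x = .data$labeled_form,
                               y = .data$scaled_value,
                               fill = .data$labeled_form)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_grid(site ~ species, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL,
      y = expression(paste("Pool-dilution-scaled shoot ", {}^15,
                           "N uptake (nmol ", g^-1, " DW)"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
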