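#' Blocked factorial ANOVA on recovery or concentration data
#'
#' Fits the comparison layer of the tracer analysis: an ANOVA of a recovery
#' or concentration response against any subset of the design factors
#' (`site`, `pool`/fraction, `labeled_form`, `block`). Block is always kept
#' as a factor when present in `factors`, mirroring the blocked field
#' design. Sums of squares are Type II by default (robust to the mild
#' imbalance of field data; configurable to sequential Type I).
#'
#' A transform can be applied before fitting: `"none"`, `"log"`
#' (log(x + offset), offset = half the smallest positive response when
#' zeros/negatives are present), `"sqrt"`, or `"auto"`, which starts
#' untransformed and switches to log — with a message — when a Shapiro-Wilk
#' check of the residuals fails at the 5 % level. The transform actually
#' used is recorded in the result.
#'
#' @param data A data frame (e.g. a [aggregate_recovery()] table).
#' @param response Name of the response column (string).
#' @param factors Character vector of factor columns; each must have >= 2
#'   levels in `data`.
#' @param transform `"none"`, `"log"`, `"sqrt"` or `"auto"`.
#' @param ss_type `"II"` (default) or `"I"`.
#' @return An object of class `turf_anova`; use [tidy()] for the ANOVA
#'   table and [glance()] for fit summaries.
#' @export
fit_factorial_anova <- function(data, response,
                                factors = c("site", "labeled_form",
                                            "pool", "block"),
                                transform = c("none", "log", "sqrt", "auto"),
                                ss_type = c("II", "I")) {
  transform <- match.arg(transform)
  ss_type <- match.arg(ss_type)
  missing_cols <- setdiff(c(response, factors), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("column(s) not found in data: %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "turftracer_error_config")
  }
  df <- data |>
    dplyr::filter(is.finite(.data[[response]])) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(factors), as.factor))
  for (f in factors) {
    if (nlevels(droplevels(df[[f]])) < 2) {
      abort(sprintf("factor `%s` has fewer than 2 levels in the data.", f),
            class = "turftracer_error_degenerate_design")
    }
  }
  treatment_factors <- setdiff(factors, "block")
  if (length(treatment_factors) > 1) {
    cells <- table(df[treatment_factors])
    if (any(cells == 0)) {
      empty <- which(cells == 0, arr.ind = TRUE, useNames = TRUE)
      lbls <- apply(empty, 1, function(i) {
        paste(mapply(function(d, k) dimnames(cells)[[d]][k],
                     seq_along(treatment_factors), i),
              collapse = " x ")
      })
      abort(sprintf("degenerate design: empty cell(s) %s.",
                    paste(unique(lbls), collapse = "; ")),
            class = "turftracer_error_degenerate_design")
    }
  }

  y <- df[[response]]
  applied <- transform
  offset <- 0
  tf <- function(x, kind, off) {
    switch(kind, none = x, sqrt = sqrt(x), log = log(x + off))
  }
  if (transform == "auto") applied <- "none"
  if (applied == "log" && any(y <= 0)) {
    offset <- min(y[y > 0]) / 2
  }
  df$.response <- tf(y, applied, offset)
  fml <- stats::reformulate(factors, response = ".response")
  fit <- stats::lm(fml, data = df)

  if (transform == "auto") {
    sw <- stats::shapiro.test(stats::residuals(fit))
    if (sw$p.value < 0.05) {
      applied <- "log"
      if (any(y <= 0)) offset <- min(y[y > 0]) / 2
      df$.response <- tf(y, "log", offset)
      fit <- stats::lm(fml, data = df)
      message(sprintf(
        "residual normality check failed (Shapiro-Wilk p = %.3g); refit on log(x%s) scale.",
        sw$p.value, if (offset > 0) sprintf(" + %.3g", offset) else ""))
    }
  }

  tab <- if (ss_type == "II") {
    a <- car::Anova(fit, type = "II")
    tibble::tibble(
      term = trimws(rownames(a)),
      df = a$Df,
      sumsq = a$`Sum Sq`,
      statistic = a$`F value`,
      p.value = a$`Pr(>F)`
    )
  } else {
    a <- stats::anova(fit)
    tibble::tibble(
      term = trimws(rownames(a)),
      df = a$Df,
      sumsq = a$`Sum Sq`,
      statistic = a$`F value`,
      p.value = a$`Pr(>F)`
    )
  }
  structure(
    list(table = tab, model = fit, response = response, factors = factors,
         transform = applied, transform_offset = offset, ss_type = ss_type),
    class = "turf_anova"
  )
}

#' @export
print.turf_anova <- function(x, ...) {
  cat(sprintf("Factorial ANOVA of %s (~ %s), Type %s SS, transform: %s\n",
              x$response, paste(x$factors, collapse = " + "),
              x$ss_type, x$transform))
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.turf_anova <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.turf_anova <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    df.residual = x$model$df.residual,
    transform = x$transform,
    ss_type = x$ss_type
  )
}

#' Between-site contrast on block means
#'
#' The field design supplies only a handful of true replicates (blocks) per
#' site, so between-site tests are run by default on block means: the
#' response is averaged within site x block and a one-way site ANOVA is
#' fitted to the aggregates. This reproduces the small denominator degrees
#' of freedom characteristic of blocked field comparisons. Set
#' `aggregate_blocks = FALSE` to test on raw observations instead; the route
#' used is recorded in the result.
#'
#' @inheritParams fit_factorial_anova
#' @param aggregate_blocks Average over `block` within site before testing?
#' @return A tibble with `term`, `df1`, `df2`, `statistic` (F), `p.value`
#'   and `aggregated`.
#' @export
site_contrast <- function(data, response, aggregate_blocks = TRUE) {
  df <- data |>
    dplyr::filter(is.finite(.data[[response]])) |>
    dplyr::mutate(site = as.factor(.data$site))
  if (nlevels(droplevels(df$site)) < 2) {
    abort("need both sites for a site contrast.",
          class = "turftracer_error_degenerate_design")
  }
  if (aggregate_blocks) {
    df <- df |>
      dplyr::group_by(.data$site, .data$block) |>
      dplyr::summarise(.response = mean(.data[[response]]),
                       .groups = "drop")
  } else {
    df$.response <- df[[response]]
  }
  fit <- stats::aov(.response ~ site, data = df)
  a <- summary(fit)[[1]]
  tibble::tibble(
    term = "site",
    df1 = a$Df[1], df2 = a$Df[2],
    statistic = a$`F value`[1],
    p.value = a$`Pr(>F)`[1],
    aggregated = aggregate_blocks
  )
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise comparisons between levels of one grouping factor with
#' familywise error control (Tukey's honest significant difference).
#'
#' @param data A data frame.
#' @param response Name of the response column.
#' @param group Name of the grouping column (>= 2 levels, each with >= 2
#'   observations).
#' @return Tibble with `contrast`, `estimate` (mean difference),
#'   `conf.low`, `conf.high`, `adj.p.value` and `direction`.
#' @export
tukey_pairwise <- function(data, response, group) {
  df <- data |>
    dplyr::filter(is.finite(.data[[response]])) |>
    dplyr::mutate(.group = as.factor(.data[[group]]))
  counts <- table(droplevels(df$.group))
  if (length(counts) < 2) {
    abort("need at least two groups for pairwise comparisons.",
          class = "turftracer_error_degenerate_design")
  }
  if (any(counts < 2)) {
    abort(sprintf(
      "insufficient replication: group(s) %s have fewer than 2 observations.",
      paste(names(counts)[counts < 2], collapse = ", ")),
      class = "turftracer_error_insufficient_replication")
  }
  df$.response <- df[[response]]
  fit <- stats::aov(.response ~ .group, data = df)
  hsd <- stats::TukeyHSD(fit)$.group
  tibble::tibble(
    contrast = rownames(hsd),
    estimate = hsd[, "diff"],
    conf.low = hsd[, "lwr"],
    conf.high = hsd[, "upr"],
    adj.p.value = hsd[, "p adj"],
    direction = dplyr::case_when(
      hsd[, "diff"] > 0 ~ "greater",
      hsd[, "diff"] < 0 ~ "less",
      TRUE ~ "equal"
    )
  )
}

#' Dual-isotope colocation regression
#'
#' Ordinary least squares of 13C excess concentration on 15N excess
#' concentration across samples of one tissue. Intact uptake of a dual
#' labeled substrate puts 13C and 15N into tissue at the substrate's C:N
#' stoichiometry (3 C per N for alanine and tri-alanine), so a slope near 3
#' indicates intact uptake while uptake of mineralization products carries
#' 15N without 13C (slope near 0).
#'
#' @param data A data frame of paired concentrations.
#' @param x,y Names of the 15N (predictor) and 13C (response) concentration
#'   columns.
#' @return One-row tibble with `slope`, `intercept`, `r.squared`, `p.value`,
#'   `n` and an `undefined` flag (zero variance in the predictor yields a
#'   flagged row of `NA`s rather than an error).
#' @export
isotope_colocation_regression <- function(data,
                                          x = "conc_excess_15N",
                                          y = "conc_excess_13C") {
  df <- data |>
    dplyr::filter(is.finite(.data[[x]]), is.finite(.data[[y]]))
  n <- nrow(df)
  if (n < 3) {
    abort("need at least 3 paired finite values for a regression.",
          class = "turftracer_error_config")
  }
  if (stats::var(df[[x]]) == 0) {
    return(tibble::tibble(slope = NA_real_, intercept = NA_real_,
                          r.squared = NA_real_, p.value = NA_real_,
                          n = n, undefined = TRUE))
  }
  fit <- stats::lm(stats::reformulate(x, response = y), data = df)
  s <- summary(fit)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r.squared = s$r.squared,
    p.value = unname(s$coefficients[2, 4]),
    n = n,
    undefined = FALSE
  )
}
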