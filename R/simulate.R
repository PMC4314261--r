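#' Ground-truth parameters for the synthetic turf experiment
#'
#' Builds the parameter set of the forward simulator, which emulates the
#' full dual-label field design: two grasslands of contrasting productivity,
#' 5 blocks of 5 turves each (four labeled N forms plus a water control), a
#' 2.5 h chase, and harvest into per-species shoots, roots and a
#' fumigation-extraction pair per turf. All defaults can be overridden.
#'
#' Mechanism defaults: organic substrates are mineralized by a
#' single-compartment first-order process with half-lives of 6 min
#' (alanine) and 7.5 min (tri-alanine); label captured intact carries 3 C
#' per N into the consumer, with half of microbially assimilated C respired;
#' label captured after mineralization carries 15N only. Root-captured label
#' passes a form-specific translocation fraction to shoots, split across
#' species by shoot mass share. Per-turf uptake allocations are jittered by
#' a lognormal biological-variability factor (`uptake_cv`).
#'
#' Natural-abundance baselines default to C3-plant values (about -28 permil
#' 13C, low-single-digit 15N) with deliberately noisy 13C (SD 1.5 permil vs
#' 0.5 permil for 15N), reflecting how small the added 13C signal is against
#' the large ambient C pool. Setting both `noise` SDs to zero gives a
#' noise-free experiment whose analysis must reproduce the ground truth
#' exactly.
#'
#' @param sites Site labels (two sites by default).
#' @param n_blocks Replicate blocks per site.
#' @param chase_minutes Chase period between injection and harvest.
#' @param half_life_min Named mineralization half-lives (min) of the
#'   organic forms.
#' @param direct_uptake Tibble `site`, `labeled_form`, `microbial`, `root`:
#'   fractions of the dose captured intact (organics) or directly
#'   (inorganics) by each consumer.
#' @param mineral_uptake Tibble `site`, `microbial`, `root`: fractions of
#'   the mineralized-N pool captured by each consumer.
#' @param translocation Named per-form fractions of root-captured label
#'   translocated to shoots within the chase.
#' @param respired_13C_frac Fraction of microbially assimilated intact-13C
#'   respired as CO2 within the chase.
#' @param uptake_cv Lognormal CV of per-turf biological variability in the
#'   uptake allocations (0 disables).
#' @param resid_extract_frac Fraction of unassimilated residual label that
#'   appears in the K2SO4 extracts (cancels in the fumigation flush).
#' @param biomass Tibble `site`, `pool`, `mean_g`, `sd_g` of whole-turf dry
#'   masses (soil mass from the sites' bulk densities over the 8 cm
#'   injection depth).
#' @param species Named list (per site) of named shoot-mass shares.
#' @param content Tibble `fraction`, `c_content`, `n_content` (g/g DW).
#' @param baselines Tibble `fraction`, `delta13C_mean`, `delta15N_mean`
#'   natural-abundance means (permil).
#' @param noise List with `delta13C_sd`, `delta15N_sd` (permil), the
#'   combined natural-abundance + measurement scatter applied per sample.
#' @param addition Arguments passed to [tracer_addition()] as a list.
#' @param k_extract Fumigation extraction efficiency encoded into the
#'   simulated flush (and assumed by the matching analysis).
#' @return A list of class `experiment_params`.
#' @export
experiment_params <- function(
    sites = c("high", "low"),
    n_blocks = 5,
    chase_minutes = 150,
    half_life_min = c(alanine = 6, trialanine = 7.5),
    direct_uptake = NULL,
    mineral_uptake = NULL,
    translocation = c(NO3 = 0.25, NH4 = 0.2, alanine = 0.12,
                      trialanine = 0.1),
    respired_13C_frac = 0.5,
    uptake_cv = 0.3,
    resid_extract_frac = 0.5,
    biomass = NULL,
    species = NULL,
    content = NULL,
    baselines = NULL,
    noise = list(delta13C_sd = 1.5, delta15N_sd = 0.5),
    addition = list(),
    k_extract = 1) {
  direct_uptake <- direct_uptake %||% tibble::tribble(
    ~site,  ~labeled_form, ~microbial, ~root,
    "high", "NO3",         0.030,      0.055,
    "high", "NH4",         0.080,      0.060,
    "high", "alanine",     0.140,      0.025,
    "high", "trialanine",  0.090,      0.020,
    "low",  "NO3",         0.015,      0.010,
    "low",  "NH4",         0.050,      0.040,
    "low",  "alanine",     0.080,      0.012,
    "low",  "trialanine",  0.050,      0.015
  ) |> dplyr::filter(.data$site %in% sites)
  mineral_uptake <- mineral_uptake %||% tibble::tibble(
    site = c("high", "low"), microbial = c(0.12, 0.08),
    root = c(0.06, 0.035)
  ) |> dplyr::filter(.data$site %in% sites)
  biomass <- biomass %||% tibble::tribble(
    ~site,  ~pool,   ~mean_g, ~sd_g,
    "high", "shoot", 15,      2,
    "high", "root",  60,      8,
    "high", "soil",  3488,    200,
    "low",  "shoot", 8,       1.2,
    "low",  "root",  120,     15,
    "low",  "soil",  1440,    120
  ) |> dplyr::filter(.data$site %in% sites)
  species <- species %||% list(
    high = c("Trifolium repens" = 0.5, "Poa trivialis" = 0.5),
    low = c("Agrostis capillaris" = 0.30, "Anthoxanthum odoratum" = 0.25,
            "Festuca ovina" = 0.20, "Luzula sp." = 0.15,
            "Potentilla erecta" = 0.10)
  )[sites]
  content <- content %||% tibble::tribble(
    ~fraction,           ~c_content, ~n_content,
    "shoot",             0.45,       0.030,
    "root",              0.42,       0.015,
    "soil_fumigated",    4e-4,       8e-5,
    "soil_nonfumigated", 2e-4,       3e-5
  )
  baselines <- baselines %||% tibble::tribble(
    ~fraction,           ~delta13C_mean, ~delta15N_mean,
    "shoot",             -29,            1.5,
    "root",              -28,            2.5,
    "soil_fumigated",    -27,            3.5,
    "soil_nonfumigated", -27,            3.5
  )
  allocs <- dplyr::left_join(direct_uptake, mineral_uptake, by = "site",
                             suffix = c("", "_mineral"))
  if (any(allocs$microbial + allocs$root > 1) ||
      any(allocs$microbial_mineral + allocs$root_mineral > 1) ||
      any(unlist(direct_uptake[c("microbial", "root")]) < 0) ||
      any(translocation < 0 | translocation > 1)) {
    abort("uptake allocations and translocation fractions must be in [0, 1] and sum to <= 1 per form.",
          class = "turftracer_error_invalid_params")
  }
  if (any(half_life_min <= 0) || chase_minutes <= 0) {
    abort("half-lives and chase time must be positive.",
          class = "turftracer_error_invalid_params")
  }
  structure(
    list(sites = sites, n_blocks = n_blocks, chase_minutes = chase_minutes,
         half_life_min = half_life_min, direct_uptake = direct_uptake,
         mineral_uptake = mineral_uptake, translocation = translocation,
         respired_13C_frac = respired_13C_frac, uptake_cv = uptake_cv,
         resid_extract_frac = resid_extract_frac, biomass = biomass,
         species = species, content = content, baselines = baselines,
         noise = noise, addition = addition, k_extract = k_extract),
    class = "experiment_params"
  )
}

# lognormal mean-1 multiplier for biological variability
ln_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

rnorm_pos <- function(n, mean, sd) pmax(rnorm(n, mean, sd), mean * 0.1)

#' Forward-simulate the dual-label turf experiment
#'
#' Generates one realisation of the full experiment under the mechanism in
#' [experiment_params()], returning both the measurement table (the same
#' schema [compute_enrichment()] consumes) and the ground truth of where
#' every labeled atom ended up, so the downstream mass balance can be
#' validated end to end.
#'
#' One master seed governs the run; per-turf seeds are derived from it so
#' any single turf is reproducible in isolation. Atom conservation holds
#' exactly in the truth table: per turf, the 15N in
#' microbial + root + shoot + residual pools equals the added label, and the
#' 13C in pools + residual + respired CO2 equals the added 13C.
#'
#' @param params An [experiment_params()] object.
#' @param seed Integer master seed.
#' @return A list of class `turf_simulation` with elements `measurements`
#'   (tibble, [read_measurements()] schema), `truth` (per turf x pool true
#'   label content and recovery, with the intact vs mineralized 15N split),
#'   `additions` (the [tracer_addition()] table) and `params`.
#' @export
simulate_experiment <- function(params = experiment_params(), seed = 1) {
  stopifnot(inherits(params, "experiment_params"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)

  additions <- do.call(tracer_addition, params$addition)
  forms <- c(n_forms(), "control")
  design <- tidyr::expand_grid(
    site = params$sites,
    block = seq_len(params$n_blocks),
    labeled_form = forms
  ) |>
    dplyr::mutate(turf = sprintf("%s_b%d_%s", site, block, labeled_form))
  turf_seeds <- sample.int(.Machine$integer.max - 1, nrow(design))

  sys13 <- isotope_system("13C")
  sys15 <- isotope_system("15N")

  res <- purrr::pmap(
    list(design$site, design$block, design$labeled_form, turf_seeds),
    function(site, block, form, tseed) {
      set.seed(tseed)
      simulate_turf(site, block, form, params, additions, sys13, sys15)
    }
  )
  measurements <- purrr::map_dfr(res, "measurements")
  truth <- purrr::map_dfr(res, "truth")
  structure(
    list(measurements = measurements, truth = truth,
         additions = additions, params = params, seed = seed),
    class = "turf_simulation"
  )
}

#' @export
print.turf_simulation <- function(x, ...) {
  cat(sprintf(
    "<turf_simulation> seed %d: %d sites x %d blocks, %d measurement rows\n",
    x$seed, length(x$params$sites), x$params$n_blocks, nrow(x$measurements)))
  invisible(x)
}

# One turf: allocate label per the mechanism, then express pool contents as
# the delta values an IRMS would report. Assumes the RNG substream for this
# turf is already seeded.
simulate_turf <- function(site, block, form, params, additions,
                          sys13, sys15) {
  turf <- sprintf("%s_b%d_%s", site, block, form)
  spp <- params$species[[site]]
  bm <- params$biomass[params$biomass$site == site, ]
  mass <- setNames(
    rnorm_pos(nrow(bm), bm$mean_g, bm$sd_g), bm$pool)
  sp_mass <- mass[["shoot"]] * spp / sum(spp)

  is_control <- form == "control"
  is_organic <- form %in% c("alanine", "trialanine")
  D15 <- if (is_control) 0 else
    additions$added_label_nmol_15N[additions$labeled_form == form]
  D13 <- if (is_control) 0 else
    additions$added_label_nmol_13C[additions$labeled_form == form]

  if (!is_control) {
    du <- params$direct_uptake
    du <- du[du$site == site & du$labeled_form == form, ]
    mu <- params$mineral_uptake[params$mineral_uptake$site == site, ]
    m <- ln_mult(2, params$uptake_cv)  # microbial, root multipliers
    a_mic <- du$microbial * m[1]
    a_root <- du$root * m[2]
    if ((s <- a_mic + a_root) > 0.95) {
      a_mic <- a_mic * 0.95 / s; a_root <- a_root * 0.95 / s
    }
    b_mic <- mu$microbial * m[1]
    b_root <- mu$root * m[2]
    if ((s <- b_mic + b_root) > 0.95) {
      b_mic <- b_mic * 0.95 / s; b_root <- b_root * 0.95 / s
    }
    if (is_organic) {
      mic15_i <- a_mic * D15
      root15_i <- a_root * D15
      U <- D15 - mic15_i - root15_i
      k <- log(2) / params$half_life_min[[form]]
      intact_remaining <- U * exp(-k * params$chase_minutes)
      M <- U - intact_remaining
      mic15_m <- b_mic * M
      root15_m <- b_root * M
      resid15 <- intact_remaining + (M - mic15_m - root15_m)
    } else {
      mic15_i <- 0; root15_i <- 0
      mic15_m <- a_mic * D15
      root15_m <- a_root * D15
      intact_remaining <- 0
      resid15 <- D15 - mic15_m - root15_m
    }
    tf <- params$translocation[[form]]
    root15_cap_i <- root15_i; root15_cap_m <- root15_m
    shoot15_i <- tf * root15_cap_i; shoot15_m <- tf * root15_cap_m
    root15_i <- (1 - tf) * root15_cap_i
    root15_m <- (1 - tf) * root15_cap_m
    mic15 <- mic15_i + mic15_m
    root15 <- root15_i + root15_m
    shoot15 <- shoot15_i + shoot15_m

    if (is_organic) {
      mic13_assim <- 3 * mic15_i
      respired13 <- params$respired_13C_frac * mic13_assim +
        3 * (D15 - mic15_i - root15_cap_i - intact_remaining)
      mic13 <- mic13_assim * (1 - params$respired_13C_frac)
      root13_cap <- 3 * root15_cap_i
      shoot13 <- tf * root13_cap
      root13 <- (1 - tf) * root13_cap
      resid13 <- 3 * intact_remaining
    } else {
      mic13 <- 0; root13 <- 0; shoot13 <- 0
      respired13 <- 0; resid13 <- 0
    }
  } else {
    mic15 <- root15 <- shoot15 <- resid15 <- 0
    mic15_i <- root15_i <- shoot15_i <- 0
    mic13 <- root13 <- shoot13 <- resid13 <- respired13 <- 0
    intact_remaining <- 0
  }

  truth <- tibble::tibble(
    site = site, block = block, turf = turf, labeled_form = form,
    pool = c("microbial", "root", "shoot", "residual", "respired_CO2"),
    true_nmol_15N = c(mic15, root15, shoot15, resid15, 0),
    true_nmol_13C = c(mic13, root13, shoot13, resid13, respired13),
    true_nmol_15N_intact = c(mic15_i, root15_i, shoot15_i,
                             intact_remaining, NA),
    true_recovery_pct_15N = if (is_control) {
      c(0, 0, 0, NA, NA)
    } else {
      100 * c(mic15, root15, shoot15, resid15, 0) / D15
    },
    true_recovery_pct_13C = if (D13 > 0) {
      100 * c(mic13, root13, shoot13, resid13, respired13) / D13
    } else {
      rep(NA_real_, 5)
    }
  )

  # express pool contents as measurements -------------------------------
  cont <- params$content
  base <- params$baselines
  meas_row <- function(fraction, species, conc13, conc15, mass_g) {
    cc <- cont[cont$fraction == fraction, ]
    bb <- base[base$fraction == fraction, ]
    ape13 <- conc13 * 100 * sys13$atomic_mass / (cc$c_content * 1e9)
    ape15 <- conc15 * 100 * sys15$atomic_mass / (cc$n_content * 1e9)
    ap13 <- delta_to_atom_percent(bb$delta13C_mean, sys13) + ape13
    ap15 <- delta_to_atom_percent(bb$delta15N_mean, sys15) + ape15
    tibble::tibble(
      site = site, block = block, turf = turf, labeled_form = form,
      fraction = fraction, species = species,
      delta13C_permil = atom_percent_to_delta(ap13, sys13) +
        rnorm(1, 0, params$noise$delta13C_sd),
      delta15N_permil = atom_percent_to_delta(ap15, sys15) +
        rnorm(1, 0, params$noise$delta15N_sd),
      c_content = cc$c_content, n_content = cc$n_content,
      pool_dry_mass_g = mass_g
    )
  }

  ext15 <- params$resid_extract_frac * resid15 / mass[["soil"]]
  ext13 <- params$resid_extract_frac * resid13 / mass[["soil"]]
  flush15 <- params$k_extract * mic15 / mass[["soil"]]
  flush13 <- params$k_extract * mic13 / mass[["soil"]]

  shoot_rows <- purrr::imap(sp_mass, function(ms, sp) {
    share <- ms / sum(sp_mass)
    meas_row("shoot", sp, shoot13 * share / ms, shoot15 * share / ms, ms)
  })
  measurements <- dplyr::bind_rows(
    dplyr::bind_rows(shoot_rows),
    meas_row("root", NA_character_, root13 / mass[["root"]],
             root15 / mass[["root"]], mass[["root"]]),
    meas_row("soil_fumigated", NA_character_,
             ext13 + flush13, ext15 + flush15, mass[["soil"]]),
    meas_row("soil_nonfumigated", NA_character_,
             ext13, ext15, mass[["soil"]])
  )
  list(measurements = measurements, truth = truth)
}

#' Compare estimated recoveries against simulator ground truth
#'
#' Joins an estimated recovery table to the matching ground truth and
#' summarises estimation error (bias and RMSE, in percentage points of
#' added label) per site x N form x pool, across however many replicate
#' simulations are bound into the inputs.
#'
#' @param truth Truth table(s) from [simulate_experiment()] (bind rows of
#'   several replicates for a simulation study; keys must stay unique, e.g.
#'   by adding a `replicate` column to both inputs).
#' @param estimated Recovery table(s) from [aggregate_recovery()].
#' @return Tibble with `site`, `labeled_form`, `pool`, `n_obs`,
#'   `bias_pct_15N`, `rmse_pct_15N`, `bias_pct_13C`, `rmse_pct_13C`.
#' @export
parameter_recovery_report <- function(truth, estimated) {
  keys <- intersect(
    c("replicate", "site", "block", "turf", "labeled_form", "pool"),
    intersect(names(truth), names(estimated)))
  joined <- dplyr::inner_join(
    dplyr::filter(truth, .data$pool %in% c("microbial", "root", "shoot"),
                  .data$labeled_form != "control"),
    dplyr::filter(estimated, .data$labeled_form != "control"),
    by = keys
  )
  if (nrow(joined) == 0) {
    abort("no matching turf x pool keys between truth and estimates.",
          class = "turftracer_error_join")
  }
  joined |>
    dplyr::group_by(site, labeled_form, pool) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      bias_pct_15N = mean(.data$recovery_pct_15N -
                            .data$true_recovery_pct_15N),
      rmse_pct_15N = sqrt(mean((.data$recovery_pct_15N -
                                  .data$true_recovery_pct_15N)^2)),
      bias_pct_13C = mean(.data$recovery_pct_13C -
                            .data$true_recovery_pct_13C),
      rmse_pct_13C = sqrt(mean((.data$recovery_pct_13C -
                                  .data$true_recovery_pct_13C)^2)),
      .groups = "drop"
    )
}
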