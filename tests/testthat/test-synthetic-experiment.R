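test_that("invalid parameters are rejected", {
  bad_alloc <- experiment_params()$direct_uptake
  bad_alloc$microbial[1] <- 0.9
  bad_alloc$root[1] <- 0.8
  expect_error(experiment_params(direct_uptake = bad_alloc),
               class = "turftracer_error_invalid_params")
  expect_error(experiment_params(chase_minutes = -1),
               class = "turftracer_error_invalid_params")
  expect_error(experiment_params(half_life_min = c(alanine = 0,
                                                   trialanine = 7.5)),
               class = "turftracer_error_invalid_params")
})

test_that("atom conservation holds exactly in the ground truth", {
  sim <- simulate_experiment(small_params(), seed = 17)
  add <- sim$additions
  totals <- sim$truth |>
    dplyr::filter(labeled_form != "control") |>
    dplyr::group_by(turf, labeled_form) |>
    dplyr::summarise(n15 = sum(true_nmol_15N), c13 = sum(true_nmol_13C),
                     .groups = "drop") |>
    dplyr::left_join(add, by = "labeled_form")
  expect_equal(totals$n15, totals$added_label_nmol_15N, tolerance = 1e-12)
  expect_equal(totals$c13, totals$added_label_nmol_13C, tolerance = 1e-12)
})

test_that("zero uptake with zero noise yields baseline deltas and 0 recovery", {
  zero_alloc <- experiment_params()$direct_uptake |>
    dplyr::mutate(microbial = 0, root = 0)
  zero_min <- tibble::tibble(site = c("high", "low"),
                             microbial = 0, root = 0)
  p <- small_params(direct_uptake = zero_alloc, mineral_uptake = zero_min,
                    resid_extract_frac = 0, noise = noise_free())
  sim <- simulate_experiment(p, seed = 19)
  # every treatment delta equals its fraction's baseline
  m <- dplyr::left_join(sim$measurements, p$baselines, by = "fraction")
  expect_equal(m$delta15N_permil, m$delta15N_mean, tolerance = 1e-9)
  expect_equal(m$delta13C_permil, m$delta13C_mean, tolerance = 1e-9)
  rec <- aggregate_recovery(compute_enrichment(sim$measurements),
                            sim$additions)
  expect_equal(max(abs(rec$recovery_pct_15N)), 0, tolerance = 1e-9)
})

test_that("half-life bookkeeping: one half-life leaves half the dose intact", {
  zero_alloc <- experiment_params()$direct_uptake |>
    dplyr::mutate(microbial = 0, root = 0)
  zero_min <- tibble::tibble(site = c("high", "low"),
                             microbial = 0, root = 0)
  p <- small_params(direct_uptake = zero_alloc, mineral_uptake = zero_min,
                    chase_minutes = 6,
                    half_life_min = c(alanine = 6, trialanine = 7.5),
                    noise = noise_free())
  sim <- simulate_experiment(p, seed = 23)
  resid <- sim$truth |>
    dplyr::filter(labeled_form == "alanine", pool == "residual")
  dose <- sim$additions$added_label_nmol_15N[
    sim$additions$labeled_form == "alanine"]
  expect_equal(resid$true_nmol_15N_intact, rep(dose / 2, nrow(resid)),
               tolerance = 1e-12)
  expect_equal(resid$true_nmol_15N, rep(dose, nrow(resid)),
               tolerance = 1e-12)
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_experiment(small_params(), seed = 29)
  s2 <- simulate_experiment(small_params(), seed = 29)
  s3 <- simulate_experiment(small_params(), seed = 30)
  expect_identical(s1$measurements, s2$measurements)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$measurements, s3$measurements))
})

test_that("intact uptake carries 3 C per N; microbial C is respired in part", {
  p <- small_params(
    mineral_uptake = tibble::tibble(site = c("high", "low"),
                                    microbial = 0, root = 0),
    noise = noise_free())
  sim <- simulate_experiment(p, seed = 31)
  org <- dplyr::filter(sim$truth,
                       labeled_form %in% c("alanine", "trialanine"))
  plant <- dplyr::filter(org, pool %in% c("root", "shoot"))
  expect_equal(plant$true_nmol_13C, 3 * plant$true_nmol_15N,
               tolerance = 1e-12)
  mic <- dplyr::filter(org, pool == "microbial", true_nmol_15N > 0)
  expect_equal(mic$true_nmol_13C,
               3 * mic$true_nmol_15N * (1 - p$respired_13C_frac),
               tolerance = 1e-12)
})

test_that("colocation slope separates intact uptake from mineralization", {
  pure_intact <- small_params(
    mineral_uptake = tibble::tibble(site = c("high", "low"),
                                    microbial = 0, root = 0),
    noise = noise_free())
  sim <- simulate_experiment(pure_intact, seed = 37)
  plant <- compute_enrichment(sim$measurements) |>
    dplyr::filter(pool %in% c("root", "shoot"),
                  labeled_form == "trialanine")
  expect_equal(isotope_colocation_regression(plant)$slope, 3,
               tolerance = 1e-6)

  no_intact <- experiment_params()$direct_uptake |>
    dplyr::mutate(
      microbial = ifelse(labeled_form %in% c("alanine", "trialanine"),
                         0, microbial),
      root = ifelse(labeled_form %in% c("alanine", "trialanine"), 0, root))
  sim2 <- simulate_experiment(
    small_params(direct_uptake = no_intact, noise = noise_free()),
    seed = 38)
  plant2 <- compute_enrichment(sim2$measurements) |>
    dplyr::filter(pool %in% c("root", "shoot"),
                  labeled_form == "trialanine")
  expect_equal(isotope_colocation_regression(plant2)$slope, 0,
               tolerance = 1e-9)
})

test_that("simulated control-set turves have nonnegative 13C excess", {
  sim <- simulate_experiment(small_params(), seed = 41)  # default noise
  enr <- suppressWarnings(compute_enrichment(sim$measurements))
  ctl13 <- dplyr::filter(enr, labeled_form %in% c("control", "NO3", "NH4"),
                         pool %in% c("root", "shoot"))
  expect_true(all(ctl13$ape_13C >= 0))
})

test_that("recovery report is zero for perfect estimates and grows with noise", {
  sim <- simulate_experiment(small_params(noise = noise_free()), seed = 43)
  rec <- aggregate_recovery(compute_enrichment(sim$measurements),
                            sim$additions)
  rep0 <- parameter_recovery_report(sim$truth, rec)
  expect_equal(max(abs(rep0$bias_pct_15N)), 0, tolerance = 1e-9)
  expect_equal(max(rep0$rmse_pct_15N), 0, tolerance = 1e-9)

  rmse_at <- function(sd15, seeds) {
    out <- lapply(seeds, function(s) {
      p <- small_params(noise = list(delta13C_sd = 1.5, delta15N_sd = sd15))
      sim <- simulate_experiment(p, seed = s)
      enr <- suppressWarnings(compute_enrichment(sim$measurements))
      rec <- aggregate_recovery(enr, sim$additions)
      list(truth = dplyr::mutate(sim$truth, replicate = s),
           rec = dplyr::mutate(rec, replicate = s))
    })
    rep_tab <- parameter_recovery_report(
      dplyr::bind_rows(lapply(out, `[[`, "truth")),
      dplyr::bind_rows(lapply(out, `[[`, "rec")))
    mean(rep_tab$rmse_pct_15N)
  }
  expect_lt(rmse_at(0.5, 101:106), rmse_at(1.0, 101:106))

  bad <- dplyr::mutate(sim$truth, turf = paste0(turf, "_x"))
  expect_error(parameter_recovery_report(bad, rec),
               class = "turftracer_error_join")
})
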