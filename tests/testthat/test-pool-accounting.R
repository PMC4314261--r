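test_that("tracer addition reproduces the experiment's dose arithmetic", {
  ta <- tracer_addition("NH4")
  expect_equal(ta$per_form_umol_N, 25)
  expect_equal(ta$total_mg_N, 100 * 14.007 / 1000)        # 1.4007 mg
  expect_equal(ta$areal_total_mgN_m2, 1.4007 / 0.04)      # 35.0175
  expect_equal(ta$areal_per_form_mgN_m2, 8.754375)
  expect_equal(ta$added_label_nmol_15N, 25 * 0.98 * 1000) # 24500 nmol
  expect_equal(ta$added_label_nmol_13C, 0)                # inorganic: no C
})

test_that("organic forms carry 3 labeled C per labeled N", {
  ta <- tracer_addition(c("alanine", "trialanine"))
  expect_equal(ta$added_label_nmol_13C, 3 * ta$added_label_nmol_15N)
})

test_that("a single-form mixture is the degenerate identity", {
  ta <- tracer_addition("NO3", total_umol_N = 40, n_forms_mixed = 1)
  expect_equal(ta$per_form_umol_N, 40)
  expect_equal(ta$total_mg_N, ta$per_form_mg_N)
})

test_that("tracer addition rejects invalid configuration", {
  expect_error(tracer_addition("NH4", total_umol_N = 0),
               class = "turftracer_error_config")
  expect_error(tracer_addition("NH4", label_atom_fraction = 1.2),
               class = "turftracer_error_config")
  expect_error(tracer_addition("glycine"),
               class = "turftracer_error_config")
})

test_that("tissue excess concentration follows the closed form", {
  sys15 <- isotope_system("15N")
  expect_equal(tissue_excess_concentration(0, 0.02, sys15), 0)
  # hand arithmetic: 0.01/100 * 0.02 / 14.007 * 1e9 = 142.786 nmol/g
  expect_equal(tissue_excess_concentration(0.01, 0.02, sys15),
               142.786, tolerance = 1e-5)
  # linear in both arguments
  expect_equal(tissue_excess_concentration(0.01, 0.04, sys15),
               2 * tissue_excess_concentration(0.01, 0.02, sys15))
  expect_equal(tissue_excess_concentration(0.02, 0.02, sys15),
               2 * tissue_excess_concentration(0.01, 0.02, sys15))
  expect_error(tissue_excess_concentration(0.01, 1.5, sys15),
               class = "turftracer_error_invalid_composition")
})

test_that("fumigation flush arithmetic and extraction correction", {
  expect_equal(microbial_excess(4, 4), 0)
  expect_equal(microbial_excess(10, 4), 6)
  expect_equal(microbial_excess(10, 4, k_extract = 0.54), 6 / 0.54)
  expect_equal(microbial_excess(10, 4, k_extract = 0.54),
               11.111, tolerance = 1e-4)
  # smaller k strictly increases the estimate; k = 1 is the raw flush
  expect_gt(microbial_excess(10, 4, 0.45), microbial_excess(10, 4, 0.54))
  # negative flushes are retained
  expect_equal(microbial_excess(3, 4), -1)
  expect_error(microbial_excess(10, 4, k_extract = 0),
               class = "turftracer_error_config")
  expect_error(microbial_excess(c(1, 2), 1),
               class = "turftracer_error_missing_pair")
})

test_that("pool recovery mass balance", {
  expect_equal(pool_recovery(100, 50, 25000), 20)
  expect_equal(pool_recovery(0, 50, 25000), 0)
  # bilinearity: conc x2 with mass x0.5 leaves recovery unchanged
  expect_equal(pool_recovery(200, 25, 25000), pool_recovery(100, 50, 25000))
  expect_error(pool_recovery(1, 1, 0), class = "turftracer_error_config")
})

test_that("recovery aggregation sums pools and attaches turf totals", {
  enr <- manual_enrichment()
  add <- tracer_addition("NH4")
  rec <- aggregate_recovery(enr, add)
  lab <- dplyr::filter(rec, labeled_form == "NH4")
  expect_setequal(lab$pool, c("microbial", "root", "shoot"))
  expected <- 100 * c(2 * 1000, 10 * 50, 5 * 10) / add$added_label_nmol_15N
  expect_equal(lab$recovery_pct_15N[match(c("microbial", "root", "shoot"),
                                          lab$pool)], expected)
  expect_equal(unique(lab$turf_total_pct_15N), sum(expected))
  # control turf reports zero recovery
  ctl <- dplyr::filter(rec, labeled_form == "control")
  expect_true(all(ctl$recovery_pct_15N == 0))
})

test_that("recovery is invariant to splitting a pool into subsamples", {
  enr <- manual_enrichment()
  root <- dplyr::filter(enr, pool == "root", labeled_form == "NH4")
  split_root <- dplyr::bind_rows(
    dplyr::mutate(root, pool_dry_mass_g = 20),
    dplyr::mutate(root, pool_dry_mass_g = 30))
  enr_split <- dplyr::bind_rows(
    dplyr::filter(enr, !(pool == "root" & labeled_form == "NH4")),
    split_root)
  r1 <- aggregate_recovery(enr, tracer_addition("NH4"))
  r2 <- aggregate_recovery(enr_split, tracer_addition("NH4"))
  k <- c("turf", "pool")
  expect_equal(
    dplyr::arrange(tibble::as_tibble(r1), turf, pool)$recovery_pct_15N,
    dplyr::arrange(tibble::as_tibble(r2), turf, pool)$recovery_pct_15N)
})

test_that("13C recovery is only reported for organic-form turves", {
  sim <- simulate_experiment(small_params(noise = noise_free()), seed = 3)
  rec <- aggregate_recovery(compute_enrichment(sim$measurements),
                            sim$additions)
  lab <- dplyr::filter(rec, labeled_form != "control")
  expect_true(all(is.na(
    lab$recovery_pct_13C[lab$labeled_form %in% c("NO3", "NH4")])))
  expect_true(all(is.finite(
    lab$recovery_pct_13C[!lab$labeled_form %in% c("NO3", "NH4")])))
})

test_that("noise-free simulated recovery matches ground truth exactly", {
  sim <- simulate_experiment(small_params(noise = noise_free()), seed = 5)
  rec <- aggregate_recovery(compute_enrichment(sim$measurements),
                            sim$additions)
  j <- dplyr::inner_join(
    dplyr::filter(sim$truth, pool %in% c("microbial", "root", "shoot"),
                  labeled_form != "control"),
    tibble::as_tibble(rec),
    by = c("site", "block", "turf", "labeled_form", "pool"))
  expect_equal(j$recovery_pct_15N, j$true_recovery_pct_15N,
               tolerance = 1e-9)
  expect_equal(j$recovery_pct_13C[!is.na(j$true_recovery_pct_13C)],
               j$true_recovery_pct_13C[!is.na(j$true_recovery_pct_13C)],
               tolerance = 1e-9)
  # whole-turf totals never exceed the added dose on noise-free data
  expect_true(all(rec$turf_total_pct_15N <= 100 + 1e-6))
})

test_that("missing additions and unknown forms are reported", {
  enr <- manual_enrichment()
  expect_error(aggregate_recovery(enr, tracer_addition("NO3")),
               class = "turftracer_error_config")
})
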