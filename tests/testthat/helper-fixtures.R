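# Small parameter sets and hand-built tables shared across tests.

# a reduced design (2 blocks) for fast simulator-based tests
small_params <- function(...) {
  experiment_params(n_blocks = 2, ...)
}

noise_free <- function() list(delta13C_sd = 0, delta15N_sd = 0)

# hand-built enrichment table: one labeled turf with all three pools plus a
# control turf, at exactly known concentrations
manual_enrichment <- function(conc_mic = 2, conc_root = 10, conc_shoot = 5,
                              mass_mic = 1000, mass_root = 50,
                              mass_shoot = 10) {
  tibble::tibble(
    site = "high", block = 1L,
    turf = c(rep("t1", 3), rep("t0", 3)),
    labeled_form = c(rep("NH4", 3), rep("control", 3)),
    pool = rep(c("microbial", "root", "shoot"), 2),
    species = rep(c(NA, NA, "Poa trivialis"), 2),
    ape_13C = 0, ape_15N = 0, baseline_13C = 1.1, baseline_15N = 0.366,
    conc_excess_13C = 0,
    conc_excess_15N = c(conc_mic, conc_root, conc_shoot, 0, 0, 0),
    pool_dry_mass_g = rep(c(mass_mic, mass_root, mass_shoot), 2)
  )
}

# minimal valid measurements CSV content (3 rows: shoot + extract pair)
manual_measurements <- function() {
  tibble::tibble(
    site = "high", block = 1L, turf = "t1", labeled_form = "NH4",
    fraction = c("shoot", "soil_fumigated", "soil_nonfumigated"),
    species = c("Poa trivialis", NA, NA),
    delta13C_permil = -28, delta15N_permil = c(25, 8, 4),
    c_content = c(0.45, 4e-4, 2e-4), n_content = c(0.03, 8e-5, 3e-5),
    pool_dry_mass_g = c(12, 3000, 3000)
  )
}
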