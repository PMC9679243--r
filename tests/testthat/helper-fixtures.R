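# Shared fixtures built in code. Simulations are cached per session so
# several test files can reuse the same cleaned census without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

fixture_clean_census <- function(initial_n = 1000L, seed = 11L) {
  key <- paste0("clean_", initial_n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    sim <- simulateCensus(simParams(initial_n = initial_n), seed = seed)
    .fixture_env[[key]] <- list(clean = cleanCensus(sim$records),
                                records = sim$records, truth = sim$truth)
  }
  .fixture_env[[key]]
}

fixture_population_rates <- function(initial_n = 1000L, seed = 11L) {
  key <- paste0("rates_", initial_n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    fx <- fixture_clean_census(initial_n, seed)
    .fixture_env[[key]] <- suppressWarnings(fitPopulationRates(fx$clean))
  }
  .fixture_env[[key]]
}

# generator configuration for truth-kernel agreement: the fully observable
# subprocess (no dormancy; dormancy is only partially observable, see the
# methods vignette), gentle linear size effects, recruit sizes spread over
# the mesh, no interannual variation
agreement_params <- function(n = 100000L) {
  simParams(initial_n = n,
            surv_N = c(-0.5, 0.04), surv_B = c(-0.85), surv_D = c(0.85),
            growth = c(4, 0.9), growth_sd = 3,
            trans_NB = c(-2.5, 0.02), trans_ND = c(-30), trans_BN = c(0),
            trans_BD = c(-30), trans_DN = c(0.85), trans_DB = c(-2.2),
            pfl_N = c(-3, 0.08), pfl_B = c(2.2),
            fec_N = c(1.0, 0.02), fec_B = c(2.2),
            recruit_rate = 0.1, recruit_mu = 10, recruit_sd = 5,
            year_sd = c(surv_N = 0))
}

# tiny census table for parser tests
toy_census_df <- function() {
  data.frame(population = "A", transect = "T1", quadrat = "Q1",
             plant_id = c("p1", "p1", "p2"),
             year = c(1990L, 1991L, 1990L),
             diameter_mm = c(10, NA, 12.5),
             survival = c(1L, 1L, 1L),
             fruits = c(0, 3, NA),
             stringsAsFactors = FALSE)
}
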