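# shared fixtures: canonical scenario sets and quick simulations

diploid_set <- function() enumerate_scenarios(2)

extended_diploid_set <- function() {
  enumerate_scenarios(2, trinucleate = TRUE, biii = TRUE)
}

# build a specific scenario briefly
sexual_diploid <- function(m = 2, p = m) {
  scenario_spec(m, egg_reduced = TRUE, embryo_fertilized = TRUE,
                polar_nuclei = 2L, polar_reduced = TRUE,
                endosperm_sperms = 1L, pollen_ploidy = p,
                sperm_reduced = TRUE)
}

apomict_diploid <- function(polar_nuclei = 2L, endosperm_sperms = 1L,
                            sperm_reduced = TRUE, pollen_ploidy = 2,
                            m = 2) {
  scenario_spec(m, egg_reduced = FALSE, embryo_fertilized = FALSE,
                polar_nuclei = polar_nuclei, polar_reduced = FALSE,
                endosperm_sperms = endosperm_sperms,
                pollen_ploidy = if (endosperm_sperms > 0) pollen_ploidy else NA,
                sperm_reduced = if (endosperm_sperms > 0) sperm_reduced else NA)
}

biii_diploid <- function(m = 2, p = 2) {
  scenario_spec(m, egg_reduced = FALSE, embryo_fertilized = TRUE,
                polar_nuclei = 2L, polar_reduced = FALSE,
                endosperm_sperms = 1L, pollen_ploidy = p,
                sperm_reduced = FALSE)
}

quick_sim <- function(scenario = "2/3", seed = 1, ...) {
  simulate_histogram(seed_sim(scenario, ...), rng_seed = seed)
}
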