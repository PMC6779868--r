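test_that("simulated histogram totals equal the requested particle count", {
  for (n in c(1L, 500L, 5000L)) {
    s <- simulate_histogram(seed_sim("2/5", total_particles = n),
                            rng_seed = 7)
    expect_identical(sum(s$histogram$counts), n)
  }
})

test_that("simulation is bitwise deterministic for a fixed seed", {
  a <- quick_sim("2/6", seed = 99)
  b <- quick_sim("2/6", seed = 99)
  expect_identical(a$histogram$counts, b$histogram$counts)
  c <- quick_sim("2/6", seed = 100)
  expect_false(identical(a$histogram$counts, c$histogram$counts))

  cfg <- list(list(species = "sp", mix = c("2/3" = 0.5, "2/5" = 0.5),
                   n_seeds = 4))
  s1 <- simulate_seed_set(cfg, rng_seed = 5)
  s2 <- simulate_seed_set(cfg, rng_seed = 5)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$histograms[[2]]$histogram$counts,
                   s2$histograms[[2]]$histogram$counts)

  t1 <- simulate_trait_table(trait_sim_config(rng_seed = 3))
  t2 <- simulate_trait_table(trait_sim_config(rng_seed = 3))
  expect_identical(t1, t2)
})

test_that("histogram modes sit at the scenario's expected positions", {
  # sexual: endosperm mode at 1.5x the embryo position
  s <- quick_sim("2/3", seed = 8)
  sm <- s$histogram$counts
  expect_lt(abs(which.max(sm[80:120]) + 79 - 100), 3)
  expect_lt(abs(which.max(sm[130:170]) + 129 - 150), 4)
  # pseudogamy 2/5: endosperm mode near 250
  s <- quick_sim("2/5", seed = 9)
  expect_lt(abs(which.max(s$histogram$counts[230:270]) + 229 - 250), 5)
})

test_that("the mode ratio converges to the scenario quotient at small CV", {
  for (lab in c("2/4", "2/5", "2/6")) {
    s <- simulate_histogram(
      seed_sim(lab, cv = 0.5, embryo_position = 200, total_particles = 20000,
               debris_frac = 0.05),
      rng_seed = 13)
    cnt <- s$histogram$counts
    q_true <- parse_profile(lab)$quotient
    emb <- which.max(cnt[150:250]) + 149
    endo_lo <- round(q_true * 200) - 50
    endo <- which.max(cnt[endo_lo:(endo_lo + 100)]) + endo_lo - 1
    expect_lt(abs((endo / emb) / q_true - 1), 0.01)
  }
})

test_that("endopolyploid simulation leaves no mode at the endosperm G1 position", {
  s <- simulate_histogram(seed_sim("2/3", endopolyploid = TRUE, g2 = FALSE),
                          rng_seed = 17)
  cnt <- s$histogram$counts
  # G1 position 150 empty, replicate at 300 present
  expect_lt(max(cnt[140:160]), 0.1 * max(cnt[90:110]))
  expect_gt(max(cnt[290:310]), 3 * max(cnt[140:160]))
  expect_false("endosperm_G1" %in% s$truth$role)
})

test_that("seed sets honor scenario mixes exactly via largest-remainder allocation", {
  # 20 sexual : 2 apomictic out of 22 seeds
  cfg <- list(list(species = "Festuca olgae",
                   mix = c("2/3" = 20 / 22, "2/6" = 2 / 22),
                   n_seeds = 22))
  s <- simulate_seed_set(cfg, rng_seed = 2)
  expect_equal(sum(s$truth$label == "2/6"), 2L)
  expect_equal(sum(s$truth$label == "2/3"), 20L)
  expect_equal(sum(s$truth$mode_truth == "apomictic_pseudogamous"), 2L)

  all_sex <- simulate_seed_set(list(list(species = "sp",
                                         mix = c("2/3" = 1), n_seeds = 5)),
                               rng_seed = 2)
  expect_true(all(all_sex$truth$mode_truth == "sexual"))

  half <- simulate_seed_set(list(list(species = "sp",
                                      mix = c("2/3" = 0.5, "2/5" = 0.5),
                                      n_seeds = 10)),
                            rng_seed = 4)
  expect_equal(as.integer(table(half$truth$label)[c("2/3", "2/5")]),
               c(5L, 5L))
})

test_that("seed-set config is validated", {
  expect_error(simulate_seed_set(list(), 1), "empty")
  expect_error(simulate_seed_set(list(list(species = "a",
                                           mix = c("2/3" = 0.7),
                                           n_seeds = 3)), 1),
               "sum to 1")
})

test_that("trait tables carry the configured group effects", {
  # null effects: standardized group difference within 3 SE for every trait
  cfg0 <- trait_sim_config(n_species = 200, apomict_fraction = 0.5,
                           effects = list(), rng_seed = 31)
  t0 <- simulate_trait_table(cfg0)
  cont <- setdiff(unlist(attr(t0, "trait_groups")),
                  fcss:::default_binary_traits())
  for (tr in cont) {
    a <- t0[[tr]][t0$mode_label == "apomict"]
    b <- t0[[tr]][t0$mode_label == "non_apomict"]
    se <- sqrt(var(a) / length(a) + var(b) / length(b))
    expect_lt(abs(mean(a) - mean(b)), 3 * se)
  }
  # a 1-sd shift is recovered within sampling error
  cfg1 <- trait_sim_config(n_species = 200, apomict_fraction = 0.5,
                           effects = list(moisture = 1.0), rng_seed = 32)
  t1 <- simulate_trait_table(cfg1)
  d <- (mean(t1$moisture[t1$mode_label == "apomict"]) -
          mean(t1$moisture[t1$mode_label == "non_apomict"])) /
    sd(t1$moisture[t1$mode_label == "non_apomict"])
  expect_gt(d, 0.6)
  expect_lt(d, 1.4)
})

test_that("trait simulation config is validated", {
  expect_error(trait_sim_config(n_species = 3), "n_species")
  expect_error(simulate_trait_table(
    trait_sim_config(effects = list(nonexistent_trait = 1))),
    "unknown trait")
  # both groups always populated
  t <- simulate_trait_table(trait_sim_config(n_species = 10,
                                             apomict_fraction = 0.01))
  expect_true(all(c("apomict", "non_apomict") %in% t$mode_label))
})
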